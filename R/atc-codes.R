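# The 14 WHO anatomical main groups (first-level letters).
ATC_LETTERS <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R",
                 "S", "V")

# Character widths of the first k code components: L, LDD, LDDL, LDDLL, LDDLLDD.
ATC_WIDTHS <- c(1L, 3L, 4L, 5L, 7L)

# Map total string width -> code depth; anything else is malformed.
atc_depth_from_width <- function(w) {
  d <- match(w, ATC_WIDTHS)
  d
}

#' Parse ATC code strings
#'
#' Splits WHO Anatomical Therapeutic Chemical codes into their 1-5 level
#' components and validates them against the code grammar: one anatomical
#' group letter, two digits (therapeutic group), one letter (therapeutic
#' subgroup), one letter (chemical/pharmacological subgroup) and two digits
#' (chemical substance). Codes may stop at any level; e.g. `"B01AC06"` is the
#' full five-level code of acetylsalicylic acid and `"B01A"` its three-level
#' prefix. Input is upper-cased before validation.
#'
#' @param x character vector of ATC code strings.
#' @return An object of class `"atc_code"`: a vectorised record with the raw
#'   strings, an n x 5 component matrix (`NA` beyond each code's depth) and a
#'   depth vector. Use [atc_levels()], [atc_depth()] and [atc_prefix()] to
#'   access it.
#' @examples
#' x <- parse_atc(c("B01AC06", "N02BA01", "A02BC"))
#' atc_depth(x)
#' atc_prefix(x, 3)
#' @export
parse_atc <- function(x) {
  if (length(x) == 0L || !is.character(x)) {
    stop("`x` must be a non-empty character vector of ATC codes")
  }
  if (anyNA(x) || any(!nzchar(x))) {
    stop("ATC codes must be non-empty strings")
  }
  raw <- toupper(trimws(x))
  depth <- atc_depth_from_width(nchar(raw))
  if (anyNA(depth)) {
    bad <- raw[which(is.na(depth))[1L]]
    stop(sprintf("malformed ATC code '%s': length %d is not a valid code length (1, 3, 4, 5 or 7)",
                 bad, nchar(bad)))
  }
  comp <- matrix(NA_character_, nrow = length(raw), ncol = 5L,
                 dimnames = list(NULL, paste0("L", 1:5)))
  comp[, 1L] <- substr(raw, 1L, 1L)
  has <- function(k) depth >= k
  comp[has(2L), 2L] <- substr(raw[has(2L)], 2L, 3L)
  comp[has(3L), 3L] <- substr(raw[has(3L)], 4L, 4L)
  comp[has(4L), 4L] <- substr(raw[has(4L)], 5L, 5L)
  comp[has(5L), 5L] <- substr(raw[has(5L)], 6L, 7L)

  bad1 <- !comp[, 1L] %in% ATC_LETTERS
  if (any(bad1)) {
    stop(sprintf("invalid ATC code '%s': level 1 letter '%s' is not one of the 14 anatomical groups",
                 raw[which(bad1)[1L]], comp[which(bad1)[1L], 1L]))
  }
  chk_digits <- function(k) {
    v <- comp[, k]
    bad <- !is.na(v) & !grepl("^[0-9]{2}$", v)
    if (any(bad)) {
      stop(sprintf("invalid ATC code '%s': level %d component '%s' must be two digits",
                   raw[which(bad)[1L]], k, v[which(bad)[1L]]))
    }
  }
  chk_letter <- function(k) {
    v <- comp[, k]
    bad <- !is.na(v) & !grepl("^[A-Z]$", v)
    if (any(bad)) {
      stop(sprintf("invalid ATC code '%s': level %d component '%s' must be a single letter",
                   raw[which(bad)[1L]], k, v[which(bad)[1L]]))
    }
  }
  chk_digits(2L); chk_letter(3L); chk_letter(4L); chk_digits(5L)

  structure(list(raw = raw, components = comp, depth = depth),
            class = "atc_code")
}

#' @export
print.atc_code <- function(x, ...) {
  cat(sprintf("<atc_code> %d code(s)\n", length(x$raw)))
  show <- utils::head(x$raw, 10L)
  cat(" ", paste(show, collapse = " "),
      if (length(x$raw) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.atc_code <- function(x) length(x$raw)

#' @rdname parse_atc
#' @param code an `"atc_code"` object (or a character vector, parsed on the
#'   fly).
#' @export
atc_depth <- function(code) {
  code <- as_atc(code)
  code$depth
}

#' @rdname parse_atc
#' @export
atc_levels <- function(code) {
  code <- as_atc(code)
  if (length(code$raw) == 1L) {
    v <- code$components[1L, ]
    return(unname(v[!is.na(v)]))
  }
  code$components
}

as_atc <- function(code) {
  if (inherits(code, "atc_code")) code else parse_atc(code)
}

#' Prefix of an ATC code at a given level
#'
#' Returns the concatenation of the first `k` code components, e.g. the
#' level-3 prefix of `"A02BC"` is `"A02B"`. `k = 0` yields the empty root
#' prefix.
#'
#' @param code an `"atc_code"` object or character vector of codes.
#' @param k level index, `0 <= k <= depth(code)` for every code.
#' @return character vector of prefixes.
#' @export
atc_prefix <- function(code, k) {
  code <- as_atc(code)
  if (length(k) != 1L || is.na(k) || k < 0L || k != round(k)) {
    stop("`k` must be a single non-negative integer")
  }
  k <- as.integer(k)
  if (k == 0L) return(rep("", length(code$raw)))
  if (k > 5L || any(code$depth < k)) {
    stop(sprintf("level index k = %d exceeds the depth of at least one code", k))
  }
  substr(code$raw, 1L, ATC_WIDTHS[k])
}

# Depth of a prefix string ("" -> 0). Errors on malformed widths.
prefix_depth <- function(prefix) {
  if (prefix == "") return(0L)
  d <- atc_depth_from_width(nchar(prefix))
  if (is.na(d)) stop(sprintf("'%s' is not a valid ATC prefix", prefix))
  d
}

#' Empirical child distribution under an ATC prefix
#'
#' Counts, among a set of coded instances, the occurrences of each next-level
#' component below `parent_prefix`. This is the empirical "characteristic
#' distribution" of a branch of the ATC hierarchy: each anatomical group (and
#' more so each deeper prefix) concentrates on a specific subset of child
#' codes, which is what makes prefix-conditioned prediction informative.
#'
#' @param codes an `"atc_code"` object or character vector of codes (may be
#'   empty).
#' @param parent_prefix a valid ATC prefix string, or `""` for the root.
#' @return An object of class `"hierarchy_node"`: list with `prefix`, `depth`
#'   (of the prefix), `children` (named integer counts of next-level
#'   components, lexicographically ordered) and `n` (total instances under
#'   the prefix).
#' @examples
#' nd <- class_distribution(c("A02BC", "A02BA", "N02BA01"), "A02B")
#' nd$children  # A: 1, C: 1
#' @export
class_distribution <- function(codes, parent_prefix = "") {
  d <- prefix_depth(parent_prefix)
  if (d >= 5L) stop("parent_prefix is already a full five-level code")
  if (length(codes) == 0L ||
      (is.character(codes) && length(codes) == 0L)) {
    return(new_hierarchy_node(parent_prefix, d, integer(0)))
  }
  codes <- as_atc(codes)
  keep <- codes$depth >= d + 1L
  if (d > 0L) {
    keep <- keep & substr(codes$raw, 1L, nchar(parent_prefix)) == parent_prefix
  }
  comp <- codes$components[keep, d + 1L]
  counts <- table(comp)
  children <- stats::setNames(as.integer(counts), names(counts))
  children <- children[order(names(children))]
  new_hierarchy_node(parent_prefix, d, children)
}

new_hierarchy_node <- function(prefix, depth, children) {
  structure(list(prefix = prefix, depth = depth, children = children,
                 n = sum(children)),
            class = "hierarchy_node")
}

#' @export
print.hierarchy_node <- function(x, ...) {
  cat(sprintf("<hierarchy_node> prefix '%s' (depth %d), n = %d\n",
              x$prefix, x$depth, x$n))
  if (length(x$children)) {
    cat("  children:",
        paste(sprintf("%s:%d", names(x$children), x$children),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Expand a compound table into (compound, code) instances
#'
#' A compound may carry several ATC codes (aspirin, for instance, is both
#' B01AC06 and N02BA01). For training and evaluation each (compound, code)
#' pair is treated as a separate labelled instance.
#'
#' @param ids compound identifiers.
#' @param atc_codes character vector of `';'`-delimited ATC code lists,
#'   parallel to `ids`.
#' @return data.frame with columns `id`, `code` and `row` (the index of the
#'   originating compound), one row per (compound, code) pair.
#' @export
expand_instances <- function(ids, atc_codes) {
  stopifnot(length(ids) == length(atc_codes))
  parts <- strsplit(as.character(atc_codes), ";", fixed = TRUE)
  parts <- lapply(parts, function(p) trimws(p[nzchar(trimws(p))]))
  n <- lengths(parts)
  if (any(n == 0L)) {
    stop(sprintf("compound '%s' has no ATC code", ids[which(n == 0L)[1L]]))
  }
  out <- data.frame(id = rep(as.character(ids), n),
                    code = toupper(unlist(parts, use.names = FALSE)),
                    row = rep(seq_along(ids), n),
                    stringsAsFactors = FALSE)
  parse_atc(out$code)  # validation side effect
  out
}

#' Read / write compound tables
#'
#' Compound tables are UTF-8 CSV or TSV files with a header and columns
#' `id`, optional `smiles`, and `atc_codes` (a `';'`-delimited code list).
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @return data.frame with columns `id`, `smiles` (possibly `NA`) and
#'   `atc_codes`.
#' @export
read_compound_table <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  need <- c("id", "atc_codes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("compound table %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  if (is.null(df$smiles)) df$smiles <- NA_character_
  df[c("id", "smiles", "atc_codes")]
}

#' @rdname read_compound_table
#' @param compounds data.frame with columns `id`, `smiles` (optional) and
#'   `atc_codes`.
#' @export
write_compound_table <- function(compounds, path) {
  stopifnot(all(c("id", "atc_codes") %in% names(compounds)))
  if (is.null(compounds$smiles)) compounds$smiles <- NA_character_
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(compounds[c("id", "smiles", "atc_codes")], path,
                     sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
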