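#' Descriptor configuration
#'
#' Collects the tunable parameters of the three descriptor families:
#' chemical fingerprints (CFP, hashed linear-path or Morgan), chemical
#' interaction profiles (CIP, STITCH-style combined association scores
#' against a reference compound list) and chemical-target profiles (CTP,
#' shared high-confidence target counts against the reference list).
#'
#' @param kind one of `"cfp_linear"`, `"cfp_morgan"`, `"cip"`, `"ctp"`.
#' @param fp_size linear fingerprint bit length (default 2048).
#' @param max_path maximum encoded linear path length in bonds (default 7).
#' @param morgan_radius Morgan neighbourhood radius (default 4).
#' @param morgan_bits folded Morgan bit length (default 2048, matching the
#'   linear fingerprint).
#' @param ctp_min_score minimum combined confidence score for a
#'   chemical-target interaction to count (default 700).
#' @param ctp_organism organism identifier prefix of retained proteins
#'   (default `"9606"`, human; matched against the protein id up to the
#'   first dot, the STITCH `9606.ENSP...` convention).
#' @param cip_self_score score placed in a compound's own CIP cell when it is
#'   also a reference compound (default 1000, perfect self-association; set
#'   to 0 to zero the diagonal).
#' @return list of class `"descriptor_config"`.
#' @export
descriptor_config <- function(kind = c("cfp_linear", "cfp_morgan", "cip", "ctp"),
                              fp_size = 2048L, max_path = 7L,
                              morgan_radius = 4L, morgan_bits = 2048L,
                              ctp_min_score = 700L, ctp_organism = "9606",
                              cip_self_score = 1000L) {
  kind <- match.arg(kind)
  stopifnot(fp_size >= 1L, morgan_bits >= 1L, max_path >= 1L,
            morgan_radius >= 0L,
            ctp_min_score >= 0L, ctp_min_score <= 1000L,
            cip_self_score >= 0L, cip_self_score <= 1000L)
  structure(list(kind = kind, fp_size = as.integer(fp_size),
                 max_path = as.integer(max_path),
                 morgan_radius = as.integer(morgan_radius),
                 morgan_bits = as.integer(morgan_bits),
                 ctp_min_score = as.integer(ctp_min_score),
                 ctp_organism = ctp_organism,
                 cip_self_score = as.integer(cip_self_score)),
            class = "descriptor_config")
}

new_descriptor_matrix <- function(values, kind, ref_ids = NULL) {
  stopifnot(is.matrix(values))
  structure(values, kind = kind, ref_ids = ref_ids,
            class = c("descriptor_matrix", class(values)))
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> kind '%s': %d compound(s) x %d feature(s)\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname descriptor_config
#' @param x a descriptor matrix.
#' @export
descriptor_kind <- function(x) attr(x, "kind")

# ---- STITCH-dialect readers -------------------------------------------------

read_stitch_file <- function(path, cols) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "",
                      comment.char = ""),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e))))
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  df <- df[cols]
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- is.na(score) | score != floor(score)
  if (any(bad)) {
    stop(sprintf("%s line %d: combined_score '%s' is not an integer",
                 path, which(bad)[1L] + 1L, df$combined_score[which(bad)[1L]]))
  }
  bad <- score < 0 | score > 1000
  if (any(bad)) {
    stop(sprintf("%s line %d: combined_score %d outside [0, 1000]",
                 path, which(bad)[1L] + 1L, as.integer(score[which(bad)[1L]])))
  }
  df$combined_score <- as.integer(score)
  df
}

#' Read STITCH-dialect association and target tables
#'
#' Chemical-chemical association dumps carry columns `chemical_a`,
#' `chemical_b`, `combined_score`; chemical-protein dumps carry `chemical`,
#' `protein`, `combined_score`. Combined scores are integers in \[0, 1000\]
#' (0 = no discernible association, 1000 = maximal). Files are tab-separated
#' with a header and may be gzip-compressed.
#'
#' @param path file path (plain or `.gz`).
#' @return data.frame of validated records, classed `"stitch_assoc"` or
#'   `"stitch_targets"`.
#' @export
read_stitch_associations <- function(path) {
  df <- read_stitch_file(path, c("chemical_a", "chemical_b", "combined_score"))
  class(df) <- c("stitch_assoc", "data.frame")
  df
}

#' @rdname read_stitch_associations
#' @export
read_stitch_targets <- function(path) {
  df <- read_stitch_file(path, c("chemical", "protein", "combined_score"))
  class(df) <- c("stitch_targets", "data.frame")
  df
}

#' @rdname read_stitch_associations
#' @param records an association / target record data.frame.
#' @export
write_stitch_associations <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(records[c("chemical_a", "chemical_b", "combined_score")],
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_stitch_associations
#' @export
write_stitch_targets <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(records[c("chemical", "protein", "combined_score")],
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- CIP --------------------------------------------------------------------

#' Chemical interaction profiles (CIP)
#'
#' Encodes each query compound as the vector of combined association scores
#' against an ordered reference compound list. Cell (i, j) holds the
#' combined score between query i and reference j, looked up symmetrically
#' in the association table; pairs with no record are 0 (unknown or absent
#' associations carry no signal). When a query compound is itself a
#' reference compound its own cell is set to `cip_self_score` (default
#' 1000). The reference list is typically the training-set compound list,
#' frozen at training time, so train and test descriptors share one feature
#' space.
#'
#' @param query_ids compound ids to encode (rows).
#' @param assoc association records, e.g. from [read_stitch_associations()].
#' @param reference_ids ordered, duplicate-free reference compound ids
#'   (columns).
#' @param config a [descriptor_config()]; only `cip_self_score` is used.
#' @return `"descriptor_matrix"` of kind `"cip"`, values in \[0, 1000\].
#' @export
build_cip <- function(query_ids, assoc, reference_ids,
                      config = descriptor_config("cip")) {
  check_reference(reference_ids)
  query_ids <- as.character(query_ids)
  ids <- unique(c(query_ids, reference_ids,
                  assoc$chemical_a, assoc$chemical_b))
  # symmetric sparse score matrix over the id universe; if a pair is
  # recorded more than once (or in both orientations) keep the max score
  i <- c(match(assoc$chemical_a, ids), match(assoc$chemical_b, ids))
  j <- c(match(assoc$chemical_b, ids), match(assoc$chemical_a, ids))
  x <- rep(as.numeric(assoc$combined_score), 2L)
  key <- (i - 1) * length(ids) + j
  agg <- tapply(x, key, max)
  k <- as.numeric(names(agg))
  m <- Matrix::sparseMatrix(i = (k - 1) %/% length(ids) + 1,
                            j = (k - 1) %% length(ids) + 1,
                            x = as.numeric(agg),
                            dims = c(length(ids), length(ids)))
  vals <- as.matrix(m[match(query_ids, ids), match(reference_ids, ids),
                      drop = FALSE])
  self <- outer(query_ids, reference_ids, "==")
  vals[self] <- config$cip_self_score
  dimnames(vals) <- list(query_ids, reference_ids)
  new_descriptor_matrix(vals, "cip", reference_ids)
}

check_reference <- function(reference_ids) {
  if (length(reference_ids) == 0L) stop("reference_ids must be non-empty")
  if (anyDuplicated(reference_ids)) {
    stop(sprintf("duplicate reference id '%s'",
                 reference_ids[duplicated(reference_ids)][1L]))
  }
}

# ---- CTP --------------------------------------------------------------------

#' Chemical-target profiles (CTP)
#'
#' Encodes each query compound as the vector of shared-target counts against
#' an ordered reference compound list: cell (i, j) is the number of distinct
#' proteins that both query i and reference j interact with, counting only
#' high-confidence records (combined score >= `ctp_min_score`, default 700)
#' with proteins of the configured organism (default human, prefix `9606`).
#'
#' @param query_ids compound ids to encode (rows).
#' @param targets chemical-protein records, e.g. from
#'   [read_stitch_targets()].
#' @param reference_ids ordered, duplicate-free reference compound ids.
#' @param config a [descriptor_config()]; `ctp_min_score` and `ctp_organism`
#'   are used.
#' @return `"descriptor_matrix"` of kind `"ctp"`, non-negative integer
#'   shared-target counts.
#' @export
build_ctp <- function(query_ids, targets, reference_ids,
                      config = descriptor_config("ctp")) {
  check_reference(reference_ids)
  query_ids <- as.character(query_ids)
  organism <- sub("\\..*$", "", targets$protein)
  keep <- targets$combined_score >= config$ctp_min_score &
    organism == config$ctp_organism
  t2 <- unique(targets[keep, c("chemical", "protein")])
  ids <- unique(c(query_ids, reference_ids, t2$chemical))
  prot <- unique(t2$protein)
  if (length(prot) == 0L) {
    vals <- matrix(0L, nrow = length(query_ids), ncol = length(reference_ids),
                   dimnames = list(query_ids, reference_ids))
    return(new_descriptor_matrix(vals, "ctp", reference_ids))
  }
  inc <- Matrix::sparseMatrix(i = match(t2$chemical, ids),
                              j = match(t2$protein, prot),
                              x = 1,
                              dims = c(length(ids), length(prot)))
  shared <- Matrix::tcrossprod(inc[match(query_ids, ids), , drop = FALSE],
                               inc[match(reference_ids, ids), , drop = FALSE])
  vals <- as.matrix(shared)
  storage.mode(vals) <- "integer"
  dimnames(vals) <- list(query_ids, reference_ids)
  new_descriptor_matrix(vals, "ctp", reference_ids)
}

# ---- descriptor matrix I/O --------------------------------------------------

#' Export / import descriptor matrices
#'
#' `write_descriptor_tsv()` writes a matrix as TSV with a
#' `# descriptor_kind:` comment header so the kind survives a round trip;
#' `write_descriptor_mtx()` writes sparse MatrixMarket coordinates plus row
#' and column id sidecars.
#'
#' @param x a `"descriptor_matrix"` (or plain matrix with row names).
#' @param path output path; for `write_descriptor_mtx` a path prefix.
#' @export
write_descriptor_tsv <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# descriptor_kind: %s", attr(x, "kind") %||% "unknown"),
             con)
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_tsv
#' @export
read_descriptor_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- if (grepl("^# descriptor_kind:", first)) {
    trimws(sub("^# descriptor_kind:", "", first))
  } else "unknown"
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  new_descriptor_matrix(m, kind, colnames(m))
}

#' @rdname write_descriptor_tsv
#' @export
write_descriptor_mtx <- function(x, path) {
  Matrix::writeMM(as(Matrix::Matrix(unclass(x), sparse = TRUE), "generalMatrix"),
                  paste0(path, ".mtx"))
  writeLines(rownames(x), paste0(path, ".rows"))
  writeLines(colnames(x), paste0(path, ".cols"))
  invisible(path)
}
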