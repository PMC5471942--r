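# Chemical fingerprints over molecular graphs parsed from SMILES.
#
# Two families are implemented: a hashed linear-path fingerprint (every
# linear substructure of up to `max_path` bonds sets one bit of a fixed-
# length vector) and a Morgan fingerprint (iteratively hashed circular atom
# neighbourhoods up to a preset radius, folded to a fixed bit length).
# Both depend only on the molecular graph -- element symbols, bond orders
# and connectivity -- so different atom orderings of the same structure
# ("CCO" vs "OCC") give bit-identical vectors.

# Deterministic 31-bit string hash (polynomial rolling hash; doubles keep
# the intermediate products exact well below 2^53).
hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

hash_ints <- function(v) {
  h <- 0
  for (b in v) h <- (h * 131 + (b %% 2147483647)) %% 2147483647
  h
}

# Parse one SMILES string into a molecular graph. Open Babel (via
# ChemmineOB, the engine behind ChemmineR's SMILES support) interprets the
# SMILES and emits a V2000 molblock whose atom and bond lines are read
# here; heavy atoms only, bond orders kekulized.
smiles_to_graph <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  counts_at <- grep("V2000", lines, fixed = TRUE)[1L]
  if (is.na(counts_at)) stop(sprintf("cannot parse SMILES '%s'", smiles))
  n_atoms <- as.integer(substr(lines[counts_at], 1L, 3L))
  n_bonds <- as.integer(substr(lines[counts_at], 4L, 6L))
  if (is.na(n_atoms) || n_atoms == 0L) {
    stop(sprintf("cannot parse SMILES '%s'", smiles))
  }
  atom_lines <- lines[counts_at + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  if (n_bonds > 0L) {
    bond_lines <- lines[counts_at + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(a = as.integer(substr(bond_lines, 1L, 3L)),
                        b = as.integer(substr(bond_lines, 4L, 6L)),
                        order = as.integer(substr(bond_lines, 7L, 9L)))
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  }
  n <- length(elements)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$a[r]]] <- rbind(adj[[bonds$a[r]]],
                               c(bonds$b[r], bonds$order[r]))
    adj[[bonds$b[r]]] <- rbind(adj[[bonds$b[r]]],
                               c(bonds$a[r], bonds$order[r]))
  }
  list(elements = elements, bonds = bonds, adj = adj, n = n)
}

# Enumerate canonical labels of all simple linear paths of 0..max_path bonds.
# A path label interleaves element symbols and bond orders; the canonical
# form is the lexicographic minimum of the label and its reversal, so each
# undirected path contributes one label regardless of traversal direction.
linear_path_labels <- function(g, max_path) {
  labels <- new.env(parent = emptyenv())
  walk <- function(atom, visited, elems, orders) {
    lab_fwd <- paste(elems, orders, sep = "", collapse = "|")
    lab_rev <- paste(rev(elems), c("", rev(orders[-1L])), sep = "",
                     collapse = "|")
    assign(min(lab_fwd, lab_rev), TRUE, envir = labels)
    if (length(orders) - 1L >= max_path) return()
    nb <- g$adj[[atom]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1L]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt),
           c(elems, g$elements[nxt]), c(orders, nb[r, 2L]))
    }
  }
  for (a in seq_len(g$n)) {
    walk(a, a, g$elements[a], "")
  }
  ls(labels)
}

#' Chemical fingerprints from SMILES
#'
#' `compute_cfp_linear()` enumerates every linear substructure (simple path)
#' of up to `max_path` bonds, labels it by its element symbols and bond
#' orders, and hashes each label onto a bit of a length-`fp_size` vector.
#' `compute_cfp_morgan()` starts from per-atom invariants (element, degree,
#' attached bond orders), iteratively re-hashes each atom's invariant with
#' its sorted neighbour invariants up to `morgan_radius` bond shells, and
#' folds every intermediate invariant onto a length-`morgan_bits` vector.
#' Both are deterministic and invariant to the input atom ordering of the
#' same (kekulized) structure.
#'
#' @param smiles a single SMILES string.
#' @param config a [descriptor_config()] supplying `fp_size`/`max_path`
#'   (linear) or `morgan_radius`/`morgan_bits` (Morgan).
#' @return integer 0/1 vector of the configured length.
#' @examples
#' \donttest{
#' fp <- compute_cfp_linear("CCO")
#' sum(fp)
#' }
#' @export
compute_cfp_linear <- function(smiles, config = descriptor_config("cfp_linear")) {
  g <- smiles_to_graph(smiles)
  labs <- linear_path_labels(g, config$max_path)
  fp <- integer(config$fp_size)
  idx <- vapply(labs, hash_string, numeric(1)) %% config$fp_size + 1
  fp[unique(as.integer(idx))] <- 1L
  fp
}

#' @rdname compute_cfp_linear
#' @export
compute_cfp_morgan <- function(smiles, config = descriptor_config("cfp_morgan")) {
  g <- smiles_to_graph(smiles)
  deg <- vapply(g$adj, function(nb) if (is.null(nb)) 0L else nrow(nb),
                integer(1))
  bsum <- vapply(g$adj, function(nb) if (is.null(nb)) 0L else sum(nb[, 2L]),
                 integer(1))
  inv <- vapply(seq_len(g$n), function(a) {
    hash_string(paste(g$elements[a], deg[a], bsum[a], sep = ":"))
  }, numeric(1))
  all_inv <- inv
  if (config$morgan_radius > 0L) {
    for (r in seq_len(config$morgan_radius)) {
      inv <- vapply(seq_len(g$n), function(a) {
        nb <- g$adj[[a]]
        if (is.null(nb)) return(hash_ints(c(r, inv[a])))
        pairs <- cbind(nb[, 2L], inv[nb[, 1L]])
        ord <- order(pairs[, 1L], pairs[, 2L])
        hash_ints(c(r, inv[a], t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      all_inv <- c(all_inv, inv)
    }
  }
  fp <- integer(config$morgan_bits)
  fp[unique(as.integer(all_inv %% config$morgan_bits)) + 1L] <- 1L
  fp
}

#' Build a fingerprint descriptor matrix
#'
#' @param smiles character vector of SMILES strings.
#' @param ids compound ids, parallel to `smiles`.
#' @param config a [descriptor_config()] of kind `"cfp_linear"` or
#'   `"cfp_morgan"`.
#' @return `"descriptor_matrix"` of 0/1 values, one row per compound.
#' @export
build_cfp <- function(smiles, ids, config = descriptor_config("cfp_linear")) {
  stopifnot(length(smiles) == length(ids),
            config$kind %in% c("cfp_linear", "cfp_morgan"))
  f <- if (config$kind == "cfp_linear") compute_cfp_linear else compute_cfp_morgan
  vals <- t(vapply(smiles, f, integer(
    if (config$kind == "cfp_linear") config$fp_size else config$morgan_bits),
    config = config))
  rownames(vals) <- as.character(ids)
  colnames(vals) <- paste0("bit", seq_len(ncol(vals)))
  new_descriptor_matrix(vals, config$kind, NULL)
}

#' Read a SMILES file
#'
#' One molecule per line, `SMILES<Tab>id`.
#'
#' @param path file path.
#' @return data.frame with columns `smiles` and `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop(sprintf("%s line %d: expected 'SMILES<Tab>id'", path, which(bad)[1L]))
  }
  data.frame(smiles = vapply(parts, `[[`, "", 1L),
             id = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}
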