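#' Residue contact graph from atomic coordinates
#'
#' Two residues are in contact when any pair of their atoms lies within the
#' distance cutoff (5 angstrom by default). Self-pairs are excluded;
#' sequence-adjacent residues are retained (they are genuine spatial
#' neighbors). A residue with no atoms yields a warning and an isolated
#' node.
#'
#' @param atoms data.frame with columns `residue` (1-based index), `x`, `y`,
#'   `z` (angstrom). One row per atom.
#' @param cutoff contact distance in angstrom (default 5.0).
#' @param n_residues protein length; defaults to `max(atoms$residue)`.
#' @param model_id identifier of the source structure model.
#' @return object of class `contact_graph`: `n_residues`, `edges` (2-column
#'   integer matrix, i < j), `cutoff`, `model_id`.
#' @export
contact_graph_from_coordinates <- function(atoms, cutoff = 5.0,
                                           n_residues = max(atoms$residue),
                                           model_id = "model") {
  stopifnot(all(c("residue", "x", "y", "z") %in% names(atoms)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  res <- as.integer(atoms$residue)
  if (any(res < 1 | res > n_residues)) stop("residue index outside 1..", n_residues)
  empty <- setdiff(seq_len(n_residues), unique(res))
  if (length(empty)) {
    warning(length(empty), " residue(s) have no atoms and become isolated nodes")
  }
  # any-atom-pair criterion via indicator algebra: with D the atom-atom
  # within-cutoff indicator and A the atom->residue incidence, t(A) D A
  # counts close atom pairs per residue pair.
  d2 <- as.matrix(dist(xyz))^2
  close <- d2 <= cutoff^2
  A <- matrix(0L, nrow(xyz), n_residues)
  A[cbind(seq_along(res), res)] <- 1L
  pair_counts <- t(A) %*% close %*% A
  diag(pair_counts) <- 0
  idx <- which(pair_counts > 0 & upper.tri(pair_counts), arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2, dimnames = list(NULL, c("i", "j")))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(
    list(
      n_residues = as.integer(n_residues), edges = edges,
      cutoff = cutoff, model_id = model_id
    ),
    class = "contact_graph"
  )
}

#' Contact graph from a precomputed contact list
#'
#' @param pairs data.frame or 2-column matrix of residue index pairs.
#' @param n_residues protein length.
#' @param cutoff,model_id metadata carried on the graph.
#' @return `contact_graph`.
#' @export
contact_graph_from_pairs <- function(pairs, n_residues, cutoff = 5.0,
                                     model_id = "model") {
  m <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(m) <- "integer"
  if (nrow(m)) {
    if (any(m < 1 | m > n_residues)) stop("residue index outside 1..", n_residues)
    m <- t(apply(m, 1, sort))
    m <- m[m[, 1] != m[, 2], , drop = FALSE]
    m <- unique(m)
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  colnames(m) <- c("i", "j")
  structure(
    list(n_residues = as.integer(n_residues), edges = m, cutoff = cutoff, model_id = model_id),
    class = "contact_graph"
  )
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(
    "<contact_graph> ", x$model_id, ": ", x$n_residues, " residues, ",
    nrow(x$edges), " contacts at <= ", x$cutoff, " A\n",
    sep = ""
  )
  invisible(x)
}

# Symmetric adjacency (logical matrix) with or without self-loops.
adjacency <- function(graph, include_self = FALSE) {
  A <- matrix(FALSE, graph$n_residues, graph$n_residues)
  if (nrow(graph$edges)) {
    A[graph$edges] <- TRUE
    A[graph$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  if (include_self) diag(A) <- TRUE
  A
}

#' Consensus cross-chain interface residues
#'
#' Given the interface residue sets observed in each chain-chain interacting
#' pair (e.g. from several crystallographic dimers), keep residues whose
#' cross-chain contact reproduces in at least `min_support` of the
#' `total_pairs` pairs.
#'
#' @param per_pair_sets list of integer vectors (residue indices on the
#'   reference chain), one per chain-chain pair.
#' @param min_support minimum number of supporting pairs (default 4).
#' @param total_pairs total chain-chain pairs considered (default 6;
#'   metadata only, must be >= `min_support`).
#' @return object of class `residue_set`: `residues` (sorted integer
#'   vector), `support` (named counts for every residue seen at least once),
#'   `min_support`, `total_pairs`.
#' @export
consensus_interface <- function(per_pair_sets, min_support = 4, total_pairs = 6) {
  stopifnot(total_pairs >= min_support, min_support >= 1)
  counts <- table(unlist(lapply(per_pair_sets, unique)))
  keep <- as.integer(names(counts)[counts >= min_support])
  structure(
    list(
      residues = sort(keep),
      support = setNames(as.integer(counts), names(counts)),
      min_support = min_support, total_pairs = total_pairs
    ),
    class = "residue_set"
  )
}

#' @export
print.residue_set <- function(x, ...) {
  cat(
    "<residue_set> ", length(x$residues), " residues (support >= ",
    x$min_support, "/", x$total_pairs, ")\n",
    sep = ""
  )
  invisible(x)
}
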