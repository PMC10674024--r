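#' Call single-residue mutation hotspots
#'
#' Per-residue one-sided binomial test of the observed count against the
#' expected residue probability (from a mutability profile, or uniform),
#' with Benjamini-Hochberg correction across residues. A residue is called
#' when its q-value (default; raw p optionally) falls below `alpha`.
#'
#' @param observed integer vector of per-residue mutation counts.
#' @param expected per-residue expected probabilities (normalized
#'   internally); defaults to uniform.
#' @param alpha significance threshold (default 0.005).
#' @param gate `"q"` (default) gates on BH q-values, `"p"` on raw p-values.
#' @return data.frame of class `hotspot_calls`, one row per residue:
#'   `residue`, `observed`, `expected` (count scale), `p_value`, `q_value`,
#'   `called`.
#' @export
call_linear_hotspots <- function(observed, expected = NULL, alpha = 0.005,
                                 gate = c("q", "p")) {
  gate <- match.arg(gate)
  n <- sum(observed)
  if (n <= 0) stop("no observed mutations")
  R <- length(observed)
  if (is.null(expected)) expected <- rep(1 / R, R)
  stopifnot(length(expected) == R, all(expected >= 0))
  p_res <- expected / sum(expected)
  # upper-tail P(X >= x); residues with zero expected mass and zero counts
  # are untestable for excess (p = 1)
  pv <- pbinom(observed - 1L, n, p_res, lower.tail = FALSE)
  pv[p_res == 0 & observed == 0] <- 1
  qv <- p.adjust(pv, method = "BH")
  called <- if (gate == "q") qv < alpha else pv < alpha
  out <- data.frame(
    residue = seq_len(R), observed = observed, expected = n * p_res,
    p_value = pv, q_value = qv, called = called
  )
  class(out) <- c("hotspot_calls", class(out))
  out
}

# Per-graph significant residue set for the spatial caller: each residue's
# neighborhood (itself + direct contacts) is tested for aggregate excess.
spatial_significant <- function(observed, p_res, graph, alpha, gate) {
  A <- adjacency(graph, include_self = TRUE)
  n <- sum(observed)
  obs_nb <- as.vector(A %*% observed)
  p_nb <- as.vector(A %*% p_res)
  pv <- pbinom(obs_nb - 1L, n, pmin(p_nb, 1), lower.tail = FALSE)
  pv[p_nb == 0 & obs_nb == 0] <- 1
  pv[p_nb >= 1] <- 1  # a neighborhood covering all mass cannot show excess
  qv <- p.adjust(pv, method = "BH")
  sig <- if (gate == "q") qv < alpha else pv < alpha
  list(sig = which(sig), p = pv, q = qv, A = A)
}

# Connected components of the subgraph induced on `members` (plain BFS).
components_of <- function(members, A) {
  remaining <- members
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(which(A[v, ]), remaining)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

#' Call 3D mutation hotspots on residue contact graphs
#'
#' For each structure model, every residue neighborhood (the residue plus
#' its direct <= cutoff contacts) is tested for aggregate mutation excess by
#' a one-sided binomial test, BH-corrected within the graph. Residues
#' covered by a significant neighborhood are merged into connected clusters.
#' Clusters found in different graphs that share residues are merged into
#' one reported 3D hotspot; a hotspot is `high_confidence` when every graph
#' contributed a cluster to it (the two-tier convention: any-model versus
#' all-model support). With edgeless graphs the procedure reduces to
#' [call_linear_hotspots()].
#'
#' @param observed integer vector of per-residue mutation counts
#'   (missense + inframe indels by field convention; the caller restricts).
#' @param expected per-residue expected probabilities; uniform when NULL.
#' @param graphs list of [contact_graph_from_coordinates()] objects sharing
#'   the protein length.
#' @param alpha significance threshold (default 0.005).
#' @param gate `"q"` or `"p"` as in [call_linear_hotspots()].
#' @return data.frame, one row per 3D hotspot: `cluster` (id), `residues`
#'   (comma-separated), `n_residues`, `observed`, `expected`, `p_min`
#'   (smallest neighborhood p across supporting graphs), `n_graphs`,
#'   `high_confidence`.
#' @export
call_spatial_hotspots <- function(observed, expected = NULL, graphs,
                                  alpha = 0.005, gate = c("q", "p")) {
  gate <- match.arg(gate)
  if (!length(graphs)) stop("at least one contact graph is required")
  R <- length(observed)
  if (!all(vapply(graphs, function(g) g$n_residues, integer(1)) == R)) {
    stop("all graphs must share the protein length (", R, ")")
  }
  if (is.null(expected)) expected <- rep(1 / R, R)
  p_res <- expected / sum(expected)
  n <- sum(observed)
  if (n <= 0) stop("no observed mutations")

  per_graph <- lapply(graphs, function(g) {
    s <- spatial_significant(observed, p_res, g, alpha, gate)
    comps <- components_of(s$sig, s$A)
    lapply(comps, function(resids) {
      list(residues = resids, p_min = min(s$p[resids]))
    })
  })

  flat <- list()
  for (gi in seq_along(per_graph)) {
    for (cl in per_graph[[gi]]) {
      flat[[length(flat) + 1]] <- c(cl, graph = gi)
    }
  }
  if (!length(flat)) {
    out <- data.frame(
      cluster = integer(0), residues = character(0), n_residues = integer(0),
      observed = integer(0), expected = numeric(0), p_min = numeric(0),
      n_graphs = integer(0), high_confidence = logical(0)
    )
    return(out)
  }
  # union-find over clusters sharing residues across graphs
  parent <- seq_along(flat)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(flat)) {
    for (j in seq_len(i - 1)) {
      if (length(intersect(flat[[i]]$residues, flat[[j]]$residues))) {
        parent[find(i)] <- find(j)
      }
    }
  }
  groups <- split(seq_along(flat), vapply(seq_along(flat), find, integer(1)))
  rows <- lapply(seq_along(groups), function(k) {
    members <- flat[groups[[k]]]
    resids <- sort(unique(unlist(lapply(members, `[[`, "residues"))))
    gset <- unique(vapply(members, `[[`, numeric(1), "graph"))
    data.frame(
      cluster = k,
      residues = paste(resids, collapse = ","),
      n_residues = length(resids),
      observed = sum(observed[resids]),
      expected = n * sum(p_res[resids]),
      p_min = min(vapply(members, `[[`, numeric(1), "p_min")),
      n_graphs = length(gset),
      high_confidence = length(gset) == length(graphs)
    )
  })
  do.call(rbind, rows)
}

#' Interface coldspot depletion test
#'
#' Two-sided exact binomial test of the mutation count inside a residue set
#' (e.g. the dimer interface) against its mutability-weighted expectation.
#' The fold depletion is the mutability-normalized rate ratio of the
#' outside versus the inside of the set,
#' `((n - x)/(1 - p)) / (x/p)`, i.e. how many times lower mutations occur
#' in the set than elsewhere once expected mass is accounted for (Inf when
#' nothing was observed inside). Unlike the raw expected/observed quotient,
#' the rate ratio is centered on the true fold when depletion redistributes
#' mass to the rest of the protein.
#'
#' @param observed integer vector of per-residue counts.
#' @param interface integer vector of interface residue indices, or a
#'   [consensus_interface()] `residue_set`.
#' @param expected per-residue expected probabilities; uniform when NULL.
#' @return list of class `depletion_result`: `observed_in_set`,
#'   `expected_in_set`, `fold_depletion`, `p_value`.
#' @export
interface_depletion_test <- function(observed, interface, expected = NULL) {
  if (inherits(interface, "residue_set")) interface <- interface$residues
  if (!length(interface)) stop("interface set is empty")
  R <- length(observed)
  if (any(interface < 1 | interface > R)) stop("interface residue outside 1..", R)
  if (is.null(expected)) expected <- rep(1 / R, R)
  p_res <- expected / sum(expected)
  p_set <- sum(p_res[interface])
  if (p_set <= 0) stop("interface carries zero expected mass")
  n <- sum(observed)
  if (n <= 0) stop("no observed mutations")
  if (p_set >= 1) stop("interface covers all expected mass; no outside to compare")
  x <- sum(observed[interface])
  bt <- binom.test(x, n, p_set)
  structure(
    list(
      observed_in_set = x,
      expected_in_set = n * p_set,
      fold_depletion = if (x > 0) ((n - x) / (1 - p_set)) / (x / p_set) else Inf,
      p_value = bt$p.value
    ),
    class = "depletion_result"
  )
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(
    "<depletion_result> observed ", x$observed_in_set, " vs expected ",
    format(x$expected_in_set, digits = 4), ": fold depletion ",
    format(x$fold_depletion, digits = 3), ", p = ",
    format(x$p_value, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Conservation contrast between hotspot and non-hotspot residues
#'
#' Two-sample rank-sum (Wilcoxon) test on per-residue conservation scores
#' between hotspot and non-hotspot residues. Scores follow the convention
#' that lower = more evolutionarily constrained, so `direction`
#' `"hotspots_lower"` means hotspots sit at more conserved residues.
#'
#' @param hotspot,non_hotspot disjoint integer vectors of residue indices.
#' @param scores numeric vector of per-residue conservation scores (indexed
#'   by residue) or named by residue.
#' @param alternative passed to [stats::wilcox.test()] (default two-sided).
#' @return list: `statistic` (W), `p_value`, `direction`, group medians.
#' @export
conservation_contrast <- function(hotspot, non_hotspot, scores,
                                  alternative = "two.sided") {
  if (length(intersect(hotspot, non_hotspot))) {
    stop("hotspot and non-hotspot residue sets overlap")
  }
  if (!length(hotspot) || !length(non_hotspot)) stop("both residue sets must be nonempty")
  get <- function(idx) {
    v <- if (!is.null(names(scores))) scores[as.character(idx)] else scores[idx]
    if (anyNA(v)) stop("conservation scores missing for some residues")
    unname(v)
  }
  a <- get(hotspot)
  b <- get(non_hotspot)
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative))
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    direction = if (median(a) < median(b)) "hotspots_lower" else "hotspots_higher",
    median_hotspot = median(a),
    median_non_hotspot = median(b)
  )
}
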