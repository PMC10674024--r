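#' Fit a permutation-based threshold tree for panel MSI imputation
#'
#' Recursive partitioning in the conditional-inference style: at each node the
#' feature with the smallest permutation-test association p-value with the
#' MSS/MSI-H label is selected, and the node splits only when that p-value
#' falls below `alpha`. The cutoff is found by an exhaustive scan over all
#' candidate thresholds (midpoints between consecutive distinct feature
#' values), scored by the chi-square statistic of the induced 2x2 table; ties
#' break toward the midpoint of the widest separating gap. The permutation
#' scheme makes the fit seedable and deterministic.
#'
#' Designed to learn TMB-free MSI classification from panels that report only
#' copy-number-altered fraction, mismatch-repair gene mutation status, and
#' raw mutation count.
#'
#' @param samples data.frame holding the feature columns and a label column.
#' @param features character vector of feature column names (numeric or
#'   logical).
#' @param label name of the label column (two classes; factors/characters).
#' @param alpha significance required to split (default 0.001, i.e. the
#'   ctree-style minimum criterion 0.999).
#' @param n_perm label permutations per association test (default 10000).
#' @param min_node minimum node size eligible for splitting.
#' @param seed RNG seed for the permutation draws.
#' @return object of class `ms_threshold_tree`; internal nodes carry
#'   `feature`, `cutoff` (go left when `value < cutoff`), `p_value`; leaves
#'   carry the majority `label` and class counts.
#' @export
fit_threshold_tree <- function(samples, features, label = "ms_status_known",
                               alpha = 0.001, n_perm = 10000,
                               min_node = 20, seed = 1) {
  if (!length(features)) stop("empty feature set")
  miss <- setdiff(c(features, label), names(samples))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- as.character(samples[[label]])
  classes <- sort(unique(y))
  if (length(classes) > 2) stop("label must have at most two classes")
  x <- samples[features]
  for (f in features) x[[f]] <- as.numeric(x[[f]])
  if (anyNA(x) || anyNA(y)) stop("features and label must be complete")
  set.seed(seed)
  tree <- grow_node(x, y, classes, alpha, n_perm, min_node)
  structure(
    list(root = tree, features = features, classes = classes, alpha = alpha),
    class = "ms_threshold_tree"
  )
}

# Association p-value of numeric feature vs binary label by label
# permutation; statistic = |difference of class means|.
perm_assoc_p <- function(xf, y01, n_perm) {
  n1 <- sum(y01)
  n0 <- length(y01) - n1
  if (n1 == 0 || n0 == 0) return(1)
  stat <- function(lab) abs(sum(xf[lab]) / n1 - sum(xf[!lab]) / n0)
  obs <- stat(y01)
  total <- sum(xf)
  perm <- vapply(seq_len(n_perm), function(i) {
    s1 <- sum(xf[sample.int(length(xf), n1)])
    abs(s1 / n1 - (total - s1) / n0)
  }, numeric(1))
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

# Exhaustive cutoff scan: chi-square statistic of split x label 2x2; ties to
# the midpoint of the widest gap between consecutive distinct values.
best_cutoff <- function(xf, y01) {
  vals <- sort(unique(xf))
  if (length(vals) < 2) return(NULL)
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  gaps <- diff(vals)
  n <- length(xf)
  n1 <- sum(y01)
  score <- vapply(mids, function(m) {
    left <- xf < m
    a <- sum(left & y01); b <- sum(left & !y01)
    c_ <- n1 - a; d <- (n - n1) - b
    nl <- a + b; nr <- c_ + d
    if (nl == 0 || nr == 0) return(-Inf)
    e <- outer(c(nl, nr), c(n1, n - n1)) / n
    o <- matrix(c(a, c_, b, d), 2)
    sum((o - e)^2 / pmax(e, .Machine$double.eps))
  }, numeric(1))
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  mids[cand[which.max(gaps[cand])]]
}

grow_node <- function(x, y, classes, alpha, n_perm, min_node) {
  counts <- table(factor(y, levels = classes))
  majority <- classes[which.max(counts)]
  leaf <- list(leaf = TRUE, label = majority, n = length(y), counts = as.vector(counts))
  if (length(unique(y)) < 2 || length(y) < min_node) return(leaf)
  y01 <- y == classes[2]
  pvals <- vapply(names(x), function(f) perm_assoc_p(x[[f]], y01, n_perm), numeric(1))
  f <- names(x)[which.min(pvals)]
  if (pvals[f] >= alpha) return(leaf)
  cutoff <- best_cutoff(x[[f]], y01)
  if (is.null(cutoff)) return(leaf)
  left <- x[[f]] < cutoff
  if (!any(left) || all(left)) return(leaf)
  list(
    leaf = FALSE, feature = f, cutoff = cutoff, p_value = unname(pvals[f]),
    n = length(y),
    left = grow_node(x[left, , drop = FALSE], y[left], classes, alpha, n_perm, min_node),
    right = grow_node(x[!left, , drop = FALSE], y[!left], classes, alpha, n_perm, min_node)
  )
}

#' Predict MSI status from a fitted threshold tree
#'
#' Follows the unique root-to-leaf path for each sample (`value < cutoff`
#' goes left) and returns the leaf label.
#'
#' @param tree a [fit_threshold_tree()] object.
#' @param samples data.frame containing every feature the tree uses.
#' @return character vector of leaf labels.
#' @export
predict_ms_panel <- function(tree, samples) {
  stopifnot(inherits(tree, "ms_threshold_tree"))
  used <- tree_features_used(tree$root)
  miss <- setdiff(used, names(samples))
  if (length(miss)) {
    stop("sample table lacks feature(s) used by the tree: ", paste(miss, collapse = ", "))
  }
  vapply(seq_len(nrow(samples)), function(i) {
    node <- tree$root
    while (!node$leaf) {
      v <- as.numeric(samples[[node$feature]][i])
      if (is.na(v)) stop("missing value for feature '", node$feature, "'")
      node <- if (v < node$cutoff) node$left else node$right
    }
    node$label
  }, character(1))
}

tree_features_used <- function(node) {
  if (node$leaf) return(character(0))
  unique(c(node$feature, tree_features_used(node$left), tree_features_used(node$right)))
}

#' @export
print.ms_threshold_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "leaf: ", node$label, " (n=", node$n, ")\n", sep = "")
    } else {
      cat(pad, node$feature, " < ", format(node$cutoff, digits = 4),
        "  [p=", format(node$p_value, digits = 3), "]\n", sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  cat("<ms_threshold_tree> classes:", paste(x$classes, collapse = "/"), "\n")
  show(x$root, 0)
  invisible(x)
}
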