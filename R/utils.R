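#' Default analysis configuration
#'
#' Thresholds shared across the package. Values mirror the conventions of the
#' motivating colorectal-cancer study: tumors with TMB in \[16, 100\]
#' mutations/Mb are grouped with known-MSI tumors (MT-H), TMB > 100 marks
#' hypermutated MSS (MSS-htmb, POLE-like), and published MSI-score cutoffs
#' (MSIsensor 3.5, MANTIS 0.4) are honored. The global significance threshold
#' is 0.005 (a tenfold-lowered 0.05, compensating for many parallel tests).
#'
#' @param ... named overrides for any default entry.
#' @return Named list of configuration values:
#' \describe{
#'   \item{tmb_low}{TMB below which a tumor is MT-L (mutations/Mb, 16).}
#'   \item{tmb_htmb}{TMB above which a tumor is MSS-htmb (100).}
#'   \item{sensor, mantis}{MSIsensor / MANTIS score cutoffs (3.5, 0.4).}
#'   \item{alpha}{tree-growing significance for [fit_threshold_tree()] (0.001).}
#'   \item{significance}{global significance threshold (0.005).}
#'   \item{known_status_wins}{if TRUE a known MS status overrides TMB-based
#'     imputation (except TMB > 100, which always wins).}
#'   \item{lpa_cutoff, abundance_cutoff}{functional-score cutoffs below which a
#'     substitution is loss of function (on the 0-1 score scale shipped with
#'     the synthetic tables; override for other score sets).}
#'   \item{indel_impact_cutoff}{inframe-indel impact score at or above which the
#'     indel is loss of function (0.5).}
#'   \item{na_action}{"exclude" (default) drops unscored substitutions from
#'     damage fractions; "wt" counts them as functionally wild type.}
#'   \item{min_expected}{minimum expected count per channel before pooling in
#'     chi-square-form comparisons (5).}
#' }
#' @export
#' @examples
#' cfg <- somselect_config(tmb_low = 20)
#' cfg$tmb_low
somselect_config <- function(...) {
  cfg <- list(
    tmb_low = 16,
    tmb_htmb = 100,
    sensor = 3.5,
    mantis = 0.4,
    alpha = 0.001,
    significance = 0.005,
    known_status_wins = TRUE,
    lpa_cutoff = 0.5,
    abundance_cutoff = 0.5,
    indel_impact_cutoff = 0.5,
    na_action = "exclude",
    min_expected = 5
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown config entries: ", paste(unknown, collapse = ", "))
    }
    cfg <- modifyList(cfg, overrides)
  }
  cfg
}

#' Read a configuration file
#'
#' YAML configuration with a `thresholds:` block (entries as in
#' [somselect_config()]) and an optional `columns:` block remapping input
#' table columns to canonical names.
#'
#' @param path path to a YAML file.
#' @return list with elements `thresholds` (merged into the defaults) and
#'   `columns` (possibly empty list).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  thresholds <- do.call(somselect_config, as.list(raw$thresholds %||% list()))
  list(thresholds = thresholds, columns = as.list(raw$columns %||% list()))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' wilson_ci(10, 100)
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

# Pool channels whose expected count falls below `min_expected` into a single
# residual bin (a shared rule for all chi-square-form comparisons).  Channels
# are kept if n * p >= min_expected; the rest are merged.  If the residual bin
# itself stays below min_expected it is merged with the smallest kept channel.
# With fewer than 2 bins after pooling, pooling is abandoned and the raw
# channels are used (the Monte-Carlo reference remains valid regardless).
pool_channels <- function(observed, p, n, min_expected = 5) {
  stopifnot(length(observed) == length(p))
  expected <- n * p
  keep <- expected >= min_expected
  if (all(keep) || sum(keep) < 1) {
    return(list(observed = observed, p = p, pooled = sum(!keep)))
  }
  obs_k <- observed[keep]
  p_k <- p[keep]
  obs_pool <- sum(observed[!keep])
  p_pool <- sum(p[!keep])
  if (n * p_pool < min_expected && length(p_k) > 1) {
    i <- which.min(p_k)
    p_k[i] <- p_k[i] + p_pool
    obs_k[i] <- obs_k[i] + obs_pool
    list(observed = obs_k, p = p_k, pooled = sum(!keep))
  } else {
    list(
      observed = c(obs_k, pooled = obs_pool),
      p = c(p_k, pooled = p_pool),
      pooled = sum(!keep)
    )
  }
}

# Pearson chi-square-form distance of observed counts vs expected proportions.
pearson_stat <- function(observed, p, n = sum(observed)) {
  e <- n * p
  sum((observed - e)^2 / e)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

reverse_complement <- function(x) {
  vapply(x, function(s) {
    complement_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
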