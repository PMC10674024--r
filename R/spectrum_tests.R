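#' Monte-Carlo chi-square comparison of observed vs expected spectra
#'
#' A Pearson chi-square-form statistic on observed channel counts against
#' expected proportions, with the p-value obtained by multinomial Monte-Carlo
#' resampling under the expected proportions rather than the asymptotic
#' reference distribution. Channels whose expected count falls below
#' `min_expected` are pooled into a residual bin before the statistic is
#' computed (the same pooling is applied to every replicate).
#'
#' @param observed named or plain numeric vector of observed channel counts.
#' @param expected expected proportions (same length/order as `observed`), or
#'   a [site_mutability()] profile, in which case the expected 96-channel
#'   proportions are aggregated from it and `observed` must be named by
#'   channel.
#' @param n_mc Monte-Carlo replicates (>= 999).
#' @param seed optional RNG seed for reproducibility.
#' @param min_expected pooling threshold on expected counts (default from
#'   [somselect_config()]).
#' @return object of class `spectrum_test`: list with `statistic`, `p_value`
#'   (add-one corrected: `(1 + #{sim >= obs}) / (n_mc + 1)`), `n_mc`,
#'   `n_pooled` (channels merged into the residual bin), `channels` (the
#'   pooled observed/expected table) and `method`.
#' @export
#' @examples
#' obs <- c(40, 12, 28, 5, 10, 5) * 3
#' res <- spectrum_compare(obs, c(0.4, 0.12, 0.28, 0.05, 0.1, 0.05),
#'   n_mc = 999, seed = 1
#' )
#' res$p_value
spectrum_compare <- function(observed, expected, n_mc = 9999, seed = NULL,
                             min_expected = somselect_config()$min_expected) {
  if (n_mc < 999) stop("n_mc must be at least 999")
  if (inherits(expected, "mutability_profile")) {
    chan <- rowsum(expected$sites$p, expected$sites$channel)
    expected_p <- setNames(chan[, 1], rownames(chan))
    if (is.null(names(observed))) {
      stop("observed must be named by channel when expected is a profile")
    }
    missing_ch <- setdiff(names(observed), names(expected_p))
    if (length(missing_ch)) {
      stop("observed channel(s) absent from profile: ", paste(head(missing_ch, 3), collapse = ", "))
    }
    full <- setNames(numeric(length(expected_p)), names(expected_p))
    full[names(observed)] <- observed
    observed <- full
    expected <- expected_p
  }
  stopifnot(length(observed) == length(expected))
  if (any(expected < 0)) stop("expected proportions must be non-negative")
  n <- sum(observed)
  if (n == 0) stop("total observed count is zero")
  p <- expected / sum(expected)
  pooled <- pool_channels(observed, p, n, min_expected = min_expected)
  if (any(pooled$p <= 0)) {
    stop("expected proportions must be strictly positive after pooling")
  }
  obs_stat <- pearson_stat(pooled$observed, pooled$p, n)
  if (!is.null(seed)) set.seed(seed)
  sims <- rmultinom(n_mc, size = n, prob = pooled$p)
  e <- n * pooled$p
  sim_stats <- colSums((sims - e)^2 / e)
  structure(
    list(
      statistic = obs_stat,
      p_value = (1 + sum(sim_stats >= obs_stat)) / (n_mc + 1),
      n_mc = n_mc,
      n_pooled = pooled$pooled,
      channels = data.frame(
        channel = if (is.null(names(pooled$observed))) {
          seq_along(pooled$observed)
        } else {
          names(pooled$observed)
        },
        observed = as.numeric(pooled$observed),
        expected = e
      ),
      method = "Pearson statistic, multinomial Monte-Carlo p-value, small-expectation pooling"
    ),
    class = "spectrum_test"
  )
}

#' @export
print.spectrum_test <- function(x, ...) {
  cat(
    "<spectrum_test> X2 = ", format(x$statistic, digits = 4),
    ", p = ", format(x$p_value, digits = 4),
    " (", x$n_mc, " MC replicates, ", x$n_pooled, " channels pooled)\n",
    sep = ""
  )
  invisible(x)
}

#' Deviation of observed synonymous mutations from the background model
#'
#' Synonymous changes are not expected to alter protein function, so their
#' placement probes DNA-level mutational processes beyond the signature
#' model. The test simulates synthetic synonymous per-codon count vectors by
#' multinomial draws from the profile's synonymous mass (same total as
#' observed), computes a chi-square-form distance to expectation for each,
#' and reports the fraction of replicates at least as extreme as the data.
#'
#' @param observed integer vector of observed synonymous counts per codon
#'   (length = profile codon count).
#' @param profile a [site_mutability()] profile.
#' @param n_sims simulated models (>= 999).
#' @param seed optional RNG seed.
#' @return list with `p_value` (add-one corrected), `observed_metric`,
#'   `replicate_metrics` (length `n_sims`), `n_sims`.
#' @export
synonymous_deviation_test <- function(observed, profile, n_sims = 999, seed = NULL) {
  stopifnot(inherits(profile, "mutability_profile"))
  if (n_sims < 999) stop("n_sims must be at least 999")
  cp <- codon_profile(profile)
  if (length(observed) != nrow(cp)) {
    stop("observed must have one entry per codon (", nrow(cp), ")")
  }
  syn_mass <- sum(cp$p_syn)
  if (syn_mass <= 0) stop("profile carries zero synonymous mass")
  p <- cp$p_syn / syn_mass
  if (any(observed[p == 0] > 0)) {
    stop("observed synonymous events at codon(s) with zero synonymous mass: ",
      paste(head(which(p == 0 & observed > 0), 3), collapse = ", "))
  }
  n <- sum(observed)
  if (n == 0) stop("no observed synonymous events")
  live <- p > 0
  e <- n * p[live]
  metric <- function(counts) sum((counts - e)^2 / e)
  obs_metric <- metric(observed[live])
  if (!is.null(seed)) set.seed(seed)
  sims <- rmultinom(n_sims, size = n, prob = p[live])
  rep_metrics <- colSums((sims - e)^2 / e)
  list(
    p_value = (1 + sum(rep_metrics >= obs_metric)) / (n_sims + 1),
    observed_metric = obs_metric,
    replicate_metrics = rep_metrics,
    n_sims = n_sims
  )
}
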