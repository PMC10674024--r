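#' Estimate dN/dS against the signature background
#'
#' The selection ratio for a mutation class is the observed
#' nonsynonymous-to-synonymous count ratio divided by the ratio expected
#' under the mutability profile:
#' \deqn{\omega = (N_{obs}/S_{obs}) / (N_{exp}/S_{exp})}
#' where the expected ratio is the profile's class mass over its synonymous
#' mass, so the spectrum's nucleotide preferences are normalized out. The
#' 95% CI is the exact conditional interval: given the total `N + S`, `N` is
#' binomial with success probability `w E/(1 + w E)` (`E` the expected
#' ratio), so a Clopper-Pearson interval for that probability transforms
#' into a slightly conservative interval for `w` that behaves well at small
#' counts.
#'
#' Class definitions: `non-truncating` counts missense SNVs; `truncating`
#' counts nonsense SNVs. When the profile carries no indel mass (the
#' default), frameshift records cannot be benchmarked and are excluded with
#' a message.
#'
#' @param mutations mutation records for one gene.
#' @param profile a [site_mutability()] profile for that gene.
#' @param class `"truncating"` or `"non-truncating"`.
#' @return object of class `dnds_result`: `omega`, `ci_low`, `ci_high`,
#'   `class`, `n_obs_nonsyn`, `n_obs_syn`, `expected_ratio`, and
#'   `unbounded_ci` flag (TRUE when no synonymous mutations were observed).
#' @export
#' @examples
#' # 50 class events vs 10 synonymous with expected N/S of 5 gives omega 1
estimate_dnds <- function(mutations, profile,
                          class = c("truncating", "non-truncating")) {
  class <- match.arg(class)
  stopifnot(inherits(profile, "mutability_profile"))
  cp <- codon_profile(profile)
  s_exp <- sum(cp$p_syn)
  n_exp <- if (class == "truncating") sum(cp$p_truncating) else sum(cp$p_missense)
  if (n_exp <= 0) stop("profile carries zero mass for class ", class)
  if (s_exp <= 0) stop("profile carries zero synonymous mass")

  vc <- mutations$variant_class
  s_obs <- sum(vc == "synonymous")
  if (class == "truncating") {
    n_fs <- sum(vc == "frameshift")
    if (n_fs > 0) {
      message(
        n_fs, " frameshift record(s) excluded: profile has no indel mass, ",
        "truncating dN/dS computed on nonsense substitutions only"
      )
    }
    n_obs <- sum(vc == "nonsense")
  } else {
    n_obs <- sum(vc == "missense")
  }

  expected_ratio <- n_exp / s_exp
  if (s_obs == 0) {
    omega <- NA_real_
    ci <- c(NA_real_, NA_real_)
    unbounded <- TRUE
  } else {
    omega <- (n_obs / s_obs) / expected_ratio
    q_ci <- binom.test(n_obs, n_obs + s_obs)$conf.int
    ci <- (q_ci / (1 - q_ci)) / expected_ratio
    unbounded <- FALSE
  }
  structure(
    list(
      omega = omega, ci_low = ci[1], ci_high = ci[2], class = class,
      n_obs_nonsyn = n_obs, n_obs_syn = s_obs,
      expected_ratio = expected_ratio, unbounded_ci = unbounded
    ),
    class = "dnds_result"
  )
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(
    "<dnds_result> ", x$class, ": omega = ", format(x$omega, digits = 4),
    " [", format(x$ci_low, digits = 4), ", ", format(x$ci_high, digits = 4),
    "]  (N=", x$n_obs_nonsyn, ", S=", x$n_obs_syn, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Convert a selection ratio to a driver fraction
#'
#' Under positive selection at ratio `omega`, the excess `(omega - 1)/omega`
#' of observed class mutations cannot be explained by the background process
#' and is attributed to driver selection; floored at 0.
#'
#' @param omega selection ratio (> 0).
#' @return fraction in \[0, 1).
#' @export
#' @examples
#' driver_fraction(2) # 0.5
driver_fraction <- function(omega) {
  stopifnot(all(omega > 0))
  pmax(0, (omega - 1) / omega)
}
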