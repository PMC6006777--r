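#' Analytic power of the single-CpG association test
#'
#' Power of the two-sided test that one CpG's methylation predicts a
#' transcript's expression, when the CpG explains a fraction `r2` of the
#' expression variance. The test statistic is modelled as noncentral
#' F(1, n - 2) with noncentrality `n * r2 / (1 - r2)`; the critical value is
#' the upper `alpha` quantile of the central F(1, n - 2). Covariates are not
#' counted in the degrees of freedom, so this is the power of the plain
#' single-predictor regression.
#'
#' @param n Number of samples (> 3).
#' @param alpha Two-sided significance level, in (0, 1).
#' @param r2 Fraction of expression variance explained by the CpG, in \[0, 1).
#' @return Power as a probability. At `r2 = 0` this is exactly `alpha`
#'   (the size of the test).
#' @examples
#' power_of_r2(333, 1e-11, 0.16)
#' @seealso [min_r2_detectable()], [bonferroni_alpha()]
#' @export
power_of_r2 <- function(n, alpha, r2) {
  stopifnot(n > 3, alpha > 0, alpha < 1, r2 >= 0, r2 < 1)
  crit <- qf(alpha, 1, n - 2, lower.tail = FALSE)
  suppressWarnings(
    pf(crit, 1, n - 2, ncp = n * r2 / (1 - r2), lower.tail = FALSE)
  )
}

#' Smallest detectable variance-explained fraction
#'
#' Finds by bisection the smallest `r2` at which [power_of_r2()] reaches the
#' target power. With `n = 333` and `alpha = 1e-11` the 80%-power threshold is
#' about 0.16; with `n = 1202` about 0.047 -- the detectability floors of a
#' small whole-blood cohort versus a large monocyte cohort at the genome-wide
#' significance level used by the scan.
#'
#' @inheritParams power_of_r2
#' @param power Target power, in (0, 1).
#' @param tol Bisection tolerance on `r2` (default 1e-6).
#' @return The minimal `r2` (fraction, not percent).
#' @examples
#' min_r2_detectable(1202, 1e-11, 0.8)
#' @export
min_r2_detectable <- function(n, alpha, power, tol = 1e-6) {
  stopifnot(n > 3, alpha > 0, alpha < 1, power > 0, power < 1)
  hi <- 1 - 1e-9
  if (power_of_r2(n, alpha, hi) < power) {
    abort("target power is unreachable at this sample size and alpha")
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (power_of_r2(n, alpha, mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Bonferroni-adjusted per-test significance level
#'
#' `fwer / n_tests`: the per-test alpha controlling the family-wise error rate
#' across `n_tests` independent tests. Five billion tests at FWER 0.05 give
#' the 1e-11 genome-wide threshold used to call eCpGs significant.
#'
#' @param n_tests Number of tests (>= 1).
#' @param fwer Family-wise error rate to control.
#' @return The per-test significance level.
#' @examples
#' bonferroni_alpha(5e9, 0.05)
#' @export
bonferroni_alpha <- function(n_tests, fwer = 0.05) {
  stopifnot(n_tests >= 1, fwer > 0, fwer < 1)
  fwer / n_tests
}

#' Array dimensions of the two reference blood-cell cohorts
#'
#' Probe counts and sample sizes for the two cohorts the scan design is
#' calibrated against: GTP (whole blood, Infinium 450K methylation +
#' HT-12 expression arrays) and MESA (purified monocytes, same platforms).
#' The product of the probe counts is the number of CpG-transcript
#' comparisons an all-pairs scan performs in each cohort.
#'
#' @return A tibble with columns `study`, `n_samples`, `n_cpg_probes`,
#'   `n_transcript_probes` and `n_comparisons`.
#' @examples
#' study_dimensions()
#' @export
study_dimensions <- function() {
  out <- tibble(
    study = c("GTP", "MESA"),
    n_samples = c(333L, 1202L),
    n_cpg_probes = c(472199L, 422016L),
    n_transcript_probes = c(13933L, 19445L)
  )
  mutate(out, n_comparisons = .data$n_cpg_probes * as.double(.data$n_transcript_probes))
}
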