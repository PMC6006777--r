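#' Simulate a methylation + expression cohort over a toy genome
#'
#' Draws a cohort with the statistical structure the association scan
#' assumes. Methylation beta values follow the bimodal landscape of real
#' arrays: a fraction `bimodal_fraction` of CpGs is assigned a fully
#' methylated or unmethylated mode (Beta(10, 0.5) / Beta(0.5, 10), mode
#' chosen with probability 1/2 per CpG) and the rest are intermediately
#' methylated (Beta(5, 5)). Log expression for the transcript of each gene is
#' intercept + small age/sex effects (on a random 10% of transcripts) +
#' latent confounder loadings + planted CpG effects + Gaussian noise.
#'
#' Latent confounders emulate cellular heterogeneity: each sample gets
#' standard-normal loadings on `n_confounders` factors, which perturb every
#' transcript (weights `N(0, 1)`, scale `confounder_scale_expr`) and every
#' CpG on the logit scale (scale `confounder_scale_meth`), so that
#' methylation and expression share intersample structure -- the situation
#' the intersample-correlation correction exists for. Set
#' `confounder_scale_meth = 0` for confounding that touches expression only.
#'
#' Planted effects are calibrated so the CpG explains the requested fraction
#' of the transcript's variance: the effect size is
#' `sign * sqrt(v / (1 - v)) * sd(baseline) / sd(beta)` computed from the
#' realized baseline (covariates + confounders + noise) and realized beta
#' column, giving a realized variance explained within Monte-Carlo error of
#' the request.
#'
#' @param genome A `toy_genome` from [generate_genome()]; each gene
#'   contributes one transcript (`tx_<gene_id>`).
#' @param n_samples Cohort size.
#' @param n_confounders Number of latent factors (0 for a clean cohort).
#' @param planted Ground-truth effects: data frame with columns `cpg_id`,
#'   `transcript_id`, `variance_explained` (in \[0, 1)) and `sign`
#'   (`"+"`/`"-"`), or `NULL`.
#' @param bimodal_fraction Fraction of CpGs drawn from the extreme modes.
#' @param seed Integer seed; required, all randomness flows through it.
#' @param confounder_scale_expr,confounder_scale_meth Scales of the
#'   confounder contributions to expression (log units) and methylation
#'   (logit units).
#' @param noise_sd Residual sd of log expression.
#' @return An `ecpg_cohort`: list with `methylation` (samples x CpGs),
#'   `expression` (transcripts x samples), `covariates` (tibble:
#'   `sample_id`, `age`, `sex`), `confounder_loadings` (samples x K) and
#'   `truth` (tibble: `cpg_id`, `transcript_id`, `effect_size`,
#'   `variance_explained`, `sign`).
#' @examples
#' genome <- generate_genome(2, 3, 1, seed = 1)
#' cohort <- generate_cohort(genome, n_samples = 50, n_confounders = 0, seed = 1)
#' @export
generate_cohort <- function(genome, n_samples, n_confounders = 0, planted = NULL,
                            bimodal_fraction = 0.8, seed,
                            confounder_scale_expr = 0.5,
                            confounder_scale_meth = 0.5,
                            noise_sd = 1) {
  stopifnot(inherits(genome, "toy_genome"), n_samples >= 2, n_confounders >= 0)
  if (missing(seed)) abort("seed is required")
  withr::local_seed(seed)

  cpg_ids <- genome$cpgs$cpg_id
  tx_ids <- paste0("tx_", genome$genes$gene_id)
  p <- length(cpg_ids)
  m <- length(tx_ids)
  n <- n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  planted <- .check_planted(planted, cpg_ids, tx_ids)

  covariates <- tibble(
    sample_id = sample_ids,
    age = runif(n, 18, 78),
    sex = rbinom(n, 1, 0.5)
  )

  # methylation: per-CpG mode, then per-sample Beta draws
  kind <- sample(c("bimodal", "intermediate"), p, replace = TRUE,
                 prob = c(bimodal_fraction, 1 - bimodal_fraction))
  mode_hi <- runif(p) < 0.5
  shape1 <- ifelse(kind == "bimodal", ifelse(mode_hi, 10, 0.5), 5)
  shape2 <- ifelse(kind == "bimodal", ifelse(mode_hi, 0.5, 10), 5)
  meth <- matrix(rbeta(n * p, rep(shape1, each = n), rep(shape2, each = n)),
                 nrow = n, ncol = p, dimnames = list(sample_ids, cpg_ids))

  loadings <- matrix(0, n, 0)
  if (n_confounders > 0) {
    loadings <- matrix(rnorm(n * n_confounders), n, n_confounders,
                       dimnames = list(sample_ids, paste0("cf", seq_len(n_confounders))))
    if (confounder_scale_meth > 0) {
      w_meth <- matrix(rnorm(n_confounders * p), n_confounders, p)
      shift <- loadings %*% w_meth * confounder_scale_meth
      meth <- plogis(qlogis(pmin(pmax(meth, 1e-6), 1 - 1e-6)) + shift)
    }
  }

  # expression baseline: intercept + covariates + confounders + noise
  mu <- rnorm(m, 7, 1)
  age_coef <- sex_coef <- numeric(m)
  affected <- sample.int(m, size = max(0L, round(0.1 * m)))
  age_coef[affected] <- rnorm(length(affected), 0, 0.005)
  sex_coef[affected] <- rnorm(length(affected), 0, 0.25)
  expr <- matrix(rnorm(m * n, 0, noise_sd), m, n,
                 dimnames = list(tx_ids, sample_ids))
  expr <- expr + mu +
    outer(age_coef, covariates$age - mean(covariates$age)) +
    outer(sex_coef, covariates$sex - mean(covariates$sex))
  if (n_confounders > 0) {
    w_expr <- matrix(rnorm(m * n_confounders), m, n_confounders)
    expr <- expr + confounder_scale_expr * tcrossprod(w_expr, loadings)
  }

  truth <- tibble(
    cpg_id = character(0), transcript_id = character(0),
    effect_size = numeric(0), variance_explained = numeric(0), sign = character(0)
  )
  if (nrow(planted) > 0) {
    effects <- pmap(planted, function(cpg_id, transcript_id, variance_explained, sign) {
      beta <- meth[, cpg_id]
      base <- expr[transcript_id, ]
      a <- (if (sign == "-") -1 else 1) *
        sqrt(variance_explained / (1 - variance_explained)) * sd(base) / sd(beta)
      expr[transcript_id, ] <<- base + a * beta
      a
    })
    truth <- mutate(planted, effect_size = unlist(effects)) %>%
      select("cpg_id", "transcript_id", "effect_size", "variance_explained", "sign")
  }

  structure(
    list(
      methylation = meth, expression = expr, covariates = covariates,
      confounder_loadings = loadings, truth = truth
    ),
    class = "ecpg_cohort"
  )
}

.check_planted <- function(planted, cpg_ids, tx_ids) {
  if (is.null(planted) || nrow(as.data.frame(planted)) == 0) {
    return(tibble(cpg_id = character(0), transcript_id = character(0),
                  variance_explained = numeric(0), sign = character(0)))
  }
  planted <- as_tibble(planted)
  stopifnot(all(c("cpg_id", "transcript_id", "variance_explained", "sign") %in% names(planted)))
  if (any(planted$variance_explained < 0 | planted$variance_explained >= 1)) {
    abort("variance_explained must lie in [0, 1)")
  }
  missing_cpg <- setdiff(planted$cpg_id, cpg_ids)
  missing_tx <- setdiff(planted$transcript_id, tx_ids)
  if (length(missing_cpg) || length(missing_tx)) {
    abort(sprintf(
      "planted targets absent from genome (cpgs: %s; transcripts: %s)",
      paste(missing_cpg, collapse = ","), paste(missing_tx, collapse = ",")
    ))
  }
  if (!all(planted$sign %in% c("+", "-"))) abort('sign must be "+" or "-"')
  planted
}

#' @export
print.ecpg_cohort <- function(x, ...) {
  cat(sprintf(
    "<ecpg_cohort> %d samples, %d CpGs, %d transcripts, %d confounder(s), %d planted effect(s)\n",
    nrow(x$methylation), ncol(x$methylation), nrow(x$expression),
    ncol(x$confounder_loadings), nrow(x$truth)
  ))
  invisible(x)
}

#' Scan a simulated cohort
#'
#' Convenience wrapper running [ecpg_scan()] on the matrices of an
#' `ecpg_cohort` with its age/sex covariates.
#'
#' @param cohort An `ecpg_cohort`.
#' @param ... Passed to [ecpg_scan()].
#' @return An `ecpg_scan` tibble.
#' @export
scan_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "ecpg_cohort"))
  ecpg_scan(cohort$methylation, cohort$expression, cohort$covariates, ...)
}
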