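#' Scan all CpG-transcript pairs for methylation-expression association
#'
#' Runs the mixed-model association of every CpG against every transcript.
#' The intersample correlation matrix H is estimated once from the expression
#' matrix and its eigendecomposition is shared by all fits. For each
#' transcript the variance-component ratio delta is estimated by profile
#' maximum likelihood under the covariates-only model, then every CpG is
#' tested by generalized least squares with those weights (the classic
#' two-step that makes an all-pairs scan tractable; the single-pair
#' [fit_lmm()] interface re-profiles delta with the CpG included and agrees
#' closely). Samples are aligned across the three inputs by sample id, never
#' by position.
#'
#' @param meth Methylation matrix, samples x CpGs, beta values in \[0, 1\],
#'   with sample ids as rownames and CpG ids as colnames.
#' @param expr Expression matrix, transcripts x samples (log scale), with
#'   transcript ids as rownames and sample ids as colnames.
#' @param covars Data frame of per-sample covariates with a `sample_id`
#'   column; all other columns are used as numeric fixed effects. `NULL`
#'   fits an intercept-only fixed part.
#' @param alpha_suggestive,alpha_significant P-value cutoffs for the
#'   `suggestive` and `significant` tiers (strict `<`).
#' @param method `"lmm"` (default) for the confounder-corrected model or
#'   `"ols"` for the uncorrected per-pair regression (equivalent to `H = I`).
#' @param loo Leave the focal transcript out of H when testing it (default
#'   TRUE). A transcript has zero residual in the null space of a correlation
#'   matrix it helped estimate, which biases its own fits; the leave-one-out
#'   form is computed as an exact rank-one downdate of the global
#'   eigendecomposition, so no per-transcript eigendecomposition is needed.
#' @return A tibble of class `ecpg_scan`, one row per (CpG, transcript) pair,
#'   ordered by transcript then CpG id, with columns `transcript_id`,
#'   `cpg_id`, `effect`, `se`, `T`, `p`, `tier`, and attributes `gif`
#'   (per-transcript genomic inflation factors), `delta` (per-transcript
#'   variance-ratio estimates) and `thresholds`.
#' @seealso [compute_gif()], [filter_gif()], [fit_lmm()]
#' @export
ecpg_scan <- function(meth, expr, covars = NULL,
                      alpha_suggestive = .default_alpha_suggestive,
                      alpha_significant = .default_alpha_significant,
                      method = c("lmm", "ols"), loo = TRUE) {
  method <- arg_match(method)
  stopifnot(is.matrix(meth), is.matrix(expr))
  if (min(meth) < 0 || max(meth) > 1) abort("methylation beta values must lie in [0, 1]")
  samples <- .align_samples(rownames(meth), colnames(expr), covars)
  meth <- meth[samples, , drop = FALSE]
  expr <- expr[, samples, drop = FALSE]
  n <- length(samples)
  if (n < 10) abort("need at least 10 samples")

  X <- .build_design(covars, samples)
  Z <- standardize_expression(expr)
  dropped <- attr(Z, "excluded")
  if (nrow(Z) < 2) abort("fewer than two transcripts with variance; cannot estimate H")

  if (method == "lmm") {
    H <- estimate_intersample_correlation(Z)
    U <- H$vectors[, H$support, drop = FALSE]
    S <- H$values[H$support]
  } else {
    U <- diag(n)
    S <- rep(1, n)
  }
  r_dim <- length(S)

  # rotate once: the per-transcript loop then works in the diagonal frame
  Mr <- crossprod(U, meth)              # r x p
  Xr <- crossprod(U, X)                 # r x c
  keep_x <- colSums(Xr^2) > 1e-12 * colSums(X^2)
  Xr <- Xr[, keep_x, drop = FALSE]
  Yr <- expr[setdiff(rownames(expr), dropped), , drop = FALSE] %*% U # m x r

  tx_ids <- sort(rownames(Yr))
  cpg_ids <- colnames(meth)
  ord_cpg <- order(cpg_ids)
  Mr <- Mr[, ord_cpg, drop = FALSE]
  cpg_ids <- cpg_ids[ord_cpg]
  q <- ncol(Xr) + 1L
  df <- r_dim - q
  if (df < 1) abort("not enough informative dimensions in H for the design")

  # leave-one-transcript-out H, as a rank-1 downdate in the rotated frame:
  # H_k = (m H - z_k' z_k) / (m - 1). Excluding the focal transcript from H
  # removes the self-inclusion artifact (a transcript has zero residual in
  # the null space of a matrix it helped build), which otherwise attenuates
  # its own test statistics.
  loo <- loo && method == "lmm"
  if (loo) {
    m_eff <- nrow(Z)
    Zr <- Z %*% U
  }

  fits <- map(tx_ids, function(tx) {
    yr <- Yr[tx, ]
    if (loo) {
      zh <- Zr[tx, ]
      cc <- 1 / (m_eff - 1)
      d_base <- S * m_eff / (m_eff - 1)
      # leverage of transcript k in the Gram matrix; 1 means z_k is linearly
      # independent of the other transcripts, so H_k has a null direction
      # v ~ D^-1 z inside the global support that must be projected out
      # (it is the focal transcript's own residual direction)
      lev <- sum(zh^2 / S) / m_eff
      n_eff <- r_dim
      yp <- yr; Xp <- Xr; Mp <- Mr
      project_v <- lev > 1 - 1e-6
      if (project_v) {
        v <- zh / S
        v <- v / sqrt(sum(v^2))
        yp <- yr - v * sum(v * yr)
        Xp <- Xr - v %o% drop(crossprod(v, Xr))
        Mp <- Mr - v %o% drop(crossprod(v, Mr))
        n_eff <- r_dim - 1L
      }
      solve_sigma <- function(x, d) {
        xd <- x / d
        zd <- zh / d
        denom <- max(1 - cc * sum(zh * zd), 1e-12)
        num <- crossprod(zh, xd)
        xd + zd %o% drop(cc * num / denom)
      }
      loglik <- function(delta) {
        d <- d_base + delta
        Xi <- solve_sigma(Xp, d)
        yi <- drop(solve_sigma(cbind(yp), d))
        G <- crossprod(Xp, Xi)
        bx <- tryCatch(solve(G, crossprod(Xp, yi)), error = function(e) NULL)
        if (is.null(bx)) return(-Inf)
        rss <- sum(yp * yi) - sum(crossprod(Xp, yi) * bx)
        if (rss <= 0) return(Inf)
        logdet <- sum(log(d)) + log(max(1 - cc * sum(zh^2 / d), 1e-300))
        if (project_v) logdet <- logdet - log(delta)
        -0.5 * (n_eff * log(2 * pi * rss / n_eff) + logdet + n_eff)
      }
      grid <- 10^seq(-5, 5, length.out = 100)
      ll <- vapply(grid, loglik, numeric(1))
      i <- which.max(ll)
      opt <- optimize(function(ld) loglik(10^ld),
                      interval = log10(grid[c(max(i - 1L, 1L), min(i + 1L, length(grid)))]),
                      maximum = TRUE, tol = 1e-6)
      delta <- if (opt$objective >= ll[i]) 10^opt$maximum else grid[i]
      d <- d_base + delta
      Xi <- solve_sigma(Xp, d)
      yi <- drop(solve_sigma(cbind(yp), d))
      Mi <- solve_sigma(Mp, d)
      G <- crossprod(Xp, Xi)
      Gi_Xy <- solve(G, crossprod(Xp, yi))
      Gi_XM <- solve(G, crossprod(Xp, Mi))
      s_yy <- sum(yp * yi) - sum(crossprod(Xp, yi) * Gi_Xy)
      s_my <- drop(crossprod(Mp, yi)) - drop(crossprod(crossprod(Xp, yi), Gi_XM))
      s_mm <- colSums(Mp * Mi) - colSums(crossprod(Xp, Mi) * Gi_XM)
      ok <- s_mm > 1e-12 * max(s_mm, 1e-300)
      a <- ifelse(ok, s_my / s_mm, NA_real_)
      rss <- pmax(s_yy - a^2 * s_mm, 0)
      df_t <- n_eff - q
    } else {
      df_t <- df
      if (method == "lmm") {
        delta <- .optimize_delta(yr, Xr, S)$delta
      } else {
        delta <- 0
      }
      sw <- sqrt(1 / (S + delta))
      qrX <- qr(Xr * sw)
      ry <- qr.resid(qrX, yr * sw)
      RM <- qr.resid(qrX, Mr * sw)
      s_mm <- colSums(RM^2)
      s_my <- colSums(RM * ry)
      ok <- s_mm > 1e-12 * max(s_mm, 1e-300)
      a <- ifelse(ok, s_my / s_mm, NA_real_)
      rss <- pmax(sum(ry^2) - a^2 * s_mm, 0)
    }
    se <- ifelse(ok, sqrt(rss / df_t / s_mm), NA_real_)
    Tstat <- ifelse(se > 0, a / se, ifelse(ok, sign(a) * Inf, NA_real_))
    p <- 2 * pt(-abs(Tstat), df = df_t)
    p[is.finite(a) & !is.finite(Tstat)] <- .Machine$double.xmin
    list(effect = a, se = se, T = Tstat, p = p, delta = delta)
  })
  names(fits) <- tx_ids

  records <- tibble(
    transcript_id = rep(tx_ids, each = length(cpg_ids)),
    cpg_id = rep(cpg_ids, times = length(tx_ids)),
    effect = unlist(map(fits, "effect"), use.names = FALSE),
    se = unlist(map(fits, "se"), use.names = FALSE),
    T = unlist(map(fits, "T"), use.names = FALSE),
    p = unlist(map(fits, "p"), use.names = FALSE)
  )
  records$tier <- significance_tier(records$p, alpha_suggestive, alpha_significant)

  gif <- compute_gif(records)
  structure(
    records,
    class = c("ecpg_scan", class(records)),
    gif = gif,
    delta = tibble(transcript_id = tx_ids, delta = map_dbl(fits, "delta")),
    thresholds = c(suggestive = alpha_suggestive, significant = alpha_significant),
    method = method,
    excluded_transcripts = dropped
  )
}

.align_samples <- function(meth_ids, expr_ids, covars) {
  if (is.null(meth_ids) || is.null(expr_ids)) {
    abort("methylation rownames and expression colnames must carry sample ids")
  }
  ids <- list(methylation = meth_ids, expression = expr_ids)
  if (!is.null(covars)) {
    if (!"sample_id" %in% names(covars)) abort("covariate table needs a sample_id column")
    ids$covariates <- as.character(covars$sample_id)
  }
  common <- Reduce(intersect, ids)
  offenders <- imap(ids, ~ setdiff(.x, common))
  offenders <- offenders[lengths(offenders) > 0]
  if (length(offenders) > 0) {
    msg <- paste(
      imap(offenders, ~ sprintf("%s-only: %s", .y, paste(head(.x, 5), collapse = ", "))),
      collapse = "; "
    )
    abort(paste0("sample ids do not match across inputs (", msg, ")"))
  }
  sort(common)
}

.build_design <- function(covars, samples) {
  if (is.null(covars)) {
    return(matrix(1, length(samples), 1, dimnames = list(samples, "(Intercept)")))
  }
  covars <- as.data.frame(covars)
  rownames(covars) <- covars$sample_id
  covars <- covars[samples, setdiff(names(covars), "sample_id"), drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(covars))
  if (qr(X)$rank < ncol(X)) abort("covariate design (with intercept) is rank deficient")
  X
}

#' Significance tier of a p-value
#'
#' @param p Numeric vector of p-values.
#' @param alpha_suggestive,alpha_significant Strict cutoffs for the tiers.
#' @return Factor with levels `none`, `suggestive`, `significant`.
#' @export
significance_tier <- function(p, alpha_suggestive = .default_alpha_suggestive,
                              alpha_significant = .default_alpha_significant) {
  tier <- ifelse(p < alpha_significant, "significant",
    ifelse(p < alpha_suggestive, "suggestive", "none")
  )
  factor(tier, levels = c("none", "suggestive", "significant"))
}

#' Per-transcript genomic inflation factor
#'
#' `median(T^2) / qchisq(0.5, 1)` over all CpGs tested against a transcript.
#' Under a well-calibrated null the squared Wald statistics have median equal
#' to the median of chi-square(1) (0.4549), so the GIF is ~1; transcripts
#' whose whole statistic distribution is inflated (GIF > 2) indicate residual
#' confounding and are removed before classification.
#'
#' @param records Scan records with `transcript_id` and `T` columns.
#' @param gif_max Pass/fail threshold (a transcript passes iff GIF <= gif_max).
#' @return Tibble with `transcript_id`, `gif`, `passed`, `n_pairs`.
#' @examples
#' compute_gif(tibble::tibble(transcript_id = "t1", T = c(0.5, -0.7, 1.0)))
#' @export
compute_gif <- function(records, gif_max = 2) {
  stopifnot(all(c("transcript_id", "T") %in% names(records)))
  records %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gif = median(.data$T^2, na.rm = TRUE) / qchisq(0.5, 1),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(passed = .data$gif <= gif_max) %>%
    select("transcript_id", "gif", "passed", "n_pairs")
}

#' Drop transcripts that fail the genomic inflation filter
#'
#' @param records Scan records (e.g. from [ecpg_scan()]).
#' @param gif_max Maximum tolerated GIF (default 2).
#' @return The records restricted to transcripts with GIF <= `gif_max`; the
#'   dropped transcript ids are kept in the `"removed_transcripts"` attribute.
#' @export
filter_gif <- function(records, gif_max = 2) {
  gif <- compute_gif(records, gif_max = gif_max)
  keep <- gif$transcript_id[gif$passed]
  out <- filter(as_tibble(records), .data$transcript_id %in% keep)
  attr(out, "removed_transcripts") <- setdiff(gif$transcript_id, keep)
  out
}

#' @rdname ecpg_scan
#' @param x An `ecpg_scan` result.
#' @param ... Unused.
#' @export
tidy.ecpg_scan <- function(x, ...) {
  as_tibble(unclass_scan(x))
}

#' @rdname ecpg_scan
#' @export
glance.ecpg_scan <- function(x, ...) {
  gif <- attr(x, "gif")
  tibble(
    n_pairs = nrow(x),
    n_transcripts = length(unique(x$transcript_id)),
    n_cpgs = length(unique(x$cpg_id)),
    n_suggestive = sum(x$tier != "none"),
    n_significant = sum(x$tier == "significant"),
    median_gif = median(gif$gif),
    n_gif_failed = sum(!gif$passed)
  )
}

unclass_scan <- function(x) {
  class(x) <- setdiff(class(x), "ecpg_scan")
  for (a in c("gif", "delta", "thresholds", "method", "excluded_transcripts")) {
    attr(x, a) <- NULL
  }
  x
}
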