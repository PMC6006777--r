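#' Row-standardize a log-expression matrix
#'
#' Centers and scales each transcript (row) to mean 0, sd 1 (sd with the n-1
#' denominator). Transcripts with zero variance cannot be standardized; they
#' are dropped with a warning, and their ids are recorded in the
#' `"excluded"` attribute of the result.
#'
#' @param Y Numeric matrix, transcripts x samples, with dimnames.
#' @return The standardized matrix Z (possibly with fewer rows).
#' @examples
#' Y <- rbind(tx1 = c(1, 2, 3), tx2 = c(5, 4, 6))
#' standardize_expression(Y)
#' @export
standardize_expression <- function(Y) {
  stopifnot(is.matrix(Y), is.numeric(Y))
  if (anyNA(Y)) abort("expression matrix contains missing values")
  mu <- rowMeans(Y)
  sds <- apply(Y, 1, sd)
  zero <- sds <= 0
  if (any(zero)) {
    warn(sprintf(
      "excluding %d zero-variance transcript(s): %s",
      sum(zero), paste(head(rownames(Y)[zero], 5), collapse = ", ")
    ))
  }
  Z <- (Y[!zero, , drop = FALSE] - mu[!zero]) / sds[!zero]
  attr(Z, "excluded") <- rownames(Y)[zero]
  Z
}

#' Intersample correlation matrix from standardized expression
#'
#' The n x n matrix `H = t(Z) %*% Z / m` summarizing how similar each pair of
#' samples is across all m standardized transcripts. Shared unmeasured
#' factors (cell-type composition, global expression shifts) show up as
#' off-diagonal structure in H; the mixed model uses H as the covariance of
#' its random confounder term. The eigendecomposition is computed here once
#' and reused by every fit. Eigenvalues are clamped from below at
#' `1e-6 * max(eigenvalue)` so that a rank-deficient H (more samples than
#' transcripts) stays invertible after adding the noise component.
#'
#' @param Z Standardized expression matrix (rows mean 0, sd 1), m x n.
#' @return An `intersample_correlation` object: list with elements `H`,
#'   `values` (clamped, descending), `values_raw`, `vectors`, `n`, `m`.
#' @examples
#' Z <- standardize_expression(matrix(rnorm(200), 20, 10))
#' H <- estimate_intersample_correlation(Z)
#' @export
estimate_intersample_correlation <- function(Z) {
  stopifnot(is.matrix(Z), nrow(Z) >= 2)
  n <- ncol(Z)
  m <- nrow(Z)
  if (n > m) {
    warn("more samples than transcripts: H is rank deficient; eigenvalues will be clamped")
  }
  H <- crossprod(Z) / m
  intersample_correlation(H, m = m)
}

#' Construct an intersample correlation object from a given matrix
#'
#' Low-level constructor used when H is supplied directly (e.g. the identity
#' for an uncorrected scan, or a known kinship-style matrix).
#'
#' @param H Symmetric n x n matrix.
#' @param m Number of transcripts H was estimated from (optional, for record).
#' @param clamp_frac Eigenvalue floor as a fraction of the largest eigenvalue.
#' @return An `intersample_correlation` object.
#' @export
intersample_correlation <- function(H, m = NA_integer_, clamp_frac = 1e-6) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  if (max(abs(H - t(H))) > 1e-10) abort("H must be symmetric (tolerance 1e-10)")
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  if (max(eig$values) <= 0) abort("H has no positive eigenvalue")
  if (min(eig$values) < -1e-8 * max(eig$values)) {
    warn("H has substantially negative eigenvalues; clamping")
  }
  eps <- clamp_frac * max(eig$values)
  structure(
    list(
      H = H,
      values = pmax(eig$values, eps),
      values_raw = eig$values,
      vectors = eig$vectors,
      # fits work on the positive eigenspace: directions where the estimated
      # H carries no signal (exact zeros when m < n, and the all-ones
      # direction, which row standardization always annihilates) contribute
      # artifacts rather than information, because every transcript used to
      # build H has zero residual there by construction
      support = eig$values > eps,
      n = nrow(H),
      m = m
    ),
    class = "intersample_correlation"
  )
}

#' @export
print.intersample_correlation <- function(x, ...) {
  cat(sprintf(
    "<intersample_correlation> n = %d samples, estimated from m = %s transcripts\n",
    x$n, ifelse(is.na(x$m), "?", x$m)
  ))
  cat(sprintf(
    "  eigenvalues: max %.4g, min (raw) %.4g, clamped at %.4g\n",
    max(x$values_raw), min(x$values_raw), min(x$values)
  ))
  invisible(x)
}

# profile log-likelihood of delta = sigma2_e / sigma2_g for rotated data.
# yr: rotated response; Wr: rotated design; S: eigenvalues of H.
# Returns the ML profile loglik (sigma2_g profiled out analytically).
.profile_loglik <- function(delta, yr, Wr, S) {
  n <- length(yr)
  w <- 1 / (S + delta)
  A <- crossprod(Wr, Wr * w)
  b <- tryCatch(solve(A, crossprod(Wr, yr * w)), error = function(e) NULL)
  if (is.null(b)) return(-Inf)
  r <- yr - Wr %*% b
  rss <- sum(w * r^2)
  if (rss <= 0) return(Inf)
  sigma2_g <- rss / n
  -0.5 * (n * log(2 * pi * sigma2_g) + sum(log(S + delta)) + n)
}

# grid + golden-section refinement of delta on the log10 scale
.optimize_delta <- function(yr, Wr, S, grid = 10^seq(-5, 5, length.out = 100)) {
  ll <- vapply(grid, .profile_loglik, numeric(1), yr = yr, Wr = Wr, S = S)
  i <- which.max(ll)
  lo <- log10(grid[max(i - 1L, 1L)])
  hi <- log10(grid[min(i + 1L, length(grid))])
  opt <- optimize(
    function(ld) .profile_loglik(10^ld, yr, Wr, S),
    interval = c(lo, hi), maximum = TRUE, tol = 1e-6
  )
  delta <- 10^opt$maximum
  if (opt$objective >= max(ll)) {
    list(delta = delta, loglik = opt$objective, grid_loglik = ll)
  } else {
    list(delta = grid[i], loglik = ll[i], grid_loglik = ll)
  }
}

#' Fit the mixed-model association for one CpG-transcript pair
#'
#' Fits `y = X b + M a + u + e` with `u ~ N(0, sigma2_g H)` and
#' `e ~ N(0, sigma2_e I)`: the expression of one transcript regressed on one
#' CpG's methylation, with fixed covariates and a random confounder term whose
#' covariance is the expression-derived intersample correlation matrix.
#' Everything is rotated by the eigenvectors of H, after which the covariance
#' is diagonal (`sigma2_g * (S + delta)`) and the likelihood can be profiled
#' over the single ratio `delta = sigma2_e / sigma2_g` on a log-spaced grid
#' with local refinement. Estimation is maximum likelihood; the Wald statistic
#' `T = a / se(a)` is referred to a t distribution with `n - ncol(X) - 1`
#' degrees of freedom, so that with `H = I` the fit collapses exactly to
#' ordinary least squares. When H is rank deficient (estimated from fewer
#' transcripts than samples) the fit is restricted to the positive eigenspace
#' of H and the degrees of freedom shrink to the support dimension minus the
#' number of estimable design columns.
#'
#' @param y Numeric response vector (one transcript's log expression).
#' @param M Numeric predictor vector (one CpG's beta values).
#' @param X Covariate matrix including the intercept column, n x c.
#' @param H An `intersample_correlation` object (see
#'   [estimate_intersample_correlation()]).
#' @return An `lmm_fit` object: list with `effect`, `se`, `T`, `p`, `df`,
#'   `sigma2_g`, `sigma2_e`, `delta`, `loglik`, `n`, `p_floored`.
#' @examples
#' n <- 40
#' X <- cbind(1, age = rnorm(n))
#' M <- runif(n)
#' y <- 0.5 * M + rnorm(n)
#' fit_lmm(y, M, X, intersample_correlation(diag(n)))
#' @export
fit_lmm <- function(y, M, X, H) {
  stopifnot(is.numeric(y), is.numeric(M), is.matrix(X))
  n <- length(y)
  if (length(M) != n || nrow(X) != n) abort("y, M and X must have matching lengths")
  if (!inherits(H, "intersample_correlation")) {
    H <- intersample_correlation(as.matrix(H))
  }
  if (H$n != n) abort("H dimension does not match the data")
  if (qr(X)$rank < ncol(X)) abort("covariate matrix X is rank deficient")

  U <- H$vectors[, H$support, drop = FALSE]
  S <- H$values[H$support]
  r_dim <- length(S)
  yr <- drop(crossprod(U, y))
  W <- cbind(X, M)
  Wr <- crossprod(U, W)
  # columns annihilated by the projection (e.g. the intercept when H has the
  # all-ones null direction) carry no information on the support; drop them
  keep <- colSums(Wr^2) > 1e-12 * colSums(W^2)
  if (!keep[length(keep)]) {
    abort("degenerate fit: methylation vector vanishes on the support of H")
  }
  Wr <- Wr[, keep, drop = FALSE]
  q <- ncol(Wr)
  if (r_dim <= q || qr(Wr)$rank < q) {
    abort("degenerate fit: rotated design is singular (is M collinear with X?)")
  }

  opt <- .optimize_delta(yr, Wr, S)
  delta <- opt$delta
  w <- 1 / (S + delta)
  A <- crossprod(Wr, Wr * w)
  Ainv <- solve(A)
  b <- drop(Ainv %*% crossprod(Wr, yr * w))
  r <- yr - drop(Wr %*% b)
  rss <- sum(w * r^2)
  df <- r_dim - q
  sigma2_g <- rss / r_dim
  effect <- unname(b[q])
  p_floored <- FALSE
  if (rss <= .Machine$double.eps * sum(w * yr^2)) {
    # perfect fit: no residual variance left to scale the Wald statistic
    se <- 0
    Tstat <- sign(effect) * Inf
    p <- .Machine$double.xmin
    p_floored <- TRUE
  } else {
    se <- sqrt(rss / df * Ainv[q, q])
    Tstat <- effect / se
    p <- 2 * pt(-abs(Tstat), df = df)
  }
  structure(
    list(
      effect = effect, se = se, T = Tstat, p = p, df = df,
      sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g, delta = delta,
      loglik = opt$loglik, grid_loglik = opt$grid_loglik, n = n,
      p_floored = p_floored
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> effect = %.4g (se %.4g), T = %.3f, p = %.3g, delta = %.3g\n",
    x$effect, x$se, x$T, x$p, x$delta
  ))
  invisible(x)
}

#' @rdname fit_lmm
#' @param x An `lmm_fit` object.
#' @param ... Unused.
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble(
    term = "methylation",
    estimate = x$effect,
    std.error = x$se,
    statistic = x$T,
    p.value = x$p
  )
}

#' @rdname fit_lmm
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(
    sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e, delta = x$delta,
    logLik = x$loglik, df.residual = x$df, nobs = x$n
  )
}
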