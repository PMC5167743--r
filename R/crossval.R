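#' Flag statistical outliers by z-score
#'
#' Marks values whose absolute deviation from the sample mean reaches
#' `threshold` standard deviations. With zero variance nothing is flagged.
#' A manual exclusion index vector can be merged in, mirroring studies that
#' also exclude on qualitative grounds.
#'
#' @param values Numeric vector (>= 3 values).
#' @param threshold z-score threshold (default 2).
#' @param manual Optional integer indices to flag regardless of z-score.
#' @return Logical mask, `TRUE` for excluded observations.
#' @export
flag_outliers <- function(values, threshold = 2, manual = integer(0)) {
  stopifnot(length(values) >= 3L)
  s <- stats::sd(values)
  mask <- if (is.na(s) || s == 0) rep(FALSE, length(values))
          else abs(values - mean(values)) / s >= threshold
  mask[manual] <- TRUE
  mask
}

#' One-tailed Spearman correlation with Bonferroni correction
#'
#' Midrank Spearman coefficient with a one-tailed p-value in the
#' hypothesized direction from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, and a Bonferroni-adjusted
#' p-value `min(1, m * p)` for families of `m_tests` planned correlations.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param direction `"positive"` or `"negative"` hypothesized association.
#' @param m_tests Number of tests in the family (default 1).
#' @return List of class `correlation_result`: `rho`, `r_squared`,
#'   `p_one_tailed`, `p_bonferroni`, `n`, `bonferroni_m`, `direction`.
#' @export
spearman_one_tailed <- function(x, y, direction = c("positive", "negative"),
                                m_tests = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined", call. = FALSE)
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  tval <- if (abs(rho) >= 1) sign(rho) * Inf
          else rho * sqrt((n - 2) / (1 - rho^2))
  p <- stats::pt(tval, n - 2, lower.tail = (direction == "negative"))
  structure(list(rho = rho, r_squared = rho^2, p_one_tailed = p,
                 p_bonferroni = min(1, m_tests * p), n = n,
                 bonferroni_m = as.integer(m_tests), direction = direction),
            class = "correlation_result")
}

#' Simple mediation with bias-corrected bootstrap, Sobel test and kappa^2
#'
#' Ordinary-least-squares path model: `m ~ x` gives the a path, `y ~ x + m`
#' the b and c' paths, `y ~ x` the total effect c; the indirect effect is
#' `a * b` and satisfies `c = c' + a * b` exactly on complete data. The
#' indirect effect's confidence interval is a bias-corrected percentile
#' bootstrap over case resamples; the Sobel test uses
#' `Z = a b / sqrt(b^2 SE_a^2 + a^2 SE_b^2)`; kappa^2 relates the indirect
#' effect to the largest indirect effect attainable while holding the
#' observed variances of x, m, y and the x–y correlation fixed and keeping
#' the implied correlation matrix positive semi-definite (Preacher–Kelley).
#'
#' @param x,m,y Numeric vectors of equal length (n >= 10, no missing
#'   values): independent variable, mediator, outcome.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List of class `mediation_result`: paths `a`, `b`, `c`, `c_prime`,
#'   `indirect`, `boot_ci` (length 2), `sobel_z`, `sobel_p`, `kappa_sq`,
#'   `n`, `n_boot`, `seed`.
#' @export
mediate <- function(x, m, y, n_boot = 5000L, seed = 1L, conf = 0.95) {
  stopifnot(length(x) == length(m), length(x) == length(y),
            length(x) >= 10L,
            !anyNA(x), !anyNA(m), !anyNA(y))
  n <- length(x)
  fit_a <- stats::lm(m ~ x)
  fit_b <- stats::lm(y ~ x + m)
  fit_c <- stats::lm(y ~ x)
  if (any(!is.finite(stats::coef(fit_b))))
    stop("singular design", call. = FALSE)
  a <- unname(stats::coef(fit_a)["x"])
  b <- unname(stats::coef(fit_b)["m"])
  c_prime <- unname(stats::coef(fit_b)["x"])
  c_tot <- unname(stats::coef(fit_c)["x"])
  se_a <- unname(sqrt(diag(stats::vcov(fit_a))["x"]))
  se_b <- unname(sqrt(diag(stats::vcov(fit_b))["m"]))
  indirect <- a * b

  sobel_se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  sobel_z <- indirect / sobel_se
  sobel_p <- 2 * stats::pnorm(-abs(sobel_z))

  boot <- boot_indirect(x, m, y, n_boot = n_boot, seed = seed)
  ci <- bc_ci(boot, indirect, conf = conf)

  structure(list(a = a, b = b, c = c_tot, c_prime = c_prime,
                 indirect = indirect, boot_ci = ci,
                 boot_indirect = boot,
                 sobel_z = sobel_z, sobel_p = sobel_p,
                 kappa_sq = kappa_squared(x, m, y),
                 n = n, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), conf = conf),
            class = "mediation_result")
}

# Bootstrap distribution of a*b over case resamples, computed from the
# resampled moment matrices (no per-resample lm calls). Vectorized in
# chunks to bound memory.
boot_indirect <- function(x, m, y, n_boot, seed, chunk = 500L) {
  n <- length(x)
  set.seed(seed)
  out <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    k <- min(chunk, n_boot - done)
    idx <- matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n); mb <- matrix(m[idx], nrow = n)
    yb <- matrix(y[idx], nrow = n)
    sx <- colMeans(xb); sm <- colMeans(mb); sy <- colMeans(yb)
    sxx <- colMeans(xb * xb) - sx^2
    sxm <- colMeans(xb * mb) - sx * sm
    smm <- colMeans(mb * mb) - sm^2
    sxy <- colMeans(xb * yb) - sx * sy
    smy <- colMeans(mb * yb) - sm * sy
    a <- sxm / sxx
    b <- (sxx * smy - sxm * sxy) / (sxx * smm - sxm^2)
    out[done + seq_len(k)] <- a * b
    done <- done + k
  }
  out
}

# Bias-corrected percentile interval (no acceleration).
bc_ci <- function(boot, est, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  prop <- mean(boot < est)
  # guard degenerate bootstrap distributions
  prop <- min(max(prop, 1 / (length(boot) + 1)),
              length(boot) / (length(boot) + 1))
  z0 <- stats::qnorm(prop)
  alpha <- (1 - conf) / 2
  lo_p <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  unname(stats::quantile(boot, c(lo_p, hi_p)))
}

# Preacher-Kelley kappa^2 by numeric maximization of the attainable
# indirect effect: r_xy and the three variances are held at their sample
# values; r_xm varies over (-1, 1) and, for each r_xm, r_my over the
# interval keeping the correlation matrix PSD; a*b is linear in r_my, so
# the inner maximum sits at an endpoint.
kappa_squared <- function(x, m, y) {
  sx <- stats::sd(x); sm <- stats::sd(m); sy <- stats::sd(y)
  r_xy <- stats::cor(x, y)
  r_xm <- stats::cor(x, m)
  r_my <- stats::cor(m, y)
  a_obs <- r_xm * sm / sx
  b_obs <- ((r_my - r_xy * r_xm) / (1 - r_xm^2)) * (sy / sm)
  ind_obs <- a_obs * b_obs
  if (ind_obs == 0) return(0)

  ind_at <- function(rxm) {
    half <- sqrt(pmax((1 - rxm^2) * (1 - r_xy^2), 0))
    bounds <- c(rxm * r_xy - half, rxm * r_xy + half)
    aa <- rxm * sm / sx
    bb <- ((bounds - r_xy * rxm) / (1 - rxm^2)) * (sy / sm)
    cand <- aa * bb
    cand[sign(cand) == sign(ind_obs)]
  }
  grid <- seq(-0.999, 0.999, length.out = 2001)
  vals <- unlist(lapply(grid, ind_at))
  max_ind <- max(abs(vals))
  if (max_ind == 0) return(0)
  abs(ind_obs) / max_ind
}
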