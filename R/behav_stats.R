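#' Stay probabilities by previous reward and transition type
#'
#' For every trial after the first, the first-stage choice is classified as
#' a stay (same first-stage action as the previous trial) or switch, binned
#' by the previous trial's reward and transition type. Pairs involving an
#' invalid trial are skipped; the first trial contributes no observation.
#'
#' @param trials Trial data frame for one subject (practice rows dropped).
#' @return One-row data frame with stay proportions
#'   `rewarded_common`, `rewarded_rare`, `unrewarded_common`,
#'   `unrewarded_rare` (NA for empty cells) and the four cell counts
#'   (`n_*`).
#' @export
stay_probability_table <- function(trials) {
  trials <- drop_practice(trials)
  if (nrow(trials) < 2L)
    stop("need at least two valid trials", call. = FALSE)
  stays <- matrix(0, 2, 2); counts <- matrix(0, 2, 2)
  for (t in 2:nrow(trials)) {
    if (!trials$valid[t] || !trials$valid[t - 1L]) next
    i <- if (trials$r[t - 1L] == 1L) 1L else 2L        # rewarded / not
    j <- if (trials$transition[t - 1L] == "common") 1L else 2L
    counts[i, j] <- counts[i, j] + 1
    if (trials$a1[t] == trials$a1[t - 1L]) stays[i, j] <- stays[i, j] + 1
  }
  prop <- ifelse(counts > 0, stays / counts, NA_real_)
  data.frame(rewarded_common = prop[1, 1], rewarded_rare = prop[1, 2],
             unrewarded_common = prop[2, 1], unrewarded_rare = prop[2, 2],
             n_rewarded_common = counts[1, 1], n_rewarded_rare = counts[1, 2],
             n_unrewarded_common = counts[2, 1],
             n_unrewarded_rare = counts[2, 2])
}

#' 2x2 repeated-measures ANOVA on stay probabilities
#'
#' Tests the reward main effect, the transition (state) main effect and
#' their interaction via within-subject contrasts: each effect is a
#' one-sample t test on the per-subject contrast, and `F = t^2` with
#' `df = (1, n - 1)`, which for a 2x2 design equals the textbook
#' sums-of-squares repeated-measures ANOVA.
#'
#' @param tables Data frame of per-subject stay probabilities (rows from
#'   [stay_probability_table()]). Subjects with any missing cell are dropped
#'   with a warning.
#' @return Data frame with one row per effect (`reward`, `state`,
#'   `reward:state`): `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(tables) {
  cells <- tables[, c("rewarded_common", "rewarded_rare",
                      "unrewarded_common", "unrewarded_rare")]
  ok <- stats::complete.cases(cells)
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) dropped for missing cells")
    cells <- cells[ok, , drop = FALSE]
  }
  n <- nrow(cells)
  if (n < 3L) stop("need at least three complete subjects", call. = FALSE)
  contrasts <- list(
    reward = (cells$rewarded_common + cells$rewarded_rare -
                cells$unrewarded_common - cells$unrewarded_rare) / 2,
    state = (cells$rewarded_common - cells$rewarded_rare +
               cells$unrewarded_common - cells$unrewarded_rare) / 2,
    `reward:state` = (cells$rewarded_common - cells$rewarded_rare -
                        cells$unrewarded_common + cells$unrewarded_rare))
  rows <- lapply(names(contrasts), function(nm) {
    d <- contrasts[[nm]]
    s <- stats::sd(d)
    if (s == 0) {
      # constant contrast: no within-subject error
      f <- if (mean(d) == 0) 0 else Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      t <- mean(d) / (s / sqrt(n))
      f <- t^2
      p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
    }
    data.frame(effect = nm, F = f, df1 = 1L, df2 = n - 1L, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Friedman test across training blocks
#'
#' Nonparametric test for a block effect on per-block scores (subjects x
#' blocks), wrapping the standard rank-based chi-square test with midrank
#' tie handling.
#'
#' @param block_scores Numeric matrix, one row per subject, one column per
#'   block (>= 2 columns).
#' @return List with `chisq`, `df`, `p`.
#' @export
friedman_blocks <- function(block_scores) {
  block_scores <- as.matrix(block_scores)
  if (ncol(block_scores) < 2L)
    stop("need at least two blocks", call. = FALSE)
  if (nrow(block_scores) < 2L)
    stop("need at least two subjects", call. = FALSE)
  ft <- stats::friedman.test(block_scores)
  chisq <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(chisq)) {
    # every row fully tied: the rank statistic carries no evidence
    chisq <- 0; p <- 1
  }
  list(chisq = chisq, df = unname(ft$parameter), p = p)
}

#' Wilcoxon signed-rank test with normal approximation
#'
#' Paired signed-rank test reported as a Z statistic (with tie correction),
#' the convention in the behavioral literature. Zero differences are
#' dropped.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List with `Z` (signed, negative when `x` tends below `y`), `p`
#'   (two-sided), `n` (nonzero pairs), `V` (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero; the statistic is undefined",
         call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (v - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(Z = z, p = p, n = n, V = v)
}

#' Exact one-sided binomial test against chance
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`. Two usages
#' cover the ambiguity of "above chance" cohort claims: per-subject mode
#' (`k` correct out of `n` trials) and cohort mode (`k` of `n` subjects
#' individually above chance).
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials (or subjects).
#' @param p0 Chance probability (default 0.5).
#' @return Upper-tail p-value `P(X >= k | n, p0)`.
#' @export
binomial_above_chance <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
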