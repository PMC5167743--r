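#' Specification of a synthetic cohort
#'
#' A single latent goal-directedness trait G (standard normal per subject)
#' drives, with configurable loadings, (i) the transformed model-based
#' weight omega in the two-step task, (ii) the logit goal-directedness g of
#' the instrumental-task agent and (iii) a visual short-term-memory-like
#' covariate (VPA), with weaker loadings on two further covariates (WMT,
#' DSST). Group means and spreads of the RL parameters default to published
#' group estimates for this task family (omega 0.68 +/- 0.07, beta_MB 5.28,
#' beta_MF 2.39, beta2 4.18 +/- 1.59, alpha1 0.50 +/- 0.15, alpha2
#' 0.52 +/- 0.25, lambda 0.52 +/- 0.24, rho 0.13 +/- 0.03), moment-matched
#' onto the transformed scale; covariate anchors default to the instrument
#' summaries (VPA 12.11 +/- 3.89 on 3-18, WMT 18.96 +/- 3.85 on 11-24,
#' DSST 87.05 +/- 10.74 on 60-110). Loadings are standardized: a loading
#' `l` means a fraction `l^2` of that trait's variance is shared with G, so
#' two traits with loadings `l1`, `l2` correlate `l1 * l2`.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param loading_omega,loading_g Latent loadings of the two task traits
#'   (defaults `sqrt(0.5)` each, giving a true cross-task correlation of
#'   0.5).
#' @param loading_vpa,loading_wmt,loading_dsst Latent loadings of the
#'   covariates.
#' @param rl_mean,rl_sd Named 7-vectors (transformed scale) overriding the
#'   RL group anchors.
#' @param g_mean,g_sd Mean and sd of the instrumental agent's
#'   goal-directedness on the logit scale (defaults `qlogis(0.81)` and 0.8,
#'   matching reported valued/devalued response rates).
#' @param r_base_mean,r_base_sd Response propensity distribution (natural
#'   scale, clipped to \[0.05, 1\]).
#' @param covariates Data frame of covariate anchors (columns `name`,
#'   `mean`, `sd`, `lo`, `hi`, `loading`); built from the defaults when
#'   `NULL`.
#' @param twostep A [twostep_config()] used for all subjects.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 28L,
                        loading_omega = sqrt(0.5), loading_g = sqrt(0.5),
                        loading_vpa = 0.6, loading_wmt = 0.35,
                        loading_dsst = 0.3,
                        rl_mean = NULL, rl_sd = NULL,
                        g_mean = stats::qlogis(0.81), g_sd = 0.8,
                        r_base_mean = 0.85, r_base_sd = 0.07,
                        covariates = NULL,
                        twostep = twostep_config()) {
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 2L)
  for (l in c(loading_omega, loading_g, loading_vpa, loading_wmt,
              loading_dsst))
    stopifnot(l >= 0, l <= 1)
  anchors <- rl_group_anchors()
  if (!is.null(rl_mean)) anchors$mean[names(rl_mean)] <- rl_mean
  if (!is.null(rl_sd)) anchors$sd[names(rl_sd)] <- rl_sd
  if (is.null(covariates)) {
    covariates <- data.frame(
      name = c("vpa", "wmt", "dsst"),
      mean = c(12.11, 18.96, 87.05),
      sd = c(3.891, 3.854, 10.741),
      lo = c(3, 11, 60), hi = c(18, 24, 110),
      loading = c(loading_vpa, loading_wmt, loading_dsst),
      stringsAsFactors = FALSE)
  }
  structure(list(n_subjects = n_subjects,
                 loading_omega = loading_omega, loading_g = loading_g,
                 rl_mean = anchors$mean, rl_sd = anchors$sd,
                 g_mean = g_mean, g_sd = g_sd,
                 r_base_mean = r_base_mean, r_base_sd = r_base_sd,
                 covariates = covariates, twostep = twostep),
            class = "cohort_spec")
}

# Transformed-scale group anchors, delta-method moment matching of the
# published natural-scale means/sds (logit params: mu = qlogis(m),
# sd = s / (m (1 - m)); log params: mu = log(m), sd = s / m).
rl_group_anchors <- function() {
  nat_mean <- c(alpha1 = 0.50, alpha2 = 0.52, lam = 0.52, omega = 0.68,
                beta1 = 7.67, beta2 = 4.18, rho = 0.13)
  nat_sd <- c(alpha1 = 0.15, alpha2 = 0.25, lam = 0.24, omega = 0.07,
              beta1 = 1.80, beta2 = 1.59, rho = 0.03)
  mu <- c(stats::qlogis(nat_mean[1:4]), log(nat_mean[5:6]), nat_mean[7])
  sd <- c(nat_sd[1:4] / (nat_mean[1:4] * (1 - nat_mean[1:4])),
          nat_sd[5:6] / nat_mean[5:6], nat_sd[7])
  names(mu) <- names(sd) <- param_names()
  list(mean = mu, sd = sd)
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Draws the latent trait, per-subject RL parameters, instrumental-agent
#' parameters and covariates, then simulates one two-step session and all
#' four instrumental phases per subject.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed; everything is reproducible from
#'   `(spec, seed)`.
#' @param tasks If `FALSE`, draw only the ground truth (latent trait,
#'   parameters, covariates) and skip the task simulations; useful for
#'   property checks on the generator itself.
#' @return Object of class `cohort`: `truth` (per-subject data frame with
#'   the latent trait, true parameters and covariates), `twostep` (named
#'   list of trial data frames), `slips` (named list of per-subject phase
#'   record lists), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed = 1L, tasks = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  set.seed(seed)
  G <- stats::rnorm(n)

  mix <- function(mu, sd, loading, shared = G)
    mu + sd * (loading * shared +
                 sqrt(1 - loading^2) * stats::rnorm(length(shared)))

  theta <- matrix(NA_real_, n, 7, dimnames = list(NULL, param_names()))
  for (nm in param_names()) {
    l <- if (nm == "omega") spec$loading_omega else 0
    theta[, nm] <- mix(spec$rl_mean[nm], spec$rl_sd[nm], l)
  }
  g_logit <- mix(spec$g_mean, spec$g_sd, spec$loading_g)
  g <- stats::plogis(g_logit)
  r_base <- pmin(pmax(stats::rnorm(n, spec$r_base_mean, spec$r_base_sd),
                      0.05), 1)
  cov_mat <- sapply(seq_len(nrow(spec$covariates)), function(i) {
    with(spec$covariates[i, ],
         pmin(pmax(mix(mean, sd, loading), lo), hi))
  })
  colnames(cov_mat) <- spec$covariates$name

  truth <- data.frame(subject_id = seq_len(n), G = G,
                      t(apply(theta, 1, function(th)
                        unlist(from_transformed(th)[param_names()]))),
                      g = g, r_base = r_base, cov_mat)
  truth$beta_mb <- truth$omega * truth$beta1
  truth$beta_mf <- (1 - truth$omega) * truth$beta1

  twostep <- vector("list", n)
  slips <- vector("list", n)
  if (tasks) for (i in seq_len(n)) {
    pars <- from_transformed(theta[i, ])
    twostep[[i]] <- simulate_agent(pars, spec$twostep,
                                   seed = seed + 17L * i)
    agent <- slips_agent(g = g[i], r_base = r_base[i])
    slips[[i]] <- simulate_slips_subject(agent, sro_map(seed + 53L * i),
                                         seed = seed + 53L * i + 1L)
  }
  names(twostep) <- names(slips) <- paste0("s", seq_len(n))

  structure(list(truth = truth, twostep = twostep, slips = slips,
                 spec = spec, seed = as.integer(seed)),
            class = "cohort")
}

#' Run the full cross-validation study pipeline on a cohort
#'
#' Fits the hybrid model to every subject's two-step session by
#' empirical-Bayes EM, scores all instrumental phases, computes the
#' descriptive statistics (stay-probability ANOVA, Friedman learning test,
#' above-chance binomial tests, Wilcoxon comparison of the baseline
#' difference score against the slips DSI), screens DSI outliers, computes
#' the three focal one-tailed Spearman correlations (beta_MB-DSI,
#' beta_MF-DSI, omega-DSI; Bonferroni m = 3), the covariate correlations,
#' and the mediation model (x = fitted beta_MB, m = VPA, y = DSI).
#'
#' @param spec A [cohort_spec()] (or an already generated `cohort`).
#' @param seed Master integer seed.
#' @param em_args List of overrides passed on to [em_fit()] (e.g.
#'   `max_iter`, `n_starts`).
#' @param n_boot Bootstrap resamples for the mediation (default 2000).
#' @param outlier_z DSI outlier threshold (default 2).
#' @return Object of class `dual_study`: the cohort, the EM fit, the
#'   per-subject merged table, all test results, and `truth` carried along
#'   for recovery checks.
#' @export
run_study <- function(spec, seed = 1L, em_args = list(), n_boot = 2000L,
                      outlier_z = 2) {
  cohort <- if (inherits(spec, "cohort")) spec
            else generate_cohort(spec, seed = seed)
  spec <- cohort$spec
  n <- spec$n_subjects
  if (n < 4L)
    stop("correlation analyses need at least 4 subjects", call. = FALSE)

  em <- do.call(em_fit, c(list(sessions = cohort$twostep,
                               config = spec$twostep, seed = seed),
                          em_args))
  params <- em_params_table(em)

  # instrumental-task scoring
  training_blocks <- t(sapply(cohort$slips, function(s)
    score_phase(s$training, "training")$block_pct))
  od_pct <- sapply(cohort$slips, function(s)
    score_phase(s$outcome_devaluation, "outcome_devaluation")$pct_correct)
  slips_scores <- lapply(cohort$slips, function(s)
    score_phase(s$slips, "slips"))
  base_scores <- lapply(cohort$slips, function(s)
    score_phase(s$baseline, "baseline"))
  dsi <- sapply(slips_scores, function(s) s$dsi)
  base_diff <- sapply(base_scores, function(s) s$dsi)

  stay <- do.call(rbind, lapply(cohort$twostep, stay_probability_table))
  anova <- rm_anova_2x2(stay)
  friedman <- friedman_blocks(training_blocks)
  # cohort-mode binomial: subjects above chance in the final block
  final_block <- training_blocks[, ncol(training_blocks)]
  binomial <- list(
    k_above = sum(final_block > 50), n = n,
    p = binomial_above_chance(sum(final_block > 50), n, 0.5))
  wilcoxon <- wilcoxon_signed_rank(dsi, base_diff)

  merged <- data.frame(
    subject_id = params$subject_id,
    beta_mb = params$beta_mb, beta_mf = params$beta_mf,
    omega = params$omega, dsi = dsi,
    pct_valued = sapply(slips_scores, function(s) s$pct_valued),
    pct_devalued = sapply(slips_scores, function(s) s$pct_devalued),
    baseline_diff = base_diff, od_pct = od_pct,
    vpa = cohort$truth$vpa, wmt = cohort$truth$wmt,
    dsst = cohort$truth$dsst)
  rownames(merged) <- NULL

  excluded <- flag_outliers(merged$dsi, threshold = outlier_z)
  kept <- merged[!excluded, , drop = FALSE]

  focal <- list(
    beta_mb_dsi = spearman_one_tailed(kept$beta_mb, kept$dsi,
                                      "positive", m_tests = 3L),
    beta_mf_dsi = spearman_one_tailed(kept$beta_mf, kept$dsi,
                                      "positive", m_tests = 3L),
    omega_dsi = spearman_one_tailed(kept$omega, kept$dsi,
                                    "positive", m_tests = 3L))
  covariate_cor <- list(
    dsi_vpa = spearman_one_tailed(kept$dsi, kept$vpa, "positive"),
    dsi_wmt = spearman_one_tailed(kept$dsi, kept$wmt, "positive"),
    dsi_dsst = spearman_one_tailed(kept$dsi, kept$dsst, "positive"),
    beta_mb_vpa = spearman_one_tailed(kept$beta_mb, kept$vpa, "positive"),
    beta_mb_wmt = spearman_one_tailed(kept$beta_mb, kept$wmt, "positive"),
    omega_vpa = spearman_one_tailed(kept$omega, kept$vpa, "positive"))

  mediation <- mediate(kept$beta_mb, kept$vpa, kept$dsi,
                       n_boot = n_boot, seed = seed)

  structure(list(cohort = cohort, em = em, params = params,
                 merged = merged, excluded = excluded,
                 stay = stay, anova = anova, friedman = friedman,
                 binomial = binomial, wilcoxon = wilcoxon,
                 training_blocks = training_blocks,
                 focal = focal, covariate_cor = covariate_cor,
                 mediation = mediation, truth = cohort$truth,
                 seed = as.integer(seed)),
            class = "dual_study")
}

#' @export
print.dual_study <- function(x, ...) {
  n <- nrow(x$merged)
  cat("Cross-validation study on a synthetic cohort of", n, "subjects\n")
  cat(sprintf("  EM fit: %d iteration(s), converged: %s\n",
              x$em$n_iterations, x$em$converged))
  cat(sprintf("  group-mean omega (fitted): %.3f | (true): %.3f\n",
              mean(x$params$omega), mean(x$truth$omega)))
  cat(sprintf("  mean DSI: %.2f (excluded as outliers: %d)\n",
              mean(x$merged$dsi), sum(x$excluded)))
  ia <- x$anova[x$anova$effect == "reward:state", ]
  cat(sprintf("  stay-probability reward x state interaction: F(1,%d) = %.2f, p = %.3g\n",
              ia$df2, ia$F, ia$p))
  f <- x$focal$beta_mb_dsi
  cat(sprintf("  beta_MB-DSI Spearman rho = %.3f, one-tailed p = %.4f (Bonferroni m = 3: %.4f)\n",
              f$rho, f$p_one_tailed, f$p_bonferroni))
  cat(sprintf("  mediation (beta_MB -> VPA -> DSI): indirect = %.3f, BC 95%% CI [%.3f, %.3f], kappa^2 = %.3f\n",
              x$mediation$indirect, x$mediation$boot_ci[1],
              x$mediation$boot_ci[2], x$mediation$kappa_sq))
  invisible(x)
}
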