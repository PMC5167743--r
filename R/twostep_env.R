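#' Configuration for the two-step sequential decision task
#'
#' Builds a validated configuration object for the two-stage Markov task:
#' a first-stage choice between two options leads probabilistically (the
#' common/rare transition structure) to one of two second-stage states, where
#' a second choice is rewarded according to slowly drifting Gaussian
#' random-walk probabilities.
#'
#' @param n_trials Number of main-task trials (default 201).
#' @param n_practice Number of practice trials preceding the main task
#'   (default 55). Practice trials are flagged and excluded from fitting.
#' @param p_common Probability that a first-stage action leads to its
#'   predominantly associated second-stage state (default 0.7). Must exceed
#'   0.5 so that "common" is well defined.
#' @param walk_sd Standard deviation of the per-trial Gaussian increment of
#'   each reward-probability walk (default 0.025).
#' @param walk_bounds Length-2 numeric, reflecting boundaries of the walks
#'   (default c(0.25, 0.75)).
#' @param reward_magnitude Monetary value of one reward in eurocents
#'   (cosmetic; default 20).
#'
#' @return An object of class `twostep_config` (a named list).
#' @export
#' @examples
#' cfg <- twostep_config()
#' cfg$p_common
twostep_config <- function(n_trials = 201L, n_practice = 55L,
                           p_common = 0.7, walk_sd = 0.025,
                           walk_bounds = c(0.25, 0.75),
                           reward_magnitude = 20) {
  n_trials <- as.integer(n_trials)
  n_practice <- as.integer(n_practice)
  if (is.na(n_trials) || n_trials < 1L)
    stop("`n_trials` must be a positive integer", call. = FALSE)
  if (is.na(n_practice) || n_practice < 0L)
    stop("`n_practice` must be a non-negative integer", call. = FALSE)
  if (!is.numeric(p_common) || length(p_common) != 1L ||
      p_common <= 0.5 || p_common > 1)
    stop("`p_common` must lie in (0.5, 1]", call. = FALSE)
  if (!is.numeric(walk_sd) || length(walk_sd) != 1L || walk_sd < 0)
    stop("`walk_sd` must be >= 0", call. = FALSE)
  if (length(walk_bounds) != 2L || !is.numeric(walk_bounds) ||
      walk_bounds[1] < 0 || walk_bounds[2] > 1 ||
      walk_bounds[1] >= walk_bounds[2])
    stop("`walk_bounds` must satisfy 0 <= low < high <= 1", call. = FALSE)
  structure(
    list(n_trials = n_trials, n_practice = n_practice, p_common = p_common,
         walk_sd = walk_sd, walk_bounds = as.numeric(walk_bounds),
         reward_magnitude = reward_magnitude),
    class = "twostep_config"
  )
}

#' Generate the four reward-probability random walks
#'
#' Each of the four second-stage options (two per second-stage state) has its
#' own reward probability, initialized uniformly within `walk_bounds` and
#' evolving by zero-mean Gaussian increments of sd `walk_sd`, reflected at the
#' bounds (reflection, not truncation, preserves the drift variance near the
#' boundaries).
#'
#' @param config A [twostep_config()].
#' @param seed Integer seed; the walks are a pure function of
#'   `(config, seed)`.
#'
#' @return A `n_trials x 4` numeric matrix with columns `p_s1a1`, `p_s1a2`,
#'   `p_s2a1`, `p_s2a2`: reward probability of action a in second-stage
#'   state s at each trial.
#' @export
build_reward_walks <- function(config, seed) {
  stopifnot(inherits(config, "twostep_config"))
  lo <- config$walk_bounds[1]; hi <- config$walk_bounds[2]
  set.seed(seed)
  n <- config$n_trials
  walks <- matrix(NA_real_, n, 4)
  colnames(walks) <- c("p_s1a1", "p_s1a2", "p_s2a1", "p_s2a2")
  x <- stats::runif(4, lo, hi)
  walks[1, ] <- x
  if (n > 1L) {
    for (t in 2:n) {
      x <- x + stats::rnorm(4, 0, config$walk_sd)
      x <- reflect_into(x, lo, hi)
      walks[t, ] <- x
    }
  }
  walks
}

# Reflect values into [lo, hi]; handles overshoots larger than the interval.
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

#' Sample a second-stage state given a first-stage action
#'
#' Action 1 leads predominantly to state 1, action 2 to state 2; the common
#' transition occurs with probability `p_common`, the rare one otherwise.
#'
#' @param a1 First-stage action, 1 or 2.
#' @param config A [twostep_config()].
#'
#' @return A list with `state2` (1 or 2) and `transition`
#'   (`"common"`/`"rare"`). Uses the current RNG stream.
#' @export
sample_transition <- function(a1, config) {
  if (!(length(a1) == 1L && a1 %in% c(1L, 2L)))
    stop("`a1` must be 1 or 2", call. = FALSE)
  common <- stats::runif(1) < config$p_common
  state2 <- if (common) a1 else 3L - as.integer(a1)
  list(state2 = as.integer(state2),
       transition = if (common) "common" else "rare")
}

#' Run one session of the two-step task under an arbitrary policy
#'
#' The policy sees the trial history and returns both actions; the
#' environment supplies transitions and Bernoulli rewards drawn from the
#' reward walks. Simulated sessions contain no invalid trials; the `valid`
#' column exists so imported human data with omissions share the schema.
#'
#' @param policy Function `(history, state2, t)` called twice per trial: first
#'   with `state2 = NA` to obtain the first-stage action, then with the
#'   sampled second-stage state to obtain the second-stage action. `history`
#'   is the data frame of completed trials. Must return 1 or 2.
#' @param config A [twostep_config()].
#' @param seed Integer seed; the session is a pure function of
#'   `(config, policy, seed)`.
#' @param include_practice If `TRUE`, `n_practice` practice trials (with
#'   independent reward walks) are prepended and flagged `practice = TRUE`.
#'
#' @return A data frame with one row per trial: `t`, `a1`, `state2`,
#'   `transition`, `a2`, `r`, `valid`, `practice`, and the four walk values
#'   `p_s1a1` .. `p_s2a2` current on that trial.
#' @export
run_session <- function(policy, config, seed, include_practice = FALSE) {
  stopifnot(inherits(config, "twostep_config"))
  out <- list()
  if (include_practice && config$n_practice > 0L) {
    pcfg <- config
    pcfg$n_trials <- config$n_practice
    out$practice <- run_block(policy, pcfg, seed = seed + 1000003L,
                              practice = TRUE)
  }
  out$main <- run_block(policy, config, seed = seed, practice = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$t <- seq_len(nrow(res))
  res
}

run_block <- function(policy, config, seed, practice) {
  walks <- build_reward_walks(config, seed)
  set.seed(seed + 1L)
  n <- config$n_trials
  a1 <- integer(n); s2 <- integer(n); a2 <- integer(n)
  tr <- character(n); r <- integer(n)
  hist <- empty_trials()
  for (t in seq_len(n)) {
    act1 <- policy(hist, NA_integer_, t)
    check_action(act1)
    trans <- sample_transition(act1, config)
    act2 <- policy(hist, trans$state2, t)
    check_action(act2)
    p <- walks[t, walk_col(trans$state2, act2)]
    rew <- as.integer(stats::runif(1) < p)
    a1[t] <- act1; s2[t] <- trans$state2; tr[t] <- trans$transition
    a2[t] <- act2; r[t] <- rew
    hist <- rbind(hist, data.frame(
      t = t, a1 = act1, state2 = trans$state2, transition = trans$transition,
      a2 = act2, r = rew, valid = TRUE, practice = practice,
      stringsAsFactors = FALSE))
  }
  data.frame(t = seq_len(n), a1 = a1, state2 = s2, transition = tr,
             a2 = a2, r = r, valid = TRUE, practice = practice,
             p_s1a1 = walks[, 1], p_s1a2 = walks[, 2],
             p_s2a1 = walks[, 3], p_s2a2 = walks[, 4],
             stringsAsFactors = FALSE)
}

walk_col <- function(state2, a2) (state2 - 1L) * 2L + a2

check_action <- function(a) {
  if (!(length(a) == 1L && !is.na(a) && a %in% c(1L, 2L)))
    stop("policy returned an action outside {1, 2}", call. = FALSE)
  invisible(a)
}

empty_trials <- function() {
  data.frame(t = integer(), a1 = integer(), state2 = integer(),
             transition = character(), a2 = integer(), r = integer(),
             valid = logical(), practice = logical(),
             stringsAsFactors = FALSE)
}

#' Uniform-random choice policy
#'
#' Convenience policy for contract checks and null baselines.
#' @return A policy function for [run_session()].
#' @export
random_policy <- function() {
  function(history, state2, t) sample(1:2, 1L)
}
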