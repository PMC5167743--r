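#' Parameters of the hybrid model-based/model-free learner
#'
#' The seven free parameters of the hybrid SARSA(lambda) agent: stage-wise
#' learning rates, the eligibility weight lambda carrying the second-stage
#' prediction error back to stage 1, the model-based weight omega mixing
#' planned and cached first-stage values, stage-wise softmax inverse
#' temperatures, and a perseveration bonus rho for repeating the previous
#' first-stage choice. The derived quantities `beta_mb = omega * beta1` and
#' `beta_mf = (1 - omega) * beta1` quantify how strongly choices follow the
#' model-based and model-free values respectively.
#'
#' @param alpha1,alpha2 Learning rates, in (0, 1).
#' @param lam Eligibility weight lambda, in (0, 1).
#' @param omega Model-based weight, in (0, 1).
#' @param beta1,beta2 Softmax inverse temperatures, > 0.
#' @param rho Perseveration weight (unbounded, applies at stage 1 only).
#'
#' @return An object of class `agent_params` with the seven natural-scale
#'   values plus `beta_mb` and `beta_mf`.
#' @export
#' @examples
#' p <- agent_params(omega = 0.68, beta1 = 7.67)
#' p$beta_mb + p$beta_mf == p$beta1
agent_params <- function(alpha1 = 0.5, alpha2 = 0.5, lam = 0.5,
                         omega = 0.5, beta1 = 5, beta2 = 5, rho = 0) {
  for (nm in c("alpha1", "alpha2", "lam", "omega")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
  }
  for (nm in c("beta1", "beta2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  sb <- split_betas(omega, beta1)
  structure(
    list(alpha1 = alpha1, alpha2 = alpha2, lam = lam, omega = omega,
         beta1 = beta1, beta2 = beta2, rho = rho,
         beta_mb = sb[["beta_mb"]], beta_mf = sb[["beta_mf"]]),
    class = "agent_params"
  )
}

#' Split the first-stage inverse temperature into MB and MF components
#'
#' `beta_mb = omega * beta1`, `beta_mf = (1 - omega) * beta1`; the two sum to
#' `beta1` exactly.
#'
#' @param omega Model-based weight in \[0, 1\].
#' @param beta1 First-stage inverse temperature, >= 0.
#' @return Named numeric vector `c(beta_mb =, beta_mf =)`.
#' @export
split_betas <- function(omega, beta1) {
  stopifnot(omega >= 0, omega <= 1, beta1 >= 0)
  mb <- unname(omega * beta1)
  # complement form keeps the sum identity exact in floating point
  c(beta_mb = mb, beta_mf = unname(beta1) - mb)
}

#' Names and order of the transformed parameter vector
#' @return Character vector of the seven parameter names.
#' @export
param_names <- function() {
  c("alpha1", "alpha2", "lam", "omega", "beta1", "beta2", "rho")
}

#' Map natural-scale parameters to the unconstrained fitting scale
#'
#' Unit-interval parameters (alpha1, alpha2, lambda, omega) are mapped by
#' log-odds, inverse temperatures by log, and rho by the identity, so that
#' group-level Gaussian priors live on an unbounded scale.
#'
#' @param params An [agent_params()] object.
#' @return Named numeric 7-vector on the transformed scale.
#' @export
to_transformed <- function(params) {
  stopifnot(inherits(params, "agent_params"))
  v <- unlist(params[param_names()])
  if (any(v[1:4] <= 0) || any(v[1:4] >= 1) || any(v[5:6] <= 0))
    stop("boundary parameter values have no finite transform", call. = FALSE)
  c(stats::qlogis(v[1:4]), log(v[5:6]), v[7])
}

#' Map a transformed 7-vector back to natural-scale parameters
#'
#' Inverse of [to_transformed()]; the round trip is the identity to numerical
#' precision.
#'
#' @param theta Numeric 7-vector on the transformed scale.
#' @return An [agent_params()] object.
#' @export
from_transformed <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 7L, all(is.finite(theta)))
  theta <- unname(theta)
  agent_params(alpha1 = stats::plogis(theta[1]),
               alpha2 = stats::plogis(theta[2]),
               lam    = stats::plogis(theta[3]),
               omega  = stats::plogis(theta[4]),
               beta1  = exp(theta[5]),
               beta2  = exp(theta[6]),
               rho    = theta[7])
}

#' Fresh value state at the start of a session
#'
#' All action values are initialized at zero and there is no previous
#' first-stage action to perseverate on.
#'
#' @return A list with `q1` (2 model-free first-stage values), `q2`
#'   (2 states x 2 actions model-free second-stage values) and `last_a1`.
#' @export
value_state <- function() {
  list(q1 = c(0, 0), q2 = matrix(0, 2, 2), last_a1 = NA_integer_)
}

#' SARSA(lambda) model-free update for one trial
#'
#' Computes the stage-1 prediction error with the pre-update second-stage
#' value (no reward is delivered after the first choice), then the
#' second-stage reward prediction error, and applies the three updates:
#' stage-2 value by `alpha2 * delta2`, stage-1 value by `alpha1 * delta1`
#' and additionally by `alpha1 * lam * delta2`. Unchosen values are
#' untouched; invalid trials leave the state unchanged.
#'
#' @param state A [value_state()].
#' @param trial One-row trial record (fields `a1`, `state2`, `a2`, `r`,
#'   `valid`).
#' @param params An [agent_params()].
#' @return List with the updated `state`, `delta1` and `delta2`.
#' @export
mf_update <- function(state, trial, params) {
  if (!isTRUE(as.logical(trial$valid)))
    return(list(state = state, delta1 = NA_real_, delta2 = NA_real_))
  a1 <- trial$a1; s2 <- trial$state2; a2 <- trial$a2; r <- trial$r
  delta1 <- state$q2[s2, a2] - state$q1[a1]
  delta2 <- r - state$q2[s2, a2]
  state$q2[s2, a2] <- state$q2[s2, a2] + params$alpha2 * delta2
  state$q1[a1] <- state$q1[a1] + params$alpha1 * delta1
  state$q1[a1] <- state$q1[a1] + params$alpha1 * params$lam * delta2
  state$last_a1 <- as.integer(a1)
  list(state = state, delta1 = delta1, delta2 = delta2)
}

#' Model-based first-stage values by one-step planning
#'
#' With the transition structure instructed and fixed, the model-based value
#' of each first-stage action is the transition-probability-weighted maximum
#' over the model-free values of the two second-stage states.
#'
#' @param state A [value_state()].
#' @param config A [twostep_config()] (supplies `p_common`).
#' @return Numeric 2-vector of first-stage model-based values.
#' @export
mb_values <- function(state, config) {
  p <- config$p_common
  m <- c(max(state$q2[1, ]), max(state$q2[2, ]))
  c(p * m[1] + (1 - p) * m[2],
    (1 - p) * m[1] + p * m[2])
}

#' Hybrid first-stage values
#'
#' Convex combination `omega * Q_MB + (1 - omega) * Q_MF` of planned and
#' cached first-stage values.
#'
#' @param state A [value_state()].
#' @param params An [agent_params()].
#' @param config A [twostep_config()].
#' @return Numeric 2-vector of hybrid first-stage values.
#' @export
hybrid_values <- function(state, params, config) {
  params$omega * mb_values(state, config) + (1 - params$omega) * state$q1
}

#' Softmax choice probabilities with perseveration
#'
#' `p(a) = exp(beta * (Q(a) + rho * rep(a))) / sum_a' exp(...)`, where
#' `rep(a) = 1` iff `a` repeats the previous trial's first-stage action and
#' `stage == 1`. Computed with max-subtraction so large `beta * Q` never
#' overflows.
#'
#' @param values Numeric 2-vector of action values.
#' @param beta Inverse temperature, >= 0.
#' @param rho Perseveration weight.
#' @param last_action Previous first-stage action (1, 2 or `NA`).
#' @param stage 1 or 2; perseveration applies at stage 1 only.
#' @return Numeric 2-vector of probabilities summing to 1.
#' @export
choice_probs <- function(values, beta, rho = 0, last_action = NA, stage = 1L) {
  stopifnot(length(values) == 2L, is.finite(values[1]), is.finite(values[2]),
            beta >= 0)
  rep_bonus <- c(0, 0)
  if (stage == 1L && !is.na(last_action)) rep_bonus[last_action] <- 1
  z <- beta * (values + rho * rep_bonus)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Negative log-likelihood of a session under the hybrid model
#'
#' Sums `-log p(a1) - log p(a2)` over valid main-task trials, with values
#' updated trial by trial; invalid and practice trials contribute nothing
#' and do not update values. Second-stage probabilities use the raw
#' model-free second-stage values with `beta2` (planning collapses onto the
#' cached values once the second state is reached).
#'
#' @param trials Trial data frame from [run_session()] / [simulate_agent()]
#'   (practice rows, if present, are dropped).
#' @param params An [agent_params()].
#' @param config A [twostep_config()].
#' @return Non-negative scalar; 0 for an empty session.
#' @export
session_nll <- function(trials, params, config) {
  stopifnot(inherits(params, "agent_params"))
  trials <- drop_practice(trials)
  if (nrow(trials) == 0L) return(0)
  cpp_session_nll(as.integer(trials$a1), as.integer(trials$state2),
                  as.integer(trials$a2), as.integer(trials$r),
                  as.logical(trials$valid),
                  params$alpha1, params$alpha2, params$lam, params$omega,
                  params$beta1, params$beta2, params$rho,
                  config$p_common)
}

drop_practice <- function(trials) {
  if ("practice" %in% names(trials)) trials[!trials$practice, , drop = FALSE]
  else trials
}

#' Simulate a hybrid agent on the two-step task
#'
#' Generates a full session with choices sampled from the model's softmax
#' probabilities and rewards from the environment's random walks.
#'
#' @param params An [agent_params()].
#' @param config A [twostep_config()].
#' @param seed Integer seed; the session is reproducible from
#'   `(params, config, seed)`.
#' @param include_practice Prepend flagged practice trials (independent
#'   walks, values carried over into the main task are reset).
#' @return Trial data frame as in [run_session()].
#' @export
simulate_agent <- function(params, config, seed, include_practice = FALSE) {
  stopifnot(inherits(params, "agent_params"))
  blocks <- list()
  if (include_practice && config$n_practice > 0L) {
    pcfg <- config
    pcfg$n_trials <- config$n_practice
    blocks$practice <- simulate_agent_block(params, pcfg,
                                            seed = seed + 1000003L,
                                            practice = TRUE)
  }
  blocks$main <- simulate_agent_block(params, config, seed, practice = FALSE)
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  res$t <- seq_len(nrow(res))
  res
}

# One block of agent simulation: fresh value state, own reward walks.
simulate_agent_block <- function(params, config, seed, practice) {
  walks <- build_reward_walks(config, seed)
  set.seed(seed + 1L)
  n <- config$n_trials
  a1 <- integer(n); s2 <- integer(n); a2 <- integer(n)
  tr <- character(n); r <- integer(n)
  state <- value_state()
  for (t in seq_len(n)) {
    pr1 <- choice_probs(hybrid_values(state, params, config),
                        params$beta1, params$rho, state$last_a1, 1L)
    act1 <- if (stats::runif(1) < pr1[1]) 1L else 2L
    trans <- sample_transition(act1, config)
    pr2 <- choice_probs(state$q2[trans$state2, ], params$beta2, stage = 2L)
    act2 <- if (stats::runif(1) < pr2[1]) 1L else 2L
    p <- walks[t, walk_col(trans$state2, act2)]
    rew <- as.integer(stats::runif(1) < p)
    a1[t] <- act1; s2[t] <- trans$state2; tr[t] <- trans$transition
    a2[t] <- act2; r[t] <- rew
    state <- mf_update(state, list(a1 = act1, state2 = trans$state2,
                                   a2 = act2, r = rew, valid = TRUE),
                       params)$state
  }
  data.frame(t = seq_len(n), a1 = a1, state2 = s2, transition = tr,
             a2 = a2, r = r, valid = TRUE, practice = practice,
             p_s1a1 = walks[, 1], p_s1a2 = walks[, 2],
             p_s2a1 = walks[, 3], p_s2a2 = walks[, 4],
             stringsAsFactors = FALSE)
}
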