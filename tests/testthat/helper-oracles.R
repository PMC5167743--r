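# Independent oracles and small fixtures, written as straight-line code so
# they share nothing with the package implementation paths they check.

# Step-by-step trace of the hybrid-model session likelihood.
oracle_session_nll <- function(tr, pars, p_common) {
  q1 <- c(0, 0)
  q2 <- matrix(0, 2, 2)
  last <- NA_integer_
  nll <- 0
  for (t in seq_len(nrow(tr))) {
    if (!tr$valid[t]) next
    m <- c(max(q2[1, ]), max(q2[2, ]))
    qmb <- c(p_common * m[1] + (1 - p_common) * m[2],
             (1 - p_common) * m[1] + p_common * m[2])
    qh <- pars$omega * qmb + (1 - pars$omega) * q1
    bonus <- c(0, 0)
    if (!is.na(last)) bonus[last] <- pars$rho
    z1 <- pars$beta1 * (qh + bonus)
    pr1 <- exp(z1) / sum(exp(z1))
    nll <- nll - log(pr1[tr$a1[t]])
    z2 <- pars$beta2 * q2[tr$state2[t], ]
    pr2 <- exp(z2) / sum(exp(z2))
    nll <- nll - log(pr2[tr$a2[t]])
    d1 <- q2[tr$state2[t], tr$a2[t]] - q1[tr$a1[t]]
    d2 <- tr$r[t] - q2[tr$state2[t], tr$a2[t]]
    q2[tr$state2[t], tr$a2[t]] <- q2[tr$state2[t], tr$a2[t]] +
      pars$alpha2 * d2
    q1[tr$a1[t]] <- q1[tr$a1[t]] + pars$alpha1 * d1 +
      pars$alpha1 * pars$lam * d2
    last <- tr$a1[t]
  }
  nll
}

# Classic sums-of-squares 2x2 repeated-measures ANOVA via aov() with an
# Error stratum.
oracle_rm_anova <- function(cells) {
  n <- nrow(cells)
  long <- data.frame(
    y = c(cells$rewarded_common, cells$rewarded_rare,
          cells$unrewarded_common, cells$unrewarded_rare),
    reward = factor(rep(c("r", "r", "u", "u"), each = n)),
    state = factor(rep(c("c", "rr", "c", "rr"), each = n)),
    subject = factor(rep(seq_len(n), times = 4)))
  fit <- stats::aov(y ~ reward * state +
                      Error(subject / (reward * state)), data = long)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    row <- trimws(rownames(tab)) == term
    c(F = tab[row, "F value"], p = tab[row, "Pr(>F)"])
  }
  list(reward = grab("Error: subject:reward", "reward"),
       state = grab("Error: subject:state", "state"),
       interaction = grab("Error: subject:reward:state", "reward:state"))
}

# Hand-built random trial table (not produced by the simulator) for
# likelihood fixtures; includes an invalid trial when n allows.
make_fixture_trials <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    t = seq_len(n),
    a1 = sample(1:2, n, replace = TRUE),
    state2 = sample(1:2, n, replace = TRUE),
    transition = "common",
    a2 = sample(1:2, n, replace = TRUE),
    r = sample(0:1, n, replace = TRUE),
    valid = TRUE, practice = FALSE)
  df$transition <- ifelse(df$a1 == df$state2, "common", "rare")
  if (n >= 5) df$valid[3] <- FALSE
  df
}

random_agent <- function(seed) {
  set.seed(seed)
  agent_params(alpha1 = runif(1, 0.1, 0.9), alpha2 = runif(1, 0.1, 0.9),
               lam = runif(1, 0.1, 0.9), omega = runif(1, 0.1, 0.9),
               beta1 = runif(1, 0.5, 9), beta2 = runif(1, 0.5, 9),
               rho = runif(1, -0.3, 0.5))
}

# Transformed-scale group anchors shared by recovery tests.
anchor_means <- function() dualcontrol:::rl_group_anchors()$mean
anchor_sds <- function() dualcontrol:::rl_group_anchors()$sd

# Stay-table interaction and main-effect contrasts from one row.
stay_contrasts <- function(st) {
  list(reward = (st$rewarded_common + st$rewarded_rare) / 2 -
         (st$unrewarded_common + st$unrewarded_rare) / 2,
       interaction = (st$rewarded_common - st$rewarded_rare) -
         (st$unrewarded_common - st$unrewarded_rare))
}
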