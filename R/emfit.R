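#' Group-level Gaussian prior on transformed parameters
#'
#' Diagonal Gaussian over the 7-dimensional transformed parameter space,
#' used as the empirical prior in hierarchical MAP fitting.
#'
#' @param mean Numeric 7-vector of prior means (transformed scale).
#' @param var Numeric 7-vector of prior variances, all > 0.
#' @return An object of class `group_prior`.
#' @export
group_prior <- function(mean, var) {
  mean <- as.numeric(mean); var <- as.numeric(var)
  stopifnot(length(mean) == 7L, length(var) == 7L,
            all(is.finite(mean)), all(is.finite(var)), all(var > 0))
  names(mean) <- names(var) <- param_names()
  structure(list(mean = mean, var = var), class = "group_prior")
}

#' A broad default prior centered on neutral parameter values
#'
#' Mean zero on the transformed scale (learning rates, lambda and omega at
#' 0.5; inverse temperatures at 1; rho at 0) with variance 6.25 per
#' dimension.
#'
#' @param var0 Prior variance per dimension (default 6.25).
#' @return A [group_prior()].
#' @export
default_prior <- function(var0 = 6.25) {
  group_prior(rep(0, 7), rep(var0, 7))
}

# Pre-extract the integer session columns once per fit so that each
# objective evaluation goes straight to the compiled likelihood.
prep_session <- function(trials) {
  trials <- drop_practice(trials)
  list(a1 = as.integer(trials$a1), s2 = as.integer(trials$state2),
       a2 = as.integer(trials$a2), r = as.integer(trials$r),
       valid = as.logical(trials$valid))
}

# Penalized objective: data NLL plus Gaussian prior NLL over the free
# dimensions. `theta_free` are the free transformed coordinates; pinned
# dimensions are held at `theta_fixed`. `prepped` is a list of
# prep_session() outputs.
penalized_nll <- function(theta_free, free_idx, theta_fixed, prepped,
                          prior, config) {
  theta <- theta_fixed
  theta[free_idx] <- theta_free
  # keep exp()/plogis() finite when a line search overshoots
  if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
  a1 <- stats::plogis(theta[1]); a2 <- stats::plogis(theta[2])
  lam <- stats::plogis(theta[3]); om <- stats::plogis(theta[4])
  b1 <- exp(theta[5]); b2 <- exp(theta[6]); rho <- theta[7]
  nll <- 0
  for (s in prepped)
    nll <- nll + cpp_session_nll(s$a1, s$s2, s$a2, s$r, s$valid,
                                 a1, a2, lam, om, b1, b2, rho,
                                 config$p_common)
  pen <- -sum(stats::dnorm(theta[free_idx], prior$mean[free_idx],
                           sqrt(prior$var[free_idx]), log = TRUE))
  val <- nll + pen
  if (!is.finite(val)) 1e10 else val
}

#' Per-subject maximum-a-posteriori fit
#'
#' Maximizes the session log-likelihood plus the log prior density on the
#' transformed scale, with multi-start quasi-Newton optimization (prior mean
#' plus jittered draws, plus any user-supplied warm start), and returns the
#' best optimum together with the diagonal Laplace curvature of the
#' penalized objective.
#'
#' @param trials Trial data frame for one subject (non-empty).
#' @param prior A [group_prior()].
#' @param config A [twostep_config()].
#' @param fixed Optional named list of natural-scale parameter values to pin
#'   (those dimensions are excluded from optimization and prior penalty).
#' @param n_starts Number of optimization starts (>= 1; default 5).
#' @param seed Seed controlling the start jitter.
#' @param start Optional transformed 7-vector used as an additional start
#'   (warm start during EM).
#'
#' @return An object of class `subject_fit`: `theta` (transformed MAP,
#'   7-vector), `params` (natural scale, [agent_params()]), `nll` (data
#'   negative log-likelihood at the MAP, prior term excluded), `penalized`
#'   (value of the penalized objective), `hessian_diag` (curvature of the
#'   penalized objective at the MAP, free dimensions), `converged`.
#' @export
subject_map <- function(trials, prior, config, fixed = NULL,
                        n_starts = 5L, seed = 1L, start = NULL) {
  trials <- drop_practice(trials)
  if (is.null(trials) || nrow(trials) == 0L)
    stop("`trials` must contain at least one trial", call. = FALSE)
  stopifnot(inherits(prior, "group_prior"))
  nm <- param_names()
  theta_fixed <- rep(NA_real_, 7); names(theta_fixed) <- nm
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% nm))
      stop("unknown parameter in `fixed`", call. = FALSE)
    nat <- formals(agent_params)
    for (k in names(fixed)) nat[[k]] <- fixed[[k]]
    full <- to_transformed(do.call(agent_params, lapply(nat, eval)))
    theta_fixed[names(fixed)] <- full[names(fixed)]
  }
  free_idx <- which(is.na(theta_fixed))
  theta_fixed[free_idx] <- 0  # placeholder, overwritten by free coords

  prepped <- list(prep_session(trials))
  obj <- function(th) penalized_nll(th, free_idx, theta_fixed,
                                    prepped, prior, config)

  set.seed(seed)
  starts <- if (n_starts >= 1L) list(prior$mean[free_idx]) else list()
  if (n_starts > 1L) {
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- prior$mean[free_idx] +
        stats::rnorm(length(free_idx), 0, 0.5 * sqrt(prior$var[free_idx]))
    }
  }
  if (!is.null(start)) starts[[length(starts) + 1L]] <- start[free_idx]
  if (length(starts) == 0L)
    stop("need at least one start (`n_starts` >= 1 or `start`)",
         call. = FALSE)

  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimization starts failed", call. = FALSE)

  theta <- theta_fixed
  theta[free_idx] <- best$par
  names(theta) <- nm
  params <- from_transformed(theta)
  nll <- session_nll(trials, params, config)

  hd <- numeric(length(free_idx))
  f0 <- best$value
  for (j in seq_along(free_idx)) {
    h <- 1e-3 * (1 + abs(best$par[j]))
    up <- best$par; up[j] <- up[j] + h
    dn <- best$par; dn[j] <- dn[j] - h
    hd[j] <- (obj(up) - 2 * f0 + obj(dn)) / h^2
  }
  names(hd) <- nm[free_idx]

  structure(list(theta = theta, params = params, nll = nll,
                 penalized = best$value, hessian_diag = hd,
                 free = nm[free_idx], converged = any_conv),
            class = "subject_fit")
}

#' Initialize the group prior from pooled maximum likelihood
#'
#' The prior mean is set to the transformed-scale maximum-likelihood
#' estimate on the pooled data of all subjects (one likelihood summed over
#' subjects, values reset at each subject's session start); the variance is
#' a broad default.
#'
#' @param sessions List of per-subject trial data frames (>= 1).
#' @param config A [twostep_config()].
#' @param var0 Prior variance per dimension (default 6.25).
#' @param n_starts Optimization starts (default 5).
#' @param seed Seed for start jitter.
#' @return A [group_prior()].
#' @export
init_prior <- function(sessions, config, var0 = 6.25, n_starts = 5L,
                       seed = 1L) {
  if (length(sessions) == 0L)
    stop("`sessions` must contain at least one subject", call. = FALSE)
  flat <- group_prior(rep(0, 7), rep(1e8, 7))  # effectively flat
  prepped <- lapply(sessions, prep_session)
  obj <- function(th) penalized_nll(th, 1:7, rep(0, 7), prepped, flat,
                                    config)
  set.seed(seed)
  starts <- list(rep(0, 7))
  if (n_starts > 1L)
    for (i in seq_len(n_starts - 1L))
      starts[[i + 1L]] <- stats::rnorm(7, 0, 1)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) {
    warning("pooled ML optimization failed; using broad default prior")
    return(default_prior(var0))
  }
  group_prior(best$par, rep(var0, 7))
}

#' Hierarchical empirical-Bayes fit by Expectation-Maximization
#'
#' Alternates per-subject MAP estimation under the current group prior
#' (E-step, with Laplace curvature giving per-subject posterior variances)
#' with moment-matching updates of the prior (M-step): the prior mean
#' becomes the mean of the MAP estimates and the prior variance the mean of
#' squared estimates plus Laplace variances minus the squared mean.
#' Iteration stops when the largest absolute change in the prior mean falls
#' below `tol`.
#'
#' @param sessions List of per-subject trial data frames (>= 2 subjects).
#' @param config A [twostep_config()].
#' @param tol Convergence tolerance on the prior mean (default 1e-3).
#' @param max_iter Maximum EM iterations (default 100).
#' @param n_starts Optimization starts per subject and E-step (default 5).
#' @param seed Seed controlling all optimizer jitter.
#' @param prior Optional initial [group_prior()]; by default obtained from
#'   [init_prior()].
#' @param update_variance If `TRUE` (default) the prior variance is
#'   re-estimated each M-step; otherwise it is held at its initial value.
#' @param verbose Log iteration summaries to standard error.
#'
#' @return An object of class `em_result`: `prior` (final [group_prior()]),
#'   `fits` (list of `subject_fit`), `n_iterations`, `trajectory`
#'   (variational objective per iteration), `converged`.
#' @export
em_fit <- function(sessions, config, tol = 1e-3, max_iter = 100L,
                   n_starts = 5L, seed = 1L, prior = NULL,
                   update_variance = TRUE, verbose = FALSE) {
  if (length(sessions) < 2L)
    stop("EM fitting needs at least two subjects", call. = FALSE)
  if (is.null(prior)) prior <- init_prior(sessions, config, seed = seed)
  n_sub <- length(sessions)
  fits <- vector("list", n_sub)
  warm <- vector("list", n_sub)
  trajectory <- numeric(0)
  converged <- FALSE
  it <- 0L

  for (it in seq_len(max_iter)) {
    # E-step: MAP + Laplace variance per subject. The first iteration uses
    # the full multi-start budget; later iterations are warm-started from
    # the previous MAP and only add the prior mean plus one jitter.
    # Full multi-start on the first E-step; afterwards warm starts carry
    # the optimum, with a periodic prior-mean restart against mode capture.
    it_starts <- if (it == 1L) n_starts else if (it %% 5L == 0L) 1L else 0L
    for (i in seq_len(n_sub)) {
      fits[[i]] <- subject_map(sessions[[i]], prior, config,
                               n_starts = it_starts,
                               seed = seed + 1000L * it + i,
                               start = warm[[i]])
      warm[[i]] <- fits[[i]]$theta
    }
    ok <- vapply(fits, function(f) f$converged, logical(1))
    use <- if (any(ok)) which(ok) else seq_len(n_sub)

    theta_mat <- do.call(rbind, lapply(fits[use], function(f) f$theta))
    s2_mat <- do.call(rbind, lapply(fits[use], function(f) {
      s2 <- 1 / pmax(f$hessian_diag, 1e-8)
      pmin(s2, prior$var)  # cap uninformative curvature at the prior width
    }))

    # variational objective (ELBO up to constants) under the current prior
    elbo <- sum(vapply(fits[use], function(f) -f$penalized, numeric(1))) +
      0.5 * sum(log(s2_mat))
    trajectory <- c(trajectory, elbo)

    # M-step: moment matching
    mu_new <- colMeans(theta_mat)
    if (update_variance) {
      v_new <- colMeans(theta_mat^2 + s2_mat) - mu_new^2
      v_new <- pmax(v_new, 1e-4)
    } else {
      v_new <- prior$var
    }
    delta <- max(abs(mu_new - prior$mean))
    if (verbose)
      message(sprintf("EM iter %d: ELBO %.3f, max |d mean| %.5f",
                      it, elbo, delta))
    prior <- group_prior(mu_new, v_new)
    if (delta < tol) { converged <- TRUE; break }
  }

  structure(list(prior = prior, fits = fits, n_iterations = it,
                 trajectory = trajectory, converged = converged),
            class = "em_result")
}

#' Tidy per-subject parameter table from an EM fit
#'
#' @param em An `em_result` from [em_fit()].
#' @return Data frame, one row per subject: natural-scale parameters,
#'   derived `beta_mb`/`beta_mf`, transformed parameters (prefixed `t_`)
#'   and the data `-LL` at the MAP.
#' @export
em_params_table <- function(em) {
  stopifnot(inherits(em, "em_result"))
  rows <- lapply(seq_along(em$fits), function(i) {
    f <- em$fits[[i]]
    p <- f$params
    tt <- as.list(f$theta); names(tt) <- paste0("t_", names(f$theta))
    cbind(data.frame(subject_id = i,
                     alpha1 = p$alpha1, alpha2 = p$alpha2, lam = p$lam,
                     omega = p$omega, beta1 = p$beta1, beta2 = p$beta2,
                     rho = p$rho, beta_mb = p$beta_mb, beta_mf = p$beta_mf,
                     nll = f$nll, converged = f$converged),
          as.data.frame(tt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
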