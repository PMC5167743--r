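#' Stimulus-response-outcome map for the instrumental learning task
#'
#' Six stimuli each deterministically yield a unique outcome when the
#' correct response is made; three stimuli require a left and three a right
#' button press.
#'
#' @param seed Integer seed controlling the side assignment.
#' @return An object of class `sro_map`: data frame with columns
#'   `stimulus` (1..6), `response` (`"left"`/`"right"`), `outcome` (1..6).
#' @export
sro_map <- function(seed = 1L) {
  set.seed(seed)
  sides <- sample(rep(c("left", "right"), each = 3L))
  out <- data.frame(stimulus = 1:6, response = sides, outcome = 1:6,
                    stringsAsFactors = FALSE)
  class(out) <- c("sro_map", "data.frame")
  out
}

#' Generate a trial schedule for one phase of the instrumental task
#'
#' Phases: discrimination `training` (8 blocks x 12 trials, each stimulus
#' twice per block, 16 times in total); `outcome_devaluation` (36 trials,
#' each pairing one left- and one right-associated outcome with one of the
#' two devalued, all nine pairs four times with the devalued side
#' counterbalanced); `slips` (9 blocks x 12 trials, each stimulus twice per
#' block, never immediately repeated, two outcomes — one left- and one
#' right-associated — devalued per block, each outcome devalued in exactly
#' three blocks: 36 devalued and 72 valued trials); `baseline` (same
#' structure with devalued stimuli instead of outcomes).
#'
#' @param phase One of `"training"`, `"outcome_devaluation"`, `"slips"`,
#'   `"baseline"`.
#' @param sro An [sro_map()].
#' @param seed Integer seed; schedules are pure functions of
#'   `(phase, sro, seed)`.
#' @return An object of class `slips_schedule`: list with `phase`, `trials`
#'   (data frame) and `devalued_by_block` (list; outcomes for `slips`,
#'   stimuli for `baseline`).
#' @export
build_schedule <- function(phase = c("training", "outcome_devaluation",
                                     "slips", "baseline"),
                           sro, seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(inherits(sro, "sro_map"))
  set.seed(seed)
  out <- switch(phase,
    training = schedule_training(sro),
    outcome_devaluation = schedule_outcome_devaluation(sro),
    slips = schedule_go_nogo(sro, devalue_on = "outcome"),
    baseline = schedule_go_nogo(sro, devalue_on = "stimulus"))
  out$phase <- phase
  class(out) <- "slips_schedule"
  out
}

schedule_training <- function(sro) {
  rows <- lapply(1:8, function(b) {
    stim <- sample(rep(sro$stimulus, 2L))
    data.frame(block = b, trial = seq_along(stim), stimulus = stim,
               correct_response = sro$response[stim],
               outcome = sro$outcome[stim], stringsAsFactors = FALSE)
  })
  list(trials = do.call(rbind, rows), devalued_by_block = NULL)
}

schedule_outcome_devaluation <- function(sro) {
  left_o <- sro$outcome[sro$response == "left"]
  right_o <- sro$outcome[sro$response == "right"]
  pairs <- expand.grid(o_left = left_o, o_right = right_o)
  # each of the 9 pairs four times, devalued side counterbalanced (2 + 2)
  trials <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(o_left = pairs$o_left[i], o_right = pairs$o_right[i],
               devalued = c(pairs$o_left[i], pairs$o_left[i],
                            pairs$o_right[i], pairs$o_right[i]))
  }))
  trials <- trials[sample(nrow(trials)), ]
  trials$block <- 1L
  trials$trial <- seq_len(nrow(trials))
  valued <- ifelse(trials$devalued == trials$o_left, trials$o_right,
                   trials$o_left)
  trials$correct_response <- sro$response[match(valued, sro$outcome)]
  rownames(trials) <- NULL
  list(trials = trials, devalued_by_block = NULL)
}

# Go/no-go test schedule: 9 blocks, each stimulus twice per block with no
# immediate repetition (also across block boundaries), two devalued items
# per block (one left- and one right-associated), each item devalued in
# exactly 3 of the 9 blocks via the full 3 x 3 pairing design.
schedule_go_nogo <- function(sro, devalue_on) {
  if (devalue_on == "outcome") {
    left_items <- sro$outcome[sro$response == "left"]
    right_items <- sro$outcome[sro$response == "right"]
  } else {
    left_items <- sro$stimulus[sro$response == "left"]
    right_items <- sro$stimulus[sro$response == "right"]
  }
  pairs <- expand.grid(left = left_items, right = right_items)
  pairs <- pairs[sample(nrow(pairs)), ]
  devalued_by_block <- lapply(seq_len(9L), function(b)
    c(pairs$left[b], pairs$right[b]))

  rows <- vector("list", 9L)
  prev_last <- NA_integer_
  for (b in 1:9) {
    stim <- order_no_repeat(rep(sro$stimulus, 2L), prev_last)
    prev_last <- stim[length(stim)]
    dv <- devalued_by_block[[b]]
    devalued <- if (devalue_on == "outcome")
      sro$outcome[stim] %in% dv else stim %in% dv
    rows[[b]] <- data.frame(block = b, trial = seq_along(stim),
                            stimulus = stim,
                            correct_response = sro$response[stim],
                            outcome = sro$outcome[stim],
                            devalued = devalued, stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, rows), devalued_by_block = devalued_by_block)
}

# Random order of `items` with no two equal neighbours and first element
# different from `prev`; rejection sampling (feasible with margin at these
# multiplicities).
order_no_repeat <- function(items, prev = NA_integer_, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    cand <- sample(items)
    if (!is.na(prev) && cand[1] == prev) next
    if (!any(cand[-1] == cand[-length(cand)])) return(cand)
  }
  stop("could not satisfy the no-immediate-repeat constraint", call. = FALSE)
}

#' Synthetic agent for the instrumental learning task
#'
#' A deliberately minimal responder: during training, per-stimulus accuracy
#' rises from chance toward `1 - eps` with an exponential learning curve of
#' rate `a_learn`; in the go/no-go test phases it responds on valued trials
#' with probability `r_base` and "slips" on devalued trials with probability
#' `r_base * (1 - g)` (goal-directedness `g` gates the suppression). In the
#' baseline phase the same rule uses `g_baseline`, near 1, because
#' stimulus-based inhibition is easy.
#'
#' @param g Goal-directedness in \[0, 1\].
#' @param r_base Response propensity on valued trials in \[0, 1\].
#' @param a_learn Training learning rate in \[0, 1\].
#' @param eps Lapse rate in \[0, 1\].
#' @param g_baseline Stimulus-based suppression in \[0, 1\] for the baseline
#'   test.
#' @return Object of class `slips_agent`.
#' @export
slips_agent <- function(g = 0.8, r_base = 0.85, a_learn = 0.3, eps = 0.02,
                        g_baseline = 0.91) {
  for (nm in c("g", "r_base", "a_learn", "eps", "g_baseline")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
  }
  structure(list(g = g, r_base = r_base, a_learn = a_learn, eps = eps,
                 g_baseline = g_baseline), class = "slips_agent")
}

#' Simulate the discrimination training phase
#'
#' Per-stimulus probability of a correct response after k previous
#' encounters is `(1 - eps) - (0.5 - eps) * (1 - a_learn)^k`, i.e. chance at
#' the first encounter approaching the `1 - eps` ceiling.
#'
#' @param agent A [slips_agent()].
#' @param schedule A training [build_schedule()].
#' @param seed Integer seed.
#' @return Data frame of trial records with `response` and `correct`.
#' @export
simulate_training <- function(agent, schedule, seed = 1L) {
  stopifnot(inherits(agent, "slips_agent"),
            inherits(schedule, "slips_schedule"),
            schedule$phase == "training")
  set.seed(seed)
  tr <- schedule$trials
  seen <- integer(6)
  n <- nrow(tr)
  correct <- logical(n); response <- character(n)
  ceiling_p <- 1 - agent$eps
  for (i in seq_len(n)) {
    s <- tr$stimulus[i]
    p <- ceiling_p - (ceiling_p - 0.5) * (1 - agent$a_learn)^seen[s]
    ok <- stats::runif(1) < p
    correct[i] <- ok
    response[i] <- if (ok) tr$correct_response[i] else
      setdiff(c("left", "right"), tr$correct_response[i])
    seen[s] <- seen[s] + 1L
  }
  cbind(tr, data.frame(response = response, correct = correct,
                       stringsAsFactors = FALSE))
}

#' Simulate the outcome-devaluation test phase
#'
#' The agent chooses the response leading to the valued outcome with
#' probability tied to its goal-directedness: `0.5 + 0.5 * g`, minus lapses.
#'
#' @param agent A [slips_agent()].
#' @param schedule An outcome-devaluation [build_schedule()].
#' @param seed Integer seed.
#' @return Data frame of trial records with `response` and `correct`.
#' @export
simulate_outcome_devaluation <- function(agent, schedule, seed = 1L) {
  stopifnot(inherits(agent, "slips_agent"),
            inherits(schedule, "slips_schedule"),
            schedule$phase == "outcome_devaluation")
  set.seed(seed)
  tr <- schedule$trials
  p_correct <- (0.5 + 0.5 * agent$g) * (1 - agent$eps)
  ok <- stats::runif(nrow(tr)) < p_correct
  response <- ifelse(ok, tr$correct_response,
                     ifelse(tr$correct_response == "left", "right", "left"))
  cbind(tr, data.frame(response = response, correct = ok,
                       stringsAsFactors = FALSE))
}

#' Simulate a go/no-go test phase (slips or baseline)
#'
#' Responds on valued trials with probability `r_base`; responds (slips) on
#' devalued trials with probability `r_base * (1 - g)` in the slips phase
#' and `r_base * (1 - g_baseline)` in the baseline phase. Emitted responses
#' use the trained response side.
#'
#' @param agent A [slips_agent()].
#' @param schedule A slips or baseline [build_schedule()].
#' @param seed Integer seed.
#' @return Data frame of trial records with `response` (`"left"`, `"right"`
#'   or `"none"`), `responded` and `correct` (responding on a valued trial
#'   or withholding on a devalued one).
#' @export
simulate_test_phase <- function(agent, schedule, seed = 1L) {
  stopifnot(inherits(agent, "slips_agent"),
            inherits(schedule, "slips_schedule"),
            schedule$phase %in% c("slips", "baseline"))
  set.seed(seed)
  tr <- schedule$trials
  gg <- if (schedule$phase == "slips") agent$g else agent$g_baseline
  p_go <- ifelse(tr$devalued, agent$r_base * (1 - gg), agent$r_base)
  responded <- stats::runif(nrow(tr)) < p_go
  response <- ifelse(responded, tr$correct_response, "none")
  correct <- responded != tr$devalued
  cbind(tr, data.frame(response = response, responded = responded,
                       correct = correct, stringsAsFactors = FALSE))
}

#' Score one phase of the instrumental learning task
#'
#' Training: percentage correct per block and overall. Outcome devaluation:
#' percentage correct. Slips/baseline: percentage of responses on valued
#' trials, on devalued trials, and their difference — the devaluation
#' sensitivity index (DSI) for the slips phase. By default the two
#' percentages are computed per trial type (responses on valued trials out
#' of valued trials, likewise devalued); `normalization = "total_responses"`
#' instead divides both counts by the total number of responses emitted.
#'
#' @param records Trial records from one of the `simulate_*` functions (or
#'   imported data with the same columns).
#' @param phase Phase name; defaults to the `phase` attribute-free guess
#'   from the columns is not attempted — pass it explicitly.
#' @param normalization `"per_trial_type"` (default) or
#'   `"total_responses"`.
#' @return A list of class `slips_scores`; for the go/no-go phases it has
#'   `pct_valued`, `pct_devalued` and `dsi` (in percentage points).
#' @export
score_phase <- function(records, phase = c("training", "outcome_devaluation",
                                           "slips", "baseline"),
                        normalization = c("per_trial_type",
                                          "total_responses")) {
  phase <- match.arg(phase)
  normalization <- match.arg(normalization)
  out <- switch(phase,
    training = {
      expected <- 96L
      if (nrow(records) < expected)
        warning("fewer training trials than the full schedule; ",
                "scoring available trials")
      blk <- tapply(records$correct, records$block, mean) * 100
      list(block_pct = as.numeric(blk),
           overall_pct = mean(records$correct) * 100)
    },
    outcome_devaluation = list(pct_correct = mean(records$correct) * 100),
    {
      dev <- as.logical(records$devalued)   # robust to 0/1 CSV re-import
      resp <- as.logical(records$responded)
      n_val <- sum(!dev); n_dev <- sum(dev)
      if (n_val == 0L || n_dev == 0L)
        stop("need both valued and devalued trials to score", call. = FALSE)
      k_val <- sum(resp[!dev])
      k_dev <- sum(resp[dev])
      if (normalization == "per_trial_type") {
        pv <- 100 * k_val / n_val
        pd <- 100 * k_dev / n_dev
      } else {
        tot <- k_val + k_dev
        pv <- if (tot == 0L) 0 else 100 * k_val / tot
        pd <- if (tot == 0L) 0 else 100 * k_dev / tot
      }
      list(pct_valued = pv, pct_devalued = pd, dsi = pv - pd)
    })
  out$phase <- phase
  class(out) <- "slips_scores"
  out
}

#' Simulate all four phases of the instrumental task for one subject
#'
#' @param agent A [slips_agent()].
#' @param sro An [sro_map()].
#' @param seed Integer seed (distinct sub-seeds per phase).
#' @return Named list of trial-record data frames:
#'   `training`, `outcome_devaluation`, `slips`, `baseline`.
#' @export
simulate_slips_subject <- function(agent, sro, seed = 1L) {
  phases <- c("training", "outcome_devaluation", "slips", "baseline")
  out <- vector("list", 4L); names(out) <- phases
  for (i in seq_along(phases)) {
    sch <- build_schedule(phases[i], sro, seed = seed + i * 101L)
    out[[i]] <- switch(phases[i],
      training = simulate_training(agent, sch, seed = seed + i * 101L + 1L),
      outcome_devaluation =
        simulate_outcome_devaluation(agent, sch, seed = seed + i * 101L + 1L),
      simulate_test_phase(agent, sch, seed = seed + i * 101L + 1L))
    out[[i]]$phase <- phases[i]
  }
  out
}
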