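test_that("the S-R-O map balances response sides with unique outcomes", {
  for (seed in 1:20) {
    m <- sro_map(seed)
    expect_equal(sum(m$response == "left"), 3L)
    expect_equal(sum(m$response == "right"), 3L)
    expect_equal(sort(m$outcome), 1:6)
  }
})

test_that("training schedules show each stimulus twice per block", {
  sch <- build_schedule("training", sro_map(1), seed = 2)
  tr <- sch$trials
  expect_equal(nrow(tr), 96L)
  expect_equal(max(tr$block), 8L)
  expect_true(all(table(tr$stimulus) == 16L))
  per_block <- table(tr$block, tr$stimulus)
  expect_true(all(per_block == 2L))
})

test_that("outcome-devaluation schedules pair sides and counterbalance", {
  m <- sro_map(3)
  sch <- build_schedule("outcome_devaluation", m, seed = 4)
  tr <- sch$trials
  expect_equal(nrow(tr), 36L)
  left_o <- m$outcome[m$response == "left"]
  right_o <- m$outcome[m$response == "right"]
  expect_true(all(tr$o_left %in% left_o))
  expect_true(all(tr$o_right %in% right_o))
  expect_true(all(tr$devalued == tr$o_left | tr$devalued == tr$o_right))
  # every pair 4 times, devalued side split 2/2
  expect_true(all(table(tr$o_left, tr$o_right) == 4L))
  dev_left <- tapply(tr$devalued == tr$o_left,
                     paste(tr$o_left, tr$o_right), sum)
  expect_true(all(dev_left == 2L))
  # the correct response opens the still-valued outcome
  valued <- ifelse(tr$devalued == tr$o_left, tr$o_right, tr$o_left)
  expect_equal(tr$correct_response, m$response[match(valued, m$outcome)])
})

test_that("slips schedules meet the devaluation and repetition design", {
  m <- sro_map(5)
  for (seed in 1:100) {
    sch <- build_schedule("slips", m, seed = seed)
    tr <- sch$trials
    expect_equal(nrow(tr), 108L)
    expect_equal(sum(tr$devalued), 36L)
    expect_equal(sum(!tr$devalued), 72L)
    expect_true(all(table(tr$block, tr$stimulus) == 2L))
    # no stimulus is ever directly repeated, block boundaries included
    expect_true(all(tr$stimulus[-1] != tr$stimulus[-nrow(tr)]))
    # each outcome devalued in exactly 3 of 9 blocks, one per side
    dv <- do.call(rbind, sch$devalued_by_block)
    expect_true(all(table(c(dv)) == 3L))
    left_o <- m$outcome[m$response == "left"]
    expect_true(all(dv[, 1] %in% left_o))
  }
})

test_that("baseline schedules devalue stimuli with the same balance", {
  m <- sro_map(6)
  sch <- build_schedule("baseline", m, seed = 7)
  tr <- sch$trials
  expect_equal(nrow(tr), 108L)
  expect_equal(sum(tr$devalued), 36L)
  dv <- do.call(rbind, sch$devalued_by_block)
  expect_true(all(table(c(dv)) == 3L))
  expect_true(all(dv[, 1] %in% m$stimulus[m$response == "left"]))
})

test_that("training simulation spans chance to ceiling with learning", {
  m <- sro_map(8)
  sch <- build_schedule("training", m, seed = 9)
  fast <- simulate_training(slips_agent(a_learn = 0.95, eps = 0),
                            sch, seed = 1)
  expect_gt(mean(fast$correct[fast$block == 8]), 0.95)
  flat <- do.call(rbind, lapply(1:40, function(s)
    simulate_training(slips_agent(a_learn = 0), sch, seed = s)))
  expect_equal(mean(flat$correct), 0.5, tolerance = 0.03)
  # mean learning curves rise across blocks
  many <- do.call(rbind, lapply(1:100, function(s)
    simulate_training(slips_agent(a_learn = 0.3, eps = 0.02),
                      sch, seed = 100 + s)))
  curve <- tapply(many$correct, many$block, mean)
  expect_true(all(diff(curve) > -0.02))
  expect_gt(curve[8], curve[1] + 0.3)
})

test_that("go/no-go simulation realizes the response model", {
  m <- sro_map(10)
  sch <- build_schedule("slips", m, seed = 11)
  ideal <- simulate_test_phase(slips_agent(g = 1, r_base = 1), sch, seed = 1)
  sc <- score_phase(ideal, "slips")
  expect_equal(sc$pct_valued, 100)
  expect_equal(sc$pct_devalued, 0)
  expect_equal(sc$dsi, 100)
  # a pure stimulus-response agent shows no devaluation sensitivity
  habitual <- do.call(rbind, lapply(1:50, function(s)
    simulate_test_phase(slips_agent(g = 0, r_base = 0.8), sch, seed = s)))
  pv <- mean(habitual$responded[!habitual$devalued])
  pd <- mean(habitual$responded[habitual$devalued])
  expect_equal(pv - pd, 0, tolerance = 0.03)
  # emitted responses reuse the trained side
  expect_true(all(ideal$response[ideal$responded] ==
                    ideal$correct_response[ideal$responded]))
})

test_that("scoring reproduces hand-computed percentages and the DSI", {
  rec <- data.frame(devalued = c(rep(FALSE, 72), rep(TRUE, 36)),
                    responded = c(rep(TRUE, 60), rep(FALSE, 12),
                                  rep(TRUE, 9), rep(FALSE, 27)))
  sc <- score_phase(rec, "slips")
  expect_equal(sc$pct_valued, 100 * 60 / 72)
  expect_equal(sc$pct_devalued, 25)
  expect_equal(sc$dsi, 100 * 60 / 72 - 25)
  # the literal total-responses normalization is available as a switch
  sc2 <- score_phase(rec, "slips", normalization = "total_responses")
  expect_equal(sc2$pct_valued, 100 * 60 / 69)
  expect_equal(sc2$pct_devalued, 100 * 9 / 69)
  # indiscriminate responder: zero difference under either convention
  all_go <- data.frame(devalued = c(rep(FALSE, 72), rep(TRUE, 36)),
                       responded = TRUE)
  expect_equal(score_phase(all_go, "slips")$dsi, 0)
})

test_that("DSI expectation is 100 * r_base * g under the response model", {
  m <- sro_map(12)
  sch <- build_schedule("slips", m, seed = 13)
  for (pars in list(c(g = 0.8, r = 0.9), c(g = 0.5, r = 0.7))) {
    recs <- do.call(rbind, lapply(1:100, function(s)
      simulate_test_phase(slips_agent(g = pars["g"], r_base = pars["r"]),
                          sch, seed = 200 + s)))
    pv <- 100 * mean(recs$responded[!recs$devalued])
    pd <- 100 * mean(recs$responded[recs$devalued])
    expect_equal(pv - pd, 100 * pars[["r"]] * pars[["g"]], tolerance = 2.5)
  }
})

test_that("baseline inhibition outperforms outcome-based inhibition", {
  m <- sro_map(14)
  agent <- slips_agent(g = 0.8, r_base = 0.9, g_baseline = 0.95)
  slips_dsi <- numeric(30); base_diff <- numeric(30)
  for (s in 1:30) {
    subj <- simulate_slips_subject(agent, m, seed = 500 + s)
    slips_dsi[s] <- score_phase(subj$slips, "slips")$dsi
    base_diff[s] <- score_phase(subj$baseline, "baseline")$dsi
  }
  expect_gt(mean(base_diff), mean(slips_dsi))
})
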