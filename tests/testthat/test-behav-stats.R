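test_that("stay probabilities match hand counts on a built fixture", {
  # 8 trials; classification uses the PREVIOUS trial's reward/transition
  tr <- data.frame(
    t = 1:8,
    a1 = c(1, 1, 2, 2, 2, 1, 1, 1),
    state2 = c(1, 2, 2, 1, 2, 1, 2, 1),
    transition = c("common", "rare", "common", "rare",
                   "common", "common", "rare", "common"),
    a2 = 1, r = c(1, 0, 1, 1, 0, 0, 1, 1),
    valid = TRUE, practice = FALSE)
  st <- stay_probability_table(tr)
  # hand enumeration of the 7 transitions between consecutive trials:
  # prev (r=1,common): t1->2 stay, t3->4 stay, t7->8 stay  => 3/3
  # prev (r=0,rare):   t2->3 switch                        => 0/1
  # prev (r=1,rare):   t4->5 stay                          => 1/1
  # prev (r=0,common): t5->6 switch, t6->7 stay            => 1/2
  expect_equal(st$rewarded_common, 1)
  expect_equal(st$unrewarded_rare, 0)
  expect_equal(st$rewarded_rare, 1)
  expect_equal(st$unrewarded_common, 0.5)
  expect_equal(st$n_rewarded_common + st$n_rewarded_rare +
                 st$n_unrewarded_common + st$n_unrewarded_rare,
               nrow(tr) - 1)
})

test_that("constant policies produce all-ones or all-zeros stay tables", {
  cfg <- twostep_config(n_trials = 60)
  stay <- run_session(function(h, s2, t) 1L, cfg, seed = 1)
  st <- stay_probability_table(stay)
  expect_true(all(st[, 1:4][!is.na(st[, 1:4])] == 1))
  alt <- run_session(function(h, s2, t)
    if (is.na(s2)) as.integer(1 + t %% 2) else 1L, cfg, seed = 2)
  st2 <- stay_probability_table(alt)
  expect_true(all(st2[, 1:4][!is.na(st2[, 1:4])] == 0))
})

test_that("contrast-based RM-ANOVA equals the sums-of-squares oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    cells <- data.frame(rewarded_common = runif(n),
                        rewarded_rare = runif(n),
                        unrewarded_common = runif(n),
                        unrewarded_rare = runif(n))
    got <- rm_anova_2x2(cells)
    want <- oracle_rm_anova(cells)
    expect_equal(got$F[got$effect == "reward"],
                 unname(want$reward["F"]), tolerance = 1e-10)
    expect_equal(got$F[got$effect == "state"],
                 unname(want$state["F"]), tolerance = 1e-10)
    expect_equal(got$F[got$effect == "reward:state"],
                 unname(want$interaction["F"]), tolerance = 1e-10)
    expect_equal(got$p[got$effect == "reward:state"],
                 unname(want$interaction["p"]), tolerance = 1e-10)
  }
})

test_that("RM-ANOVA handles null and degenerate inputs", {
  cells <- data.frame(rewarded_common = rep(0.6, 5),
                      rewarded_rare = rep(0.6, 5),
                      unrewarded_common = rep(0.6, 5),
                      unrewarded_rare = rep(0.6, 5))
  got <- rm_anova_2x2(cells)
  expect_true(all(got$F == 0))
  expect_true(all(got$p == 1))
  cells$rewarded_common[1] <- NA
  expect_warning(rm_anova_2x2(cells), "dropped")
})

test_that("Friedman wrapper matches the hand-computed rank statistic", {
  m <- matrix(c(7, 9, 8,
                6, 5, 7,
                9, 7, 6,
                4, 5, 6), nrow = 4, byrow = TRUE)
  got <- friedman_blocks(m)
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  n <- nrow(m); k <- ncol(m)
  chi <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  expect_equal(got$chisq, chi, tolerance = 1e-10)
  expect_equal(got$df, k - 1)
  # complete ties carry no evidence
  flat <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(friedman_blocks(flat)$chisq, 0)
  expect_error(friedman_blocks(m[, 1, drop = FALSE]), "two blocks")
})

test_that("a learning cohort yields a significant Friedman block effect", {
  m <- sro_map(21)
  sch <- build_schedule("training", m, seed = 22)
  hits <- 0L
  for (s in 1:10) {
    blocks <- t(sapply(1:28, function(i) {
      rec <- simulate_training(slips_agent(a_learn = 0.3), sch,
                               seed = 1000 * s + i)
      score_phase(rec, "training")$block_pct
    }))
    if (friedman_blocks(blocks)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("signed-rank Z matches the normal-approximation reference", {
  x <- c(12, 14, 9, 16, 11, 13, 18, 10, 15, 17)
  y <- c(10, 15, 8, 11, 10, 16, 13, 9, 12, 11)
  got <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$V, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  swapped <- wilcoxon_signed_rank(y, x)
  expect_equal(swapped$Z, -got$Z)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
})

test_that("exact binomial tail matches brute-force summation", {
  k <- 15; n <- 20
  brute <- sum(choose(n, k:n) * 0.5^n)
  expect_equal(binomial_above_chance(k, n, 0.5), brute, tolerance = 1e-12)
  expect_equal(binomial_above_chance(20, 20, 0.5), 0.5^20)
  expect_equal(binomial_above_chance(0, 20, 0.5), 1)
  # cohort mode: 28 of 28 subjects above chance
  expect_lt(binomial_above_chance(28, 28, 0.5), 0.001)
})
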