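# Exact nonparametric tests and strategy-switch inference.

test_that("exact signed-rank p-values match closed forms and enumeration", {
  # six positive differences, one-sided: only 1 of 2^6 sign patterns is as
  # extreme
  res <- signed_rank_test(c(1, 2, 3, 4, 5, 6), mu0 = 0, "greater")
  expect_identical(res$p_value, 1 / 64)
  expect_true(res$exact)

  # values symmetric about mu0: two-sided p = 1
  sym <- signed_rank_test(c(-1, 1, -2, 2), mu0 = 0, "two_sided")
  expect_equal(sym$p_value, 1)

  # tie-aware DP vs brute-force sign enumeration, several data sets
  set.seed(14)
  for (i in 1:10) {
    x <- round(rnorm(8), digits = sample(0:1, 1))  # induce ties often
    x <- x[x != 0]
    if (length(x) < 2) next
    r <- rank(abs(x))
    w <- sum(r[x > 0])
    tails <- signed_rank_enum(r, w)
    expect_equal(signed_rank_test(x, 0, "greater")$p_value,
                 unname(tails["ge"]))
    expect_equal(signed_rank_test(x, 0, "less")$p_value,
                 unname(tails["le"]))
  }
})

test_that("exact signed-rank agrees with wilcox.test on tie-free data", {
  set.seed(2)
  for (i in 1:8) {
    x <- rnorm(10) + 0.4
    for (alt in c("two_sided", "greater", "less")) {
      ours <- signed_rank_test(x, 0, alt)$p_value
      ref <- stats::wilcox.test(
        x, mu = 0, exact = TRUE,
        alternative = sub("two_sided", "two.sided", alt))$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("the normal approximation tracks the exact path", {
  set.seed(8)
  x <- rnorm(18, mean = 0.3)
  for (alt in c("two_sided", "greater", "less")) {
    p_exact <- signed_rank_test(x, 0, alt, exact_max = 20)$p_value
    p_approx <- signed_rank_test(x, 0, alt, exact_max = 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("degenerate signed-rank inputs are handled explicitly", {
  expect_warning(res <- signed_rank_test(rep(0.5, 6), mu0 = 0.5), "zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$n, 0L)
  # zero differences are dropped, not counted
  res2 <- signed_rank_test(c(0, 0, 1, 2, 3), mu0 = 0, "greater")
  expect_equal(res2$n, 3L)
  expect_identical(res2$p_value, 1 / 8)
})

test_that("above-chance tests use the supplied enumerated chance level", {
  ch <- chance_level(6, 3, "correct")
  res <- test_above_chance(rep(0.9, 18), ch)
  expect_lt(res$p_value, 0.001)
  expect_identical(res$p_value, 2^-18)
  expect_equal(res$chance, ch)
  expect_warning(flat <- test_above_chance(rep(ch, 10), ch), "zero")
  expect_equal(flat$p_value, 1)
})

test_that("Spearman rho and exact permutation p behave correctly", {
  expect_equal(spearman_correlation(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8))$rho, -1)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")

  # exact permutation p vs an independent brute-force enumeration (with and
  # without ties)
  set.seed(21)
  for (i in 1:5) {
    x <- sample(1:20, 6); y <- sample(1:20, 6)
    if (i > 3) y[2] <- y[1]  # tie
    expect_equal(spearman_correlation(x, y)$p_value, spearman_enum_p(x, y))
  }
})

test_that("exact Spearman p matches cor.test for tie-free n = 8", {
  set.seed(4)
  for (i in 1:5) {
    x <- sample(1:100, 8); y <- sample(1:100, 8)
    ours <- spearman_correlation(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(ours$rho, unname(ref$estimate))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # beyond the exact range the t approximation is used
  big <- spearman_correlation(1:12 + rnorm(12), 1:12 + rnorm(12))
  expect_false(big$exact)
})

test_that("switch detection labels blocks and finds the changepoint", {
  # constructed cohort summaries: block 1 rule-like, block 2 WSLS-like
  set.seed(6)
  jitter18 <- function(mu) pmin(1, pmax(0, mu + runif(18, -0.03, 0.03)))
  summaries <- rbind(
    data.frame(bee_id = sprintf("b%02d", 1:18), block_index = 1,
               accuracy_first = jitter18(0.75),
               p_win_stay = jitter18(0.40), p_lose_switch = jitter18(0.60),
               accuracy_all = jitter18(0.6), accuracy_second = jitter18(0.5),
               mean_choices_per_bout = 7, partial = FALSE),
    data.frame(bee_id = sprintf("b%02d", 1:18), block_index = 2,
               accuracy_first = jitter18(0.50),
               p_win_stay = jitter18(0.70), p_lose_switch = jitter18(0.85),
               accuracy_all = jitter18(0.7), accuracy_second = jitter18(0.75),
               mean_choices_per_bout = 5, partial = FALSE))
  sw <- detect_strategy_switch(summaries, arena_config(), alpha = 0.05)
  expect_equal(sw$blocks$label, c("rule", "wsls"))
  expect_equal(sw$switch_block, 2)

  # a single block cannot carry switch evidence
  expect_error(detect_strategy_switch(
    summaries[summaries$block_index == 1, ]), "2 blocks")

  # Holm adjustment only ever raises the per-block p-values
  sw_holm <- detect_strategy_switch(summaries, arena_config(),
                                    p_adjust = "holm")
  for (col in c("p_rule", "p_win_stay", "p_lose_switch"))
    expect_true(all(sw_holm$blocks[[col]] >= sw$blocks[[col]]))

  # a block with undefined statistics is labelled indeterminate
  broken <- summaries
  broken$p_lose_switch[broken$block_index == 2] <- NA
  sw_na <- detect_strategy_switch(broken, arena_config())
  expect_equal(sw_na$blocks$label[2], "indeterminate")
  expect_true(is.na(sw_na$blocks$wsls_evidence[2]))
})

test_that("switch detection recovers a hybrid cohort and spares a rule cohort", {
  log <- simulate_cohort(18, c(larger = 10, smaller = 8),
                         agent_spec("hybrid", switch_bout = 21),
                         master_seed = 101)
  sw <- detect_strategy_switch(block_summaries(log, 10))
  expect_equal(sw$switch_block, 3L)
  expect_equal(sw$blocks$label[1:2], c("rule", "rule"))

  log2 <- simulate_cohort(18, c(larger = 10, smaller = 8),
                          agent_spec("rule"), master_seed = 102)
  sw2 <- detect_strategy_switch(block_summaries(log2, 10))
  expect_true(is.na(sw2$switch_block))
})

test_that("split-half analysis splits at the midpoint and tests one-sided", {
  # 5 choices: first half = choices 1-3, second half = 4-5
  log <- make_log(list(c(1, 1, 0, 1, 0)), phase = "learning_test")
  sh <- split_half_test_performance(log)
  expect_equal(sh$per_bee$first_half, 2 / 3)
  expect_equal(sh$per_bee$second_half, 1 / 2)

  # 18 bees all improving: exact one-sided p = 2^-18
  bees <- lapply(1:18, function(i) list(c(0, 0, 1, 1)))
  names(bees) <- sprintf("b%02d", 1:18)
  log2 <- make_cohort_log(bees, phase = "learning_test")
  sh2 <- split_half_test_performance(log2)
  expect_identical(sh2$test$p_value, 2^-18)
  expect_lt(sh2$test$p_value, 0.001)

  # equal halves: degenerate p = 1
  log3 <- make_log(list(c(1, 1, 1, 1)), phase = "learning_test")
  expect_warning(sh3 <- split_half_test_performance(log3), "zero")
  expect_equal(sh3$test$p_value, 1)
})

test_that("a reverting hybrid agent improves across test halves", {
  # hybrid agents start tests with (uninformative) WSLS and revert to the
  # learned rule: the second half of test choices should beat the first in
  # the clear majority of replicate cohorts
  better <- vapply(1:20, function(r) {
    log <- simulate_cohort(18, c(larger = 10, smaller = 8),
                           agent_spec("hybrid", switch_bout = 21),
                           master_seed = 500 + r)
    sh <- suppressWarnings(split_half_test_performance(log))
    sh$mean_second > sh$mean_first
  }, logical(1))
  expect_gt(mean(better), 0.5)
})

test_that("training-test correlation wires block accuracy to test accuracy", {
  log <- simulate_cohort(12, c(larger = 6, smaller = 6),
                         agent_spec("hybrid", switch_bout = 21),
                         master_seed = 77)
  bs <- block_summaries(log, 10)
  ta <- test_accuracy(log, "learning_test")
  res <- training_test_correlation(bs, ta, block = 2)
  expect_true(is.finite(res$rho))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_error(training_test_correlation(bs, ta[1:2]), "at least 3")
})
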