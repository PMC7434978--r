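# Block accuracies, conditional probabilities, chance levels, bout lengths
# and spatial transition ranks.

test_that("block accuracy counts all / first / second choices correctly", {
  log <- make_log(list(c(1, 0, 1, 1)))
  expect_equal(block_accuracy(log, 10, "all")$accuracy, 0.75)
  expect_equal(block_accuracy(log, 10, "first")$accuracy, 1)
  expect_equal(block_accuracy(log, 10, "second")$accuracy, 0)

  all_correct <- make_log(list(c(1, 1, 1), c(1, 1, 1, 1)))
  for (w in c("all", "first", "second"))
    expect_equal(block_accuracy(all_correct, 10, w)$accuracy, 1)
})

test_that("empty denominators yield NA, never zero", {
  # single-choice bouts: no second choices at all
  log <- make_log(list(1, 0, 1))
  expect_true(is.na(block_accuracy(log, 10, "second")$accuracy))
  expect_equal(block_accuracy(log, 10, "first")$accuracy, 2 / 3)
})

test_that("trailing partial blocks are retained and flagged", {
  log <- make_log(rep(list(c(1, 0, 1)), 13))
  ba <- block_accuracy(log, 10, "all")
  expect_equal(nrow(ba), 2L)
  expect_equal(ba$partial, c(FALSE, TRUE))
  expect_equal(ba$n_choices, c(30L, 9L))
})

test_that("conditional probabilities match direct counts", {
  # 10 bouts: 6 with c1 correct (3 of those c2 correct),
  #           4 with c1 incorrect (3 of those c2 correct)
  bouts <- c(rep(list(c(1, 1)), 3), rep(list(c(1, 0)), 3),
             rep(list(c(0, 1)), 3), rep(list(c(0, 0)), 1))
  cp <- conditional_second_given_first(make_log(bouts))
  expect_equal(cp$p_win_stay, 0.5)
  expect_equal(cp$p_lose_switch, 0.75)
  expect_equal(cp$per_bee$p_first, 0.6)
  expect_equal(cp$per_bee$second_accuracy, 0.6)
})

test_that("an empty conditioning margin is undefined and warned about", {
  always_right <- make_log(rep(list(c(1, 1)), 5))
  expect_warning(cp <- conditional_second_given_first(always_right),
                 "lose-switch")
  expect_equal(cp$per_bee$p_win_stay, 1)
  expect_true(is.na(cp$per_bee$p_lose_switch))
  expect_error(conditional_second_given_first(make_log(list(1, 0, 1))),
               ">= 2")
})

test_that("law of total probability holds exactly on simulated data", {
  log <- simulate_cohort(5, c(larger = 3, smaller = 2), master_seed = 17,
                         n_bouts = 20)
  cp <- suppressWarnings(conditional_second_given_first(log))
  pb <- cp$per_bee
  ok <- !is.na(pb$p_win_stay) & !is.na(pb$p_lose_switch)
  lhs <- pb$p_first[ok] * pb$p_win_stay[ok] +
    (1 - pb$p_first[ok]) * pb$p_lose_switch[ok]
  expect_equal(lhs, pb$second_accuracy[ok], tolerance = 1e-12)
})

test_that("chance levels agree exactly with exhaustive enumeration", {
  # the default arena's three levels
  expect_equal(chance_level(6, 3, "correct"), 0.4)
  expect_equal(chance_level(6, 3, "incorrect"), 0.6)
  expect_equal(chance_level(6, 3, "none"), 0.5)
  expect_equal(chance_level(2, 1, "correct"), 0)
  for (n in 2:8) for (k in seq_len(n - 1)) for (o in c("none", "correct",
                                                       "incorrect"))
    expect_equal(chance_level(n, k, o), chance_enum(n, k, o),
                 info = sprintf("n=%d k=%d %s", n, k, o))
  expect_error(chance_level(6, 0), "n_rewarded")
  expect_error(chance_level(6, 6), "n_rewarded")
})

test_that("accuracy over a block lies between per-bout extremes", {
  log <- simulate_bee(agent_spec("hybrid", switch_bout = 11), n_bouts = 20,
                      seed = 23)
  tr <- log[log$phase == "training", ]
  per_bout <- tapply(tr$correct, tr$bout_index, mean)
  blk <- assign_blocks(as.integer(names(per_bout)), 10)
  ba <- block_accuracy(log, 10, "all")
  for (b in unique(blk)) {
    expect_gte(ba$accuracy[ba$block_index == b], min(per_bout[blk == b]))
    expect_lte(ba$accuracy[ba$block_index == b], max(per_bout[blk == b]))
  }
})

test_that("choices per bout summarise bout lengths", {
  log <- make_log(list(rep(1, 7) * c(1, 0, 1, 0, 1, 1, 1),
                       c(0, 1, 1, 0, 0, 1, 1),
                       c(1, 1, 0, 1, 1, 0, 1)))
  cpb <- choices_per_bout(log, 10)
  expect_equal(cpb$summary$mean, 7)
  expect_equal(cpb$summary$sem, 0)
  # a perfect non-revisiting agent needs exactly 3 choices
  perfect <- simulate_bee(agent_spec("rule", rule_accuracy_min = 1,
                                     rule_accuracy_max = 1),
                          n_bouts = 10, seed = 1)
  tr <- perfect[perfect$phase == "training", ]
  lens <- tapply(tr$choice_index, tr$bout_index, max)
  # the rule agent may revisit a drained correct disc, so lengths can
  # exceed 3, but never fall below the number of rewards
  expect_true(all(lens >= 3))
})

test_that("WSLS bouts are shorter than random bouts on average", {
  set.seed(99)
  arena <- arena_config()
  st <- build_stimulus_set("circle", "black", c("small", "large"), "larger")
  mean_len <- function(agent, n) {
    mean(replicate(n, nrow(simulate_bout(agent, arena, st, 1L))))
  }
  len_rand <- mean_len(agent_spec("random"), 1000)
  len_wsls <- mean_len(agent_spec("wsls"), 1000)
  expect_lt(len_wsls, len_rand)
})

test_that("spatial ranks match the enumerated uniform expectation", {
  # uniform transitions: compare the package enumeration and MC simulation
  # against an independently coded enumeration of the 6x5 ordered pairs
  oracle <- uniform_rank_enum()
  null <- uniform_transition_ranks(arena_config())
  expect_equal(null$nearest_rate, oracle$nearest_rate)
  expect_equal(null$mean_rank, oracle$mean_rank)

  log <- simulate_cohort(6, c(larger = 3, smaller = 3),
                         agent_spec("random"), master_seed = 55)
  sm <- spatial_transition_metrics(log)
  se <- sqrt(oracle$nearest_rate * (1 - oracle$nearest_rate) /
               sm$n_transitions)
  expect_lt(abs(sm$nearest_rate - oracle$nearest_rate), 3 * se)
  expect_equal(sum(sm$rank_counts$proportion), 1)
})

test_that("spatial metrics handle degenerate input", {
  log <- make_log(list(1, 0))   # single-choice bouts: no transitions
  sm <- spatial_transition_metrics(log)
  expect_equal(sm$n_transitions, 0L)
  expect_true(is.na(sm$nearest_rate))
  bad <- make_log(list(c(1, 1)))
  bad$disc_x <- NA_real_
  expect_error(spatial_transition_metrics(bad), "coordinates")
})

test_that("block summaries assemble the per-bee, per-block table", {
  log <- simulate_cohort(4, c(larger = 2, smaller = 2), master_seed = 13,
                         n_bouts = 20)
  bs <- block_summaries(log, 10)
  expect_equal(nrow(bs), 8L)
  expect_setequal(names(bs),
                  c("bee_id", "block_index", "partial", "accuracy_all",
                    "accuracy_first", "accuracy_second", "p_win_stay",
                    "p_lose_switch", "mean_choices_per_bout"))
  expect_true(all(bs$mean_choices_per_bout >= 3))
  ok <- !is.na(bs$accuracy_all)
  expect_true(all(bs$accuracy_all[ok] >= 0 & bs$accuracy_all[ok] <= 1))
})
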