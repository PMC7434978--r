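# Contracts of the agent-based bout generator.

bout_split <- function(log) split(log, paste(log$bee_id, log$bout_index))

test_that("training bouts terminate at 3 rewards or the landing cap", {
  log <- simulate_bee(agent_spec("random"), seed = 11)
  arena <- arena_config()
  for (b in bout_split(log[log$phase %in% c("training", "refresh"), ])) {
    expect_true(sum(b$reward_received) == arena$n_rewarded ||
                  nrow(b) == arena$max_choices_per_bout)
    expect_lte(sum(b$reward_received), arena$n_rewarded)
    expect_true(all(b$reward_received <= b$correct))  # reward => correct
  }
})

test_that("test bouts are unrewarded and of fixed length", {
  log <- simulate_bee(agent_spec("hybrid", switch_bout = 21), seed = 3,
                      n_test_choices = 8)
  tests <- log[grepl("test", log$phase), ]
  expect_false(any(tests$reward_received))
  lens <- tapply(tests$choice_index, paste(tests$phase, tests$bout_index),
                 max)
  expect_true(all(lens == 8))
  expect_setequal(unique(tests$phase),
                  c("learning_test", "novel_shape_test", "novel_color_test"))
})

test_that("consecutive landings are never on the same disc", {
  for (strat in c("random", "wsls", "proximity"))
    for (b in bout_split(simulate_bee(agent_spec(strat), n_bouts = 10,
                                      seed = 5))) {
      if (nrow(b) > 1)
        expect_true(all(diff(b$disc_id) != 0 | is.na(diff(b$disc_id))),
                    info = strat)
    }
})

test_that("identical seeds reproduce bouts and cohorts bit-for-bit", {
  a <- agent_spec("hybrid", switch_bout = 21)
  expect_identical(simulate_bee(a, seed = 42), simulate_bee(a, seed = 42))
  c1 <- simulate_cohort(4, c(larger = 2, smaller = 2), a, master_seed = 42,
                        n_bouts = 8)
  c2 <- simulate_cohort(4, c(larger = 2, smaller = 2), a, master_seed = 42,
                        n_bouts = 8)
  expect_identical(c1, c2)
})

test_that("cohorts have the requested structure", {
  log <- simulate_cohort(6, c(larger = 4, smaller = 2), master_seed = 9,
                         n_bouts = 12)
  expect_equal(length(unique(log$bee_id)), 6L)
  tr <- log[log$phase == "training", ]
  expect_equal(as.vector(table(tapply(tr$bout_index, tr$bee_id,
                                      function(x) length(unique(x))))), 6L)
  expect_true(all(tapply(tr$bout_index, tr$bee_id, max) == 12))
  grp <- tapply(log$group, log$bee_id, `[`, 1)
  expect_equal(sum(grp == "larger"), 4L)
  expect_equal(sum(grp == "smaller"), 2L)
  expect_error(simulate_cohort(5, c(larger = 3, smaller = 3)), "sum")
  expect_error(simulate_cohort(2, c(big = 1, small = 1)), "named")
})

test_that("each bee runs three distinct unrewarded tests", {
  log <- simulate_cohort(3, c(larger = 2, smaller = 1), master_seed = 2,
                         n_bouts = 5)
  for (b in unique(log$bee_id)) {
    ph <- unique(log$phase[log$bee_id == b])
    expect_true(all(c("learning_test", "novel_shape_test",
                      "novel_color_test") %in% ph))
  }
})

test_that("a proximity agent always lands on the nearest available disc", {
  log <- simulate_bee(agent_spec("proximity"), n_bouts = 20, seed = 8)
  sm <- spatial_transition_metrics(log)
  expect_equal(sm$nearest_rate, 1)
})

test_that("a fully learned rule agent makes only correct first choices", {
  a <- agent_spec("rule", rule_accuracy_min = 1, rule_accuracy_max = 1)
  log <- simulate_bee(a, n_bouts = 15, seed = 4)
  firsts <- log[log$phase == "training" & log$choice_index == 1, ]
  expect_true(all(firsts$correct))
})

test_that("random agents perform at the symmetric chance level", {
  log <- simulate_cohort(8, c(larger = 4, smaller = 4),
                         agent_spec("random"), master_seed = 31)
  tr <- log[log$phase == "training", ]
  firsts <- tr$correct[tr$choice_index == 1]
  se1 <- sqrt(0.25 / length(firsts))
  expect_lt(abs(mean(firsts) - 0.5), 3 * se1)
  # pooled accuracy over all choices: ~0.5 despite the stopping rule
  se_all <- sqrt(0.25 / nrow(tr))
  expect_lt(abs(mean(tr$correct) - 0.5), 3 * se_all)
  # contingency relabelling leaves accuracy invariant (within MC error)
  acc_g <- tapply(tr$correct, tr$group, mean)
  expect_lt(abs(acc_g[["larger"]] - acc_g[["smaller"]]),
            3 * sqrt(0.5 / (nrow(tr) / 2)))
})

test_that("WSLS conditionals sit above their chance levels by Monte Carlo", {
  # 10,000 bouts from a WSLS bee; chance levels are 0.4 / 0.6
  set.seed(123)
  a <- agent_spec("wsls")
  arena <- arena_config()
  st <- build_stimulus_set("circle", "black", c("small", "large"), "larger")
  c1 <- logical(10000); c2 <- logical(10000)
  for (i in seq_len(10000)) {
    b <- simulate_bout(a, arena, st, bout_index = 1L)
    c1[i] <- b$correct[1]; c2[i] <- b$correct[2]
  }
  p_ws <- mean(c2[c1]); p_ls <- mean(c2[!c1])
  f <- a$wsls_fidelity
  expect_gt(p_ws, chance_level(6, 3, "correct") + 0.1)
  expect_gt(p_ls, chance_level(6, 3, "incorrect") + 0.1)
  # and they agree with the closed-form mixture f + (1-f) * chance
  expect_lt(abs(p_ws - (f + (1 - f) * 0.4)), 0.02)
  expect_lt(abs(p_ls - (f + (1 - f) * 0.6)), 0.02)
})

test_that("hybrid agents drop to chance-level first choices after the switch", {
  # 100 replicate agents, switch at bout 21: WSLS first choices uninformed
  set.seed(77)
  firsts <- replicate(100, {
    log <- simulate_bee(agent_spec("hybrid", switch_bout = 21),
                        n_bouts = 30)
    tr <- log[log$phase == "training" & log$bout_index >= 21 &
                log$choice_index == 1, ]
    mean(tr$correct)
  })
  se <- sqrt(0.25 / (100 * 10))
  expect_lt(abs(mean(firsts) - 0.5), 3 * se)
})

test_that("invalid simulation inputs are rejected", {
  expect_error(agent_spec("hybrid"), "switch_bout")
  expect_error(agent_spec("rule", rule_accuracy_min = 1.2), "\\[0, 1\\]")
  expect_error(simulate_bee(agent_spec("random"), n_bouts = 0), ">= 1")
})
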