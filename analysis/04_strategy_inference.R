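#!/usr/bin/env Rscript
# Stage 4: strategy-switch inference and the unrewarded-test analyses.
#
# Labels each block of 10 bouts by the evidence pattern (rule vs WSLS),
# infers the switch block, then analyses the unrewarded tests: performance
# against chance, the training-test correlation, the drop from the last
# training bout, and the split-half comparison within tests. Everything is
# collected into results/report.json.

suppressPackageStartupMessages(library(beeswitch))

out_dir <- "results"
log <- read_choice_log(file.path(out_dir, "cohort_log.csv"))
arena <- arena_config()
bs <- block_summaries(log, 10L)

sw <- detect_strategy_switch(bs, arena, alpha = 0.05)
print(sw)

ch_first <- chance_level(arena$n_discs, arena$n_rewarded, "none")
tests <- list()
for (ph in c("learning_test", "novel_shape_test", "novel_color_test")) {
  acc <- test_accuracy(log, ph)
  res <- suppressWarnings(test_above_chance(acc, ch_first))
  tests[[ph]] <- list(mean_accuracy = mean(acc), p_value = res$p_value,
                      n = res$n)
  cat(sprintf("%s: %.1f%% correct (vs %.0f%% chance, p=%.3g)\n", ph,
              100 * mean(acc), 100 * ch_first, res$p_value))
}

learn_acc <- test_accuracy(log, "learning_test")
tt <- training_test_correlation(bs, learn_acc, block = 2L)
cat(sprintf(
  "Training (block 2 first choices) vs learning test: rho=%.2f, p=%.3g\n",
  tt$rho, tt$p_value))

# drop from the last training bout to the learning test
tr <- log[log$phase == "training", ]
last_bout <- tapply(tr$bout_index, tr$bee_id, max)
last_acc <- vapply(names(last_bout), function(b)
  mean(tr$correct[tr$bee_id == b & tr$bout_index == last_bout[b]]),
  numeric(1))
drop_test <- suppressWarnings(signed_rank_test(
  last_acc[names(learn_acc)] - learn_acc, alternative = "greater"))
cat(sprintf(
  "Last training bout (%.1f%%) vs learning test (%.1f%%): p=%.3g\n",
  100 * mean(last_acc), 100 * mean(learn_acc), drop_test$p_value))

sh <- suppressWarnings(split_half_test_performance(log))
cat(sprintf(
  "Split-half over tests: first %.1f%%, second %.1f%% (one-sided p=%.3g)\n",
  100 * sh$mean_first, 100 * sh$mean_second, sh$test$p_value))

report <- list(
  version = "1",
  chance_levels = list(
    first = ch_first,
    win_stay = chance_level(arena$n_discs, arena$n_rewarded, "correct"),
    lose_switch = chance_level(arena$n_discs, arena$n_rewarded,
                               "incorrect")),
  switch_report = list(blocks = sw$blocks,
                       switch_block = sw$switch_block, alpha = sw$alpha),
  unrewarded_tests = tests,
  training_test_correlation = list(rho = tt$rho, p_value = tt$p_value,
                                   n = tt$n),
  last_bout_vs_test = list(mean_last_bout = mean(last_acc),
                           mean_learning_test = mean(learn_acc),
                           p_value = drop_test$p_value),
  split_half = list(mean_first = sh$mean_first,
                    mean_second = sh$mean_second,
                    p_value = sh$test$p_value))
write_report(report, file.path(out_dir, "report.json"))
cat("Report written to results/report.json\n")
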