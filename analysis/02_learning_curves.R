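#!/usr/bin/env Rscript
# Stage 2: descriptive learning curves from the simulated cohort.
#
# Computes block-wise accuracy from all / first / second choices (blocks of
# 6 and of 10 bouts), the win-stay and lose-switch conditional
# probabilities against their enumerated chance levels, choices per bout,
# and the spatial transition-rank analysis.

suppressPackageStartupMessages(library(beeswitch))

out_dir <- "results"
log_path <- file.path(out_dir, "cohort_log.csv")
if (!file.exists(log_path))
  stop("run analysis/01_simulate_cohort.R first", call. = FALSE)
log <- read_choice_log(log_path)
arena <- arena_config()

for (k in c(6L, 10L)) {
  bs <- block_summaries(log, k)
  write.csv(bs, file.path(out_dir, sprintf("block_summaries_%d.csv", k)),
            row.names = FALSE)
}
bs10 <- read.csv(file.path(out_dir, "block_summaries_10.csv"))

cat("Mean accuracy by block of 10 training bouts (18 bees):\n")
for (b in sort(unique(bs10$block_index))) {
  sb <- bs10[bs10$block_index == b, ]
  cat(sprintf("  block %d: all %.1f%%  first %.1f%%  second %.1f%%\n", b,
              100 * mean(sb$accuracy_all, na.rm = TRUE),
              100 * mean(sb$accuracy_first, na.rm = TRUE),
              100 * mean(sb$accuracy_second, na.rm = TRUE)))
}

ch_ws <- chance_level(arena$n_discs, arena$n_rewarded, "correct")
ch_ls <- chance_level(arena$n_discs, arena$n_rewarded, "incorrect")
cat(sprintf("Enumerated chance levels: win-stay %.2f, lose-switch %.2f\n",
            ch_ws, ch_ls))
for (b in sort(unique(bs10$block_index))) {
  sb <- bs10[bs10$block_index == b, ]
  pw <- suppressWarnings(test_above_chance(sb$p_win_stay, ch_ws))
  pl <- suppressWarnings(test_above_chance(sb$p_lose_switch, ch_ls))
  cat(sprintf(
    "  block %d: win-stay %.2f (p=%.2g)  lose-switch %.2f (p=%.2g)\n", b,
    mean(sb$p_win_stay, na.rm = TRUE), pw$p_value,
    mean(sb$p_lose_switch, na.rm = TRUE), pl$p_value))
}

cpb <- choices_per_bout(log, 10L)
write.csv(cpb$summary, file.path(out_dir, "choices_per_bout.csv"),
          row.names = FALSE)
cat("Choices per bout (mean +/- SEM):",
    paste(sprintf("block %d: %.2f+/-%.2f", cpb$summary$block_index,
                  cpb$summary$mean, cpb$summary$sem), collapse = "  "),
    "\n")

sp <- spatial_transition_metrics(log, arena)
null_sp <- uniform_transition_ranks(arena)
write.csv(sp$rank_counts, file.path(out_dir, "transition_ranks.csv"),
          row.names = FALSE)
cat(sprintf(
  "Nearest-disc transitions: %.3f observed vs %.3f under uniform choice\n",
  sp$nearest_rate, null_sp$nearest_rate))
cat("Tables written to results/.\n")
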