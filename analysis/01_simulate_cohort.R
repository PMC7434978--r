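#!/usr/bin/env Rscript
# Stage 1: generate the study-scale synthetic cohort.
#
# 18 bees (10 on the larger-rewarded, 8 on the smaller-rewarded
# contingency) forage for 30 training bouts in the six-disc arena. Agents
# follow the relational size rule with a learning ramp and switch to a
# win-stay/lose-switch heuristic at bout 21, then run the three unrewarded
# tests (learning, novel shape, novel colour) separated by refresh bouts.

suppressPackageStartupMessages(library(beeswitch))

seed <- 20260920L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

agent <- agent_spec("hybrid", switch_bout = 21L)
log <- simulate_cohort(18L, c(larger = 10L, smaller = 8L), agent,
                       master_seed = seed)
write_choice_log(log, file.path(out_dir, "cohort_log.csv"))

tr <- log[log$phase == "training", ]
cat(sprintf("Simulated %d bees, %d landings (%d in training bouts).\n",
            length(unique(log$bee_id)), nrow(log), nrow(tr)))
cat(sprintf("Master seed %d; per-bee seeds derived deterministically.\n",
            seed))
cat(sprintf("Overall training accuracy (all choices): %.1f%%\n",
            100 * mean(tr$correct)))
cat(sprintf("Choice log written to %s\n",
            file.path(out_dir, "cohort_log.csv")))
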