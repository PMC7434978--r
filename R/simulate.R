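# Agent-based generation of foraging bouts. A bout is a sequence of landings
# on the six discs; rewarded discs pay out once (depletion), the immediately
# previous disc is never re-chosen, and training bouts end when all rewards
# are collected or the landing cap is hit. Unrewarded test bouts emit a fixed
# number of landings standing in for the 120-s test window.

.test_phases <- c("learning_test", "novel_shape_test", "novel_color_test")

#' Simulate a single foraging bout
#'
#' Sequential choices are drawn according to the agent's strategy (see
#' [agent_spec()]). A landing on a rewarded-class disc is `correct`;
#' `reward_received` additionally requires the disc not to have been drained
#' earlier in the bout (and is always `FALSE` in test phases). Training and
#' refresh bouts terminate once `n_rewarded` rewards are collected or
#' `max_choices_per_bout` landings are made; test bouts emit exactly
#' `n_test_choices` landings.
#'
#' @param agent An [agent_spec()].
#' @param arena An [arena_config()].
#' @param stim_set A stimulus set from [build_stimulus_set()].
#' @param bout_index 1-based bout number (drives the rule-accuracy ramp).
#' @param phase `"training"`, `"refresh"`, or one of the test phases.
#' @param n_test_choices Landings emitted in a test bout (default 10).
#' @param rule_bout Bout index used for the rule-accuracy ramp (defaults to
#'   `bout_index`; test bouts should pass the last training bout).
#' @return A data.frame of choice events (one row per landing).
#' @export
simulate_bout <- function(agent, arena, stim_set, bout_index,
                          phase = "training", n_test_choices = 10L,
                          rule_bout = bout_index) {
  stopifnot(inherits(agent, "agent_spec"), inherits(arena, "arena_config"))
  if (arena$n_rewarded == 0L)
    stop("arena must have at least one rewarded disc", call. = FALSE)
  testing <- phase %in% .test_phases
  n <- arena$n_discs
  ids <- seq_len(n)
  rewarded <- stim_set$rewarded
  rel_class <- stim_set$relative_class
  acc <- rule_accuracy(agent, rule_bout)
  dists <- NULL
  if (agent$strategy == "proximity")
    dists <- as.matrix(stats::dist(cbind(stim_set$x, stim_set$y)))

  max_len <- if (testing) as.integer(n_test_choices)
             else arena$max_choices_per_bout
  choice <- integer(max_len)
  correct <- logical(max_len)
  rewarded_evt <- logical(max_len)
  drained <- logical(n)
  prev <- 0L
  last_reward <- NA    # WSLS memory; NA until the first landing of the bout
  n_rewards <- 0L
  t <- 0L

  while (t < max_len) {
    t <- t + 1L
    strat <- effective_strategy(agent, bout_index, phase, t)
    avail <- if (prev == 0L) ids else ids[-prev]
    pick <- switch(strat,
      random = avail[sample.int(length(avail), 1L)],
      proximity = {
        if (prev == 0L) avail[sample.int(length(avail), 1L)] else {
          d <- dists[prev, avail]
          near <- avail[d <= min(d) + 1e-12]
          near[sample.int(length(near), 1L)]
        }
      },
      rule = {
        target <- if (stats::runif(1) < acc) rewarded[avail]
                  else !rewarded[avail]
        cand <- avail[target]
        if (length(cand) == 0L) cand <- avail   # degenerate tiny arenas
        cand[sample.int(length(cand), 1L)]
      },
      wsls = {
        if (is.na(last_reward) || stats::runif(1) >= agent$wsls_fidelity) {
          avail[sample.int(length(avail), 1L)]
        } else {
          prev_class <- rel_class[prev]
          keep <- if (last_reward) rel_class[avail] == prev_class
                  else rel_class[avail] != prev_class
          cand <- avail[keep]
          if (length(cand) == 0L) cand <- avail
          cand[sample.int(length(cand), 1L)]
        }
      },
      stop(sprintf("unknown strategy '%s'", strat), call. = FALSE))

    ok <- rewarded[pick]
    rew <- !testing && ok && !drained[pick]
    if (rew) {
      drained[pick] <- TRUE
      n_rewards <- n_rewards + 1L
    }
    choice[t] <- pick
    correct[t] <- ok
    rewarded_evt[t] <- rew
    prev <- pick
    last_reward <- rew
    if (!testing && n_rewards >= arena$n_rewarded) break
  }

  idx <- seq_len(t)
  data.frame(
    bout_index = bout_index,
    choice_index = idx,
    disc_id = choice[idx],
    disc_x = stim_set$x[choice[idx]],
    disc_y = stim_set$y[choice[idx]],
    size_class_chosen = rel_class[choice[idx]],
    correct = correct[idx],
    reward_received = rewarded_evt[idx],
    phase = phase,
    stringsAsFactors = FALSE)
}

# One bout's stimulus options, drawn as in training: one shape, one colour,
# two of the three sizes.
.draw_training_stimulus <- function(agent, arena) {
  shapes <- c("circle", "rectangle", "cross")
  shape <- shapes[sample.int(3L, 1L)]
  color <- .training_colors[sample.int(3L, 1L)]
  pairs <- list(c("small", "medium"), c("small", "large"),
                c("medium", "large"))
  pair <- pairs[[sample.int(3L, 1L)]]
  build_stimulus_set(shape, color, pair, agent$contingency, arena)
}

.draw_test_stimulus <- function(test_phase, agent, arena) {
  shapes <- c("circle", "rectangle", "cross")
  switch(test_phase,
    learning_test = build_stimulus_set(shapes[sample.int(3L, 1L)],
                                       .training_colors[sample.int(3L, 1L)],
                                       c("small", "large"),
                                       agent$contingency, arena),
    novel_shape_test = build_stimulus_set("star",
                                          .training_colors[sample.int(3L, 1L)],
                                          c("small", "large"),
                                          agent$contingency, arena),
    novel_color_test = build_stimulus_set(shapes[sample.int(3L, 1L)],
                                          "yellow", c("small", "large"),
                                          agent$contingency, arena),
    stop(sprintf("unknown test phase '%s'", test_phase), call. = FALSE))
}

#' Simulate one bee: training bouts plus unrewarded tests
#'
#' Runs `n_bouts` training bouts (per bout: one shape, one colour and two of
#' the three sizes drawn at random, rotated disc positions), then the three
#' unrewarded tests separated by `n_refresh` rewarded refresh bouts each
#' (sequence T1, refresh, T2, refresh, T3). Test bouts use the small/large
#' pair; the novel-shape test uses the star, the novel-colour test yellow.
#' Bout indexing continues through refresh and test bouts.
#'
#' @param agent An [agent_spec()].
#' @param bee_id Identifier written into the log.
#' @param n_bouts Number of training bouts (default 30).
#' @param arena An [arena_config()].
#' @param seed Optional integer seed for this bee's choices.
#' @param n_test_choices Landings per unrewarded test bout (default 10).
#' @param n_refresh Refresh bouts between consecutive tests (default 2).
#' @param test_order Permutation of the three test phases.
#' @return A choice-log data.frame (one row per landing) with columns
#'   `bee_id`, `group`, `phase`, `bout_index`, `choice_index`, `disc_id`,
#'   `disc_x`, `disc_y`, `size_class_chosen`, `correct`, `reward_received`.
#' @export
simulate_bee <- function(agent, bee_id = "bee1", n_bouts = 30L,
                         arena = arena_config(), seed = NULL,
                         n_test_choices = 10L, n_refresh = 2L,
                         test_order = .test_phases) {
  stopifnot(inherits(agent, "agent_spec"))
  if (n_bouts < 1L) stop("`n_bouts` must be >= 1", call. = FALSE)
  if (!all(sort(test_order) == sort(.test_phases)))
    stop("`test_order` must be a permutation of the three test phases",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  out <- vector("list", n_bouts + 3L + (3L - 1L) * n_refresh)
  j <- 0L
  bout <- 0L
  for (b in seq_len(n_bouts)) {
    bout <- bout + 1L
    j <- j + 1L
    out[[j]] <- simulate_bout(agent, arena,
                              .draw_training_stimulus(agent, arena),
                              bout, phase = "training")
  }
  for (k in seq_along(test_order)) {
    if (k > 1L) for (r in seq_len(n_refresh)) {
      bout <- bout + 1L
      j <- j + 1L
      out[[j]] <- simulate_bout(agent, arena,
                                .draw_training_stimulus(agent, arena),
                                bout, phase = "refresh")
    }
    bout <- bout + 1L
    j <- j + 1L
    out[[j]] <- simulate_bout(agent, arena,
                              .draw_test_stimulus(test_order[k], agent, arena),
                              bout, phase = test_order[k],
                              n_test_choices = n_test_choices,
                              rule_bout = n_bouts)
  }
  log <- do.call(rbind, out[seq_len(j)])
  data.frame(bee_id = bee_id, group = agent$contingency,
             log[, c("phase", "bout_index", "choice_index", "disc_id",
                     "disc_x", "disc_y", "size_class_chosen", "correct",
                     "reward_received")],
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of bees
#'
#' Reproducible cohort generation: per-bee child seeds are drawn
#' deterministically from `master_seed`, group (contingency) labels follow
#' `group_mix`, and the three-test order is rotated across bees as a simple
#' counterbalancing scheme. The same `master_seed` reproduces the dataset
#' bit-for-bit.
#'
#' @param n_bees Cohort size.
#' @param group_mix Named integer vector over `c("larger", "smaller")`
#'   summing to `n_bees` (default `c(larger = 10, smaller = 8)`).
#' @param agent Template [agent_spec()]; its contingency is overridden per
#'   group.
#' @param master_seed Integer master seed.
#' @param ... Passed to [simulate_bee()] (`n_bouts`, `arena`,
#'   `n_test_choices`, `n_refresh`).
#' @return A combined choice-log data.frame.
#' @export
simulate_cohort <- function(n_bees = 18L,
                            group_mix = c(larger = 10L, smaller = 8L),
                            agent = agent_spec("hybrid", switch_bout = 21L),
                            master_seed = 1L, ...) {
  if (n_bees < 1L) stop("`n_bees` must be >= 1", call. = FALSE)
  if (is.null(names(group_mix)) ||
      !all(names(group_mix) %in% c("larger", "smaller")))
    stop("`group_mix` must be named over larger/smaller", call. = FALSE)
  if (sum(group_mix) != n_bees)
    stop("`group_mix` must sum to `n_bees`", call. = FALSE)

  set.seed(master_seed)
  child_seeds <- sample.int(.Machine$integer.max, n_bees)
  groups <- rep(names(group_mix), times = group_mix)
  orders <- list(.test_phases, .test_phases[c(2, 3, 1)],
                 .test_phases[c(3, 1, 2)])
  width <- max(2L, nchar(as.character(n_bees)))
  logs <- vector("list", n_bees)
  for (i in seq_len(n_bees)) {
    a <- agent
    a$contingency <- groups[i]
    logs[[i]] <- simulate_bee(
      a, bee_id = sprintf("bee%0*d", width, i), seed = child_seeds[i],
      test_order = orders[[((i - 1L) %% 3L) + 1L]], ...)
  }
  do.call(rbind, logs)
}
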