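# Descriptive statistics over choice logs: block-wise accuracies from
# all/first/second choices, win-stay / lose-switch conditional probabilities
# with their enumerated chance levels, choices per bout, and spatial
# transition ranks. All functions consume the tidy choice-log data.frame
# produced by simulate_bee()/simulate_cohort() or read_choice_log().

#' Map bout indices to blocks
#'
#' Blocks are `[1..k], [k+1..2k], ...`; a trailing partial block keeps the
#' next index and is flagged by the callers that care.
#'
#' @param bout_index Integer vector of 1-based bout numbers.
#' @param block_size Bouts per block (>= 1).
#' @return Integer block indices.
#' @export
assign_blocks <- function(bout_index, block_size) {
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("`block_size` must be >= 1", call. = FALSE)
  ((as.integer(bout_index) - 1L) %/% block_size) + 1L
}

.check_log <- function(log) {
  need <- c("bee_id", "phase", "bout_index", "choice_index", "correct")
  miss <- setdiff(need, names(log))
  if (length(miss))
    stop("choice log lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(log)
}

# One row per bout: outcome of the first and second choice plus bout length.
.bout_outcomes <- function(log, phase = "training",
                           condition_on = c("correct", "reward")) {
  condition_on <- match.arg(condition_on)
  .check_log(log)
  sub <- log[log$phase %in% phase, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no choices in the requested phase(s)", call. = FALSE)
  key <- interaction(sub$bee_id, sub$bout_index, drop = TRUE, lex.order = TRUE)
  first <- sub$choice_index == 1L
  second <- sub$choice_index == 2L
  len <- as.integer(tapply(sub$choice_index, key, length))
  cond_col <- if (condition_on == "correct") sub$correct
              else sub$reward_received
  df <- data.frame(
    bee_id = as.character(tapply(sub$bee_id, key, `[`, 1L)),
    bout_index = as.integer(tapply(sub$bout_index, key, `[`, 1L)),
    n_choices = len,
    c1 = as.logical(tapply(cond_col & first, key, any)),
    c1_correct = as.logical(tapply(sub$correct & first, key, any)),
    c2_correct = ifelse(len >= 2L,
                        as.logical(tapply(sub$correct & second, key, any)),
                        NA),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(df$bee_id, df$bout_index), , drop = FALSE]
}

#' Block-wise proportion of correct choices
#'
#' Accuracy per bee and block computed from all choices, only first choices,
#' or only second choices of each bout. Bouts lacking the required choice
#' index contribute nothing to that statistic's denominator; a bee/block with
#' an empty denominator is reported as `NA`, never 0.
#'
#' @param log A choice-log data.frame.
#' @param block_size Bouts per block (the study uses 6 and 10).
#' @param which `"all"`, `"first"` or `"second"`.
#' @param phase Phase(s) to include (default `"training"`).
#' @return A data.frame `bee_id`, `block_index`, `n_choices`, `accuracy`,
#'   `partial` (TRUE for a trailing incomplete block).
#' @export
block_accuracy <- function(log, block_size = 10L,
                           which = c("all", "first", "second"),
                           phase = "training") {
  which <- match.arg(which)
  .check_log(log)
  sub <- log[log$phase %in% phase, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no choices in the requested phase(s)",
                            call. = FALSE)
  if (which == "first") sub <- sub[sub$choice_index == 1L, , drop = FALSE]
  if (which == "second") sub <- sub[sub$choice_index == 2L, , drop = FALSE]
  blk <- assign_blocks(sub$bout_index, block_size)
  # full grid of (bee, block) so empty denominators surface as NA
  bees <- sort(unique(log$bee_id[log$phase %in% phase]))
  max_blk <- max(assign_blocks(log$bout_index[log$phase %in% phase],
                               block_size))
  grid <- expand.grid(bee_id = bees, block_index = seq_len(max_blk),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(sub$bee_id, blk)
  acc <- tapply(sub$correct, key, mean)
  cnt <- tapply(sub$correct, key, length)
  gkey <- paste(grid$bee_id, grid$block_index)
  grid$n_choices <- as.integer(ifelse(is.na(cnt[gkey]), 0L, cnt[gkey]))
  grid$accuracy <- as.numeric(acc[gkey])
  in_phase <- log$phase %in% phase
  max_bout <- tapply(log$bout_index[in_phase], log$bee_id[in_phase], max)
  grid$partial <- grid$block_index * block_size >
    as.numeric(max_bout[grid$bee_id])
  grid[order(grid$bee_id, grid$block_index), , drop = FALSE]
}

#' Win-stay / lose-switch conditional probabilities
#'
#' For bouts with at least two choices, estimates per bee the probability of
#' a correct second choice given a correct first choice (win-stay,
#' `p_win_stay`) and given an incorrect first choice (lose-switch,
#' `p_lose_switch`), as empirical joint frequency over empirical marginal.
#' The cross-bee values are the means of the per-bee estimates; bees with an
#' empty conditioning margin are excluded from that mean with a warning.
#'
#' By construction, per bee,
#' `p_first * p_win_stay + (1 - p_first) * p_lose_switch` equals the
#' empirical second-choice accuracy exactly whenever both conditionals are
#' defined (`p_first` here is the first-choice accuracy over the same
#' qualifying bouts).
#'
#' @param log A choice-log data.frame.
#' @param block_size Optional; if given, estimates are per bee and block.
#' @param condition_on Condition the first-choice outcome on correctness
#'   (default) or on `reward_received`.
#' @param phase Phase(s) to include.
#' @return A list of class `conditional_probs`: `per_bee` (data.frame with
#'   `p_first`, `p_win_stay`, `p_lose_switch`, `second_accuracy`, counts) and
#'   cross-bee means `p_win_stay`, `p_lose_switch`.
#' @export
conditional_second_given_first <- function(log, block_size = NULL,
                                           condition_on = c("correct",
                                                            "reward"),
                                           phase = "training") {
  bo <- .bout_outcomes(log, phase = phase, condition_on = condition_on)
  bo <- bo[bo$n_choices >= 2L, , drop = FALSE]
  if (nrow(bo) == 0L)
    stop("no bouts with >= 2 choices; conditionals undefined", call. = FALSE)
  if (is.null(block_size)) {
    grp <- bo$bee_id
  } else {
    bo$block_index <- assign_blocks(bo$bout_index, block_size)
    grp <- paste(bo$bee_id, bo$block_index)
  }
  one <- function(i) {
    c1 <- bo$c1[i]; c2 <- bo$c2_correct[i]
    n1 <- sum(c1); n0 <- sum(!c1)
    c(n_bouts = length(i),
      p_first = mean(c1),
      n_win = n1,
      p_win_stay = if (n1 > 0L) sum(c2[c1]) / n1 else NA_real_,
      n_lose = n0,
      p_lose_switch = if (n0 > 0L) sum(c2[!c1]) / n0 else NA_real_,
      second_accuracy = mean(c2))
  }
  idx <- split(seq_len(nrow(bo)), grp)
  stats <- t(vapply(idx, one, numeric(7)))
  per_bee <- data.frame(
    bee_id = vapply(idx, function(i) bo$bee_id[i[1]], character(1)),
    stats, row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(block_size))
    per_bee <- data.frame(
      bee_id = per_bee$bee_id,
      block_index = vapply(idx, function(i) bo$block_index[i[1]], integer(1)),
      per_bee[, -1], row.names = NULL, stringsAsFactors = FALSE)
  n_excl_w <- sum(is.na(per_bee$p_win_stay))
  n_excl_l <- sum(is.na(per_bee$p_lose_switch))
  if (n_excl_w + n_excl_l > 0L)
    warning(sprintf(paste0("%d win-stay and %d lose-switch estimates ",
                           "undefined (empty conditioning margin); ",
                           "excluded from cross-bee means"),
                    n_excl_w, n_excl_l), call. = FALSE)
  structure(
    list(per_bee = per_bee,
         p_win_stay = mean(per_bee$p_win_stay, na.rm = TRUE),
         p_lose_switch = mean(per_bee$p_lose_switch, na.rm = TRUE),
         condition_on = match.arg(condition_on)),
    class = "conditional_probs")
}

#' Chance level of a choice in the depleting six-disc arena
#'
#' Expected accuracy of an uninformed chooser: `n_rewarded / n_discs` for a
#' first choice, and — because the immediately previous disc is excluded —
#' `(n_rewarded - 1) / (n_discs - 1)` for a second choice after a correct
#' first, `n_rewarded / (n_discs - 1)` after an incorrect first. With the
#' default arena these are 0.5, 0.4 and 0.6.
#'
#' @param n_discs,n_rewarded Arena composition; `0 < n_rewarded < n_discs`.
#' @param first_outcome `"none"` (unconditioned first choice), `"correct"` or
#'   `"incorrect"` (conditioning outcome of the previous choice).
#' @return A probability.
#' @export
chance_level <- function(n_discs = 6L, n_rewarded = 3L,
                         first_outcome = c("none", "correct", "incorrect")) {
  first_outcome <- match.arg(first_outcome)
  n_discs <- as.integer(n_discs)
  n_rewarded <- as.integer(n_rewarded)
  if (n_rewarded <= 0L || n_rewarded >= n_discs)
    stop("`n_rewarded` must satisfy 0 < n_rewarded < n_discs ",
         "(no discrimination otherwise)", call. = FALSE)
  switch(first_outcome,
         none = n_rewarded / n_discs,
         correct = (n_rewarded - 1) / (n_discs - 1),
         incorrect = n_rewarded / (n_discs - 1))
}

#' Mean number of choices per bout, by block
#'
#' Bout length (landings per bout) averaged per bee within each block, then
#' summarised across bees with its standard error.
#'
#' @inheritParams block_accuracy
#' @return A list: `per_bee` (bee x block mean bout length) and `summary`
#'   (per block: cross-bee `mean`, `sem`, `n_bees`).
#' @export
choices_per_bout <- function(log, block_size = 10L, phase = "training") {
  bo <- .bout_outcomes(log, phase = phase)
  bo$block_index <- assign_blocks(bo$bout_index, block_size)
  key <- paste(bo$bee_id, bo$block_index)
  idx <- split(seq_len(nrow(bo)), key)
  per_bee <- data.frame(
    bee_id = vapply(idx, function(i) bo$bee_id[i[1]], character(1)),
    block_index = vapply(idx, function(i) bo$block_index[i[1]], integer(1)),
    n_bouts = lengths(idx),
    mean_choices = vapply(idx, function(i) mean(bo$n_choices[i]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  sidx <- split(seq_len(nrow(per_bee)), per_bee$block_index)
  summary <- data.frame(
    block_index = as.integer(names(sidx)),
    mean = vapply(sidx, function(i) mean(per_bee$mean_choices[i]), numeric(1)),
    sem = vapply(sidx, function(i) {
      x <- per_bee$mean_choices[i]
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    }, numeric(1)),
    n_bees = lengths(sidx), row.names = NULL)
  summary <- summary[order(summary$block_index), , drop = FALSE]
  list(per_bee = per_bee, summary = summary)
}

#' Per-bee, per-block summary of sequential-choice statistics
#'
#' The workhorse table feeding strategy-switch inference: accuracies from
#' all/first/second choices, the two conditional probabilities, and mean
#' bout length, per bee and block of `block_size` training bouts.
#'
#' @inheritParams block_accuracy
#' @param condition_on Passed to [conditional_second_given_first()].
#' @return A data.frame with one row per bee and block.
#' @export
block_summaries <- function(log, block_size = 10L, phase = "training",
                            condition_on = "correct") {
  acc_all <- block_accuracy(log, block_size, "all", phase)
  acc_first <- block_accuracy(log, block_size, "first", phase)
  acc_second <- block_accuracy(log, block_size, "second", phase)
  cond <- suppressWarnings(
    conditional_second_given_first(log, block_size = block_size,
                                   condition_on = condition_on,
                                   phase = phase))$per_bee
  cpb <- choices_per_bout(log, block_size, phase)$per_bee
  out <- acc_all[, c("bee_id", "block_index", "partial")]
  out$accuracy_all <- acc_all$accuracy
  key <- function(df) paste(df$bee_id, df$block_index)
  out$accuracy_first <- acc_first$accuracy[match(key(out), key(acc_first))]
  out$accuracy_second <- acc_second$accuracy[match(key(out), key(acc_second))]
  out$p_win_stay <- cond$p_win_stay[match(key(out), key(cond))]
  out$p_lose_switch <- cond$p_lose_switch[match(key(out), key(cond))]
  out$mean_choices_per_bout <- cpb$mean_choices[match(key(out), key(cpb))]
  rownames(out) <- NULL
  out
}

#' Spatial ranks of landing transitions
#'
#' For every within-bout transition, ranks the Euclidean distance of the
#' chosen disc from the previously visited disc among all non-previous discs
#' (rank 1 = nearest; tied distances share the mean rank). Reports the
#' proportion of transitions landing on the (untied) nearest disc and the
#' full rank histogram.
#'
#' @param log A choice-log data.frame with `disc_id` coordinates.
#' @param arena The [arena_config()] providing disc geometry.
#' @param phase Phase(s) to include.
#' @return A list: `n_transitions`, `nearest_rate`, `mean_rank`,
#'   `rank_counts` (data.frame `rank`, `count`, `proportion`).
#' @export
spatial_transition_metrics <- function(log, arena = arena_config(),
                                       phase = "training") {
  .check_log(log)
  if (!all(c("disc_id", "disc_x", "disc_y") %in% names(log)))
    stop("choice log lacks disc coordinates", call. = FALSE)
  sub <- log[log$phase %in% phase, , drop = FALSE]
  if (any(is.na(sub$disc_x)) || any(is.na(sub$disc_y)))
    stop("missing disc coordinates", call. = FALSE)
  pos <- disc_positions(arena)
  if (!all(sub$disc_id %in% pos$disc_id))
    stop("disc ids outside the arena grid", call. = FALSE)
  D <- as.matrix(stats::dist(cbind(pos$x, pos$y)))
  # rank of each disc j among non-previous discs, for each previous disc
  R <- matrix(NA_real_, arena$n_discs, arena$n_discs)
  for (p in seq_len(arena$n_discs)) {
    others <- setdiff(seq_len(arena$n_discs), p)
    R[p, others] <- rank(D[p, others], ties.method = "average")
  }
  ord <- order(sub$bee_id, sub$bout_index, sub$choice_index)
  sub <- sub[ord, , drop = FALSE]
  same_bout <- with(sub, head(bee_id, -1) == tail(bee_id, -1) &
                      head(bout_index, -1) == tail(bout_index, -1))
  prev <- head(sub$disc_id, -1)[same_bout]
  nxt <- tail(sub$disc_id, -1)[same_bout]
  if (length(prev) == 0L)
    return(list(n_transitions = 0L, nearest_rate = NA_real_,
                mean_rank = NA_real_,
                rank_counts = data.frame(rank = numeric(0),
                                         count = integer(0),
                                         proportion = numeric(0))))
  ranks <- R[cbind(prev, nxt)]
  tab <- table(ranks)
  list(n_transitions = length(ranks),
       nearest_rate = mean(ranks == 1),
       mean_rank = mean(ranks),
       rank_counts = data.frame(rank = as.numeric(names(tab)),
                                count = as.integer(tab),
                                proportion = as.integer(tab) / length(ranks)))
}

#' Null distribution of transition ranks under uniform choice
#'
#' Exhaustive enumeration over all ordered (previous, next) disc pairs of the
#' arena, assuming the next disc is uniform over non-previous discs: the
#' expected rank histogram and nearest-disc rate for a spatially
#' indiscriminate chooser.
#'
#' @param arena An [arena_config()].
#' @return A list: `nearest_rate`, `mean_rank`, `rank_probs` (data.frame
#'   `rank`, `probability`).
#' @export
uniform_transition_ranks <- function(arena = arena_config()) {
  pos <- disc_positions(arena)
  D <- as.matrix(stats::dist(cbind(pos$x, pos$y)))
  ranks <- numeric(0)
  for (p in seq_len(arena$n_discs)) {
    others <- setdiff(seq_len(arena$n_discs), p)
    ranks <- c(ranks, rank(D[p, others], ties.method = "average"))
  }
  tab <- table(ranks)
  list(nearest_rate = mean(ranks == 1),
       mean_rank = mean(ranks),
       rank_probs = data.frame(rank = as.numeric(names(tab)),
                               probability = as.integer(tab) / length(ranks)))
}
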