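# Stopped Markov-chain model of per-bout performance. The chain has two
# states (correct/incorrect landing); the first landing is correct with
# probability p_first and every later landing is correct with a probability
# that depends only on the previous landing's outcome (homogeneity: all
# later transitions equal the second-given-first conditionals). A bout ends
# in success once `rewards_needed` correct landings have accrued, or in
# failure at error number `max_errors + 1` (a completed successful bout thus
# carries at most `max_errors` errors; with the defaults 3 and 2 every
# sequence has length 3, 4 or 5).

#' Transition model of sequential choices
#'
#' @param p_first Probability the first choice of a bout is correct.
#' @param p_stay_correct Probability a choice is correct given the previous
#'   choice was correct.
#' @param p_switch_correct Probability a choice is correct given the previous
#'   choice was incorrect.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(p_first, p_stay_correct, p_switch_correct) {
  p <- c(p_first = p_first, p_stay_correct = p_stay_correct,
         p_switch_correct = p_switch_correct)
  if (any(is.na(p)))
    stop("transition model has undefined probabilities", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  structure(as.list(p), class = "transition_model")
}

#' Bout stopping rule
#'
#' @param rewards_needed Correct outcomes ending the bout in success
#'   (default 3, the number of rewarded discs).
#' @param max_errors Maximum number of incorrect outcomes a completed bout
#'   may carry (default 2); the chain stops in failure at error
#'   `max_errors + 1`. Maximum sequence length is
#'   `rewards_needed + max_errors`.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(rewards_needed = 3L, max_errors = 2L) {
  rewards_needed <- as.integer(rewards_needed)
  max_errors <- as.integer(max_errors)
  if (rewards_needed < 1L) stop("`rewards_needed` must be >= 1",
                                call. = FALSE)
  if (max_errors < 0L) stop("`max_errors` must be >= 0", call. = FALSE)
  structure(list(rewards_needed = rewards_needed, max_errors = max_errors),
            class = "stopping_rule")
}

#' Estimate a transition model from observed bouts
#'
#' `p_first` is the empirical first-choice accuracy over bouts with at least
#' two choices; the two conditionals come from the empirical second-given-
#' first frequencies (see [conditional_second_given_first()]). Encodes the
#' homogeneity assumption that all later transitions equal the second|first
#' transition.
#'
#' @param log A choice-log data.frame (typically one bee, one block).
#' @param condition_on Passed through to the conditional estimator.
#' @param phase Phase(s) to include.
#' @return A [transition_model()]. Errors if either conditional is undefined
#'   (empty conditioning margin).
#' @export
estimate_transition_model <- function(log, condition_on = "correct",
                                      phase = "training") {
  cp <- suppressWarnings(
    conditional_second_given_first(log, condition_on = condition_on,
                                   phase = phase))
  pb <- cp$per_bee
  # pool across whatever bees/blocks are present in the supplied log
  n1 <- sum(pb$n_win); n0 <- sum(pb$n_lose)
  p_first <- sum(pb$p_first * pb$n_bouts) / sum(pb$n_bouts)
  p_stay <- if (n1 > 0L) sum(pb$p_win_stay * pb$n_win, na.rm = TRUE) / n1
            else NA_real_
  p_switch <- if (n0 > 0L) sum(pb$p_lose_switch * pb$n_lose, na.rm = TRUE) / n0
              else NA_real_
  transition_model(p_first, p_stay, p_switch)
}

#' Enumerate all bout outcome sequences
#'
#' Exhaustively lists every binary outcome sequence permitted by the
#' stopping rule together with its probability under the transition model.
#'
#' @param tm A [transition_model()].
#' @param stop_rule A [stopping_rule()].
#' @return A data.frame: `sequence` (string of `C`/`I`), `probability`,
#'   `n_correct`, `length`, `fraction_correct`. Probabilities sum to 1.
#' @export
enumerate_bout_sequences <- function(tm, stop_rule = stopping_rule()) {
  stopifnot(inherits(tm, "transition_model"),
            inherits(stop_rule, "stopping_rule"))
  r <- stop_rule$rewards_needed
  m <- stop_rule$max_errors
  seqs <- character(0); probs <- numeric(0); ncor <- integer(0)
  recurse <- function(seq, prob, nc, ne, prev) {
    if (nc == r || ne == m + 1L) {
      seqs <<- c(seqs, seq)
      probs <<- c(probs, prob)
      ncor <<- c(ncor, nc)
      return(invisible())
    }
    p_c <- if (is.na(prev)) tm$p_first
           else if (prev) tm$p_stay_correct else tm$p_switch_correct
    if (p_c > 0) recurse(paste0(seq, "C"), prob * p_c, nc + 1L, ne, TRUE)
    if (p_c < 1) recurse(paste0(seq, "I"), prob * (1 - p_c), nc, ne + 1L,
                         FALSE)
  }
  recurse("", 1, 0L, 0L, NA)
  len <- nchar(seqs)
  data.frame(sequence = seqs, probability = probs, n_correct = ncor,
             length = len, fraction_correct = ncor / len,
             stringsAsFactors = FALSE)
}

#' Expected per-bout performance under the stopped Markov model
#'
#' The exact expectation, over all enumerated outcome sequences, of the
#' fraction of correct choices in a bout (and, as a secondary summary, of
#' the count of correct choices).
#'
#' @inheritParams enumerate_bout_sequences
#' @return A list: `perf` (expected fraction correct), `perf_count`
#'   (expected number correct), `expected_length`, `total_probability`
#'   (should be 1 to numerical precision), `sequences` (the enumeration).
#' @export
predict_bout_performance <- function(tm, stop_rule = stopping_rule()) {
  sq <- enumerate_bout_sequences(tm, stop_rule)
  total <- sum(sq$probability)
  if (abs(total - 1) > 1e-9)
    warning(sprintf("sequence probabilities sum to %.12f", total),
            call. = FALSE)
  list(perf = sum(sq$probability * sq$fraction_correct),
       perf_count = sum(sq$probability * sq$n_correct),
       expected_length = sum(sq$probability * sq$length),
       total_probability = total,
       sequences = sq)
}

#' Monte-Carlo sampler of the stopped Markov chain
#'
#' Independent sampler used as an oracle for the exact enumeration: draws
#' `n` bout outcome sequences step by step (vectorised over bouts) and
#' reports their mean fraction correct. Seed R's RNG for reproducibility.
#'
#' @inheritParams enumerate_bout_sequences
#' @param n Number of bouts to sample.
#' @param keep_sequences If TRUE, also return the outcome matrix.
#' @return A list: `mean_fraction`, `se` (Monte-Carlo standard error),
#'   `fraction_correct` (per bout), `n`, and optionally `outcomes`.
#' @export
simulate_markov_bouts <- function(tm, stop_rule = stopping_rule(), n,
                                  keep_sequences = FALSE) {
  stopifnot(inherits(tm, "transition_model"),
            inherits(stop_rule, "stopping_rule"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  r <- stop_rule$rewards_needed
  m <- stop_rule$max_errors
  max_len <- r + m
  nc <- integer(n); ne <- integer(n)
  prev <- logical(n)
  active <- rep(TRUE, n)
  len <- integer(n)
  outcomes <- if (keep_sequences) matrix(NA, n, max_len) else NULL
  for (t in seq_len(max_len)) {
    if (!any(active)) break
    p <- if (t == 1L) rep(tm$p_first, sum(active))
         else ifelse(prev[active], tm$p_stay_correct, tm$p_switch_correct)
    hit <- stats::runif(sum(active)) < p
    nc[active] <- nc[active] + hit
    ne[active] <- ne[active] + !hit
    prev[active] <- hit
    len[active] <- t
    if (keep_sequences) outcomes[active, t] <- hit
    active[active] <- nc[active] < r & ne[active] <= m
  }
  frac <- nc / len
  out <- list(mean_fraction = mean(frac),
              se = stats::sd(frac) / sqrt(n),
              fraction_correct = frac, n = n)
  if (keep_sequences) out$outcomes <- outcomes
  out
}

#' Compare model-predicted to observed per-bee performance
#'
#' Paired two-sided exact Wilcoxon signed-rank test on the per-bee
#' differences observed minus predicted.
#'
#' @param observed Named numeric vector of per-bee observed accuracies
#'   (names = bee ids).
#' @param predicted Named numeric vector of per-bee model predictions over
#'   the same bees.
#' @return A `test_result` (see [signed_rank_test()]) with the mean
#'   difference attached as `mean_difference`.
#' @export
compare_model_to_observed <- function(observed, predicted) {
  if (is.null(names(observed)) || is.null(names(predicted)) ||
      !setequal(names(observed), names(predicted)))
    stop("`observed` and `predicted` must be named over the same bees",
         call. = FALSE)
  predicted <- predicted[names(observed)]
  res <- signed_rank_test(observed - predicted, mu0 = 0,
                          alternative = "two_sided")
  res$method <- "paired exact Wilcoxon signed-rank (observed - predicted)"
  res$mean_difference <- mean(observed - predicted)
  res
}
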