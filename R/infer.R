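# Exact nonparametric inference: sign-flip enumerated Wilcoxon signed-rank
# test, permutation Spearman correlation, above-chance tests anchored to the
# enumerated chance levels, block-wise strategy-switch detection, and the
# unrewarded-test analyses.

.new_test_result <- function(statistic, p_value, n, alternative, method,
                             ...) {
  structure(c(list(statistic = statistic, p_value = p_value, n = n,
                   alternative = alternative, method = method), list(...)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.4g, n = %d, alternative = %s, p = %.4g\n",
              x$method, x$statistic, x$n, x$alternative, x$p_value))
  invisible(x)
}

# Exact null distribution of the signed-rank sum W+ (sum of ranks of
# positive differences) over all 2^n equiprobable sign assignments, by
# dynamic programming on doubled ranks (mean ranks of tied |d| are
# half-integers, so doubling makes them integers). Returns the probability
# vector over W2 = 0 .. sum(2*ranks).
.signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f / 2
    shifted <- c(numeric(r), g[seq_len(total + 1L - r)])
    f <- g + shifted
  }
  f
}

#' Exact Wilcoxon signed-rank test
#'
#' One-sample (or paired-difference) signed-rank test of symmetry about
#' `mu0`. Zero differences are dropped (Wilcoxon convention) and tied
#' absolute differences receive mean ranks. For `n <= exact_max` remaining
#' differences the p-value is computed from the exact sign-flip null
#' distribution (all `2^n` sign assignments, tie-aware); above that, a
#' normal approximation with tie correction and continuity correction is
#' used. If every difference is zero the result is degenerate with p = 1
#' and a warning.
#'
#' @param values Numeric vector of observations (or paired differences).
#' @param mu0 Null centre of symmetry (default 0).
#' @param alternative `"two_sided"`, `"greater"` (values exceed `mu0`) or
#'   `"less"`.
#' @param exact_max Largest n for which the exact distribution is enumerated
#'   (default 20).
#' @return A `test_result` list: `statistic` (W+, the positive-rank sum),
#'   `p_value`, `n` (non-zero differences), `alternative`, `method`,
#'   `exact` (logical).
#' @export
signed_rank_test <- function(values, mu0 = 0,
                             alternative = c("two_sided", "greater", "less"),
                             exact_max = 20L) {
  alternative <- match.arg(alternative)
  d <- values[!is.na(values)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; degenerate signed-rank test",
            call. = FALSE)
    return(.new_test_result(NA_real_, 1, 0L, alternative,
                            "Wilcoxon signed-rank (degenerate)",
                            exact = TRUE))
  }
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    null <- .signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * W))
    total <- sum(ranks2)
    p_ge <- sum(null[(w2 + 1L):(total + 1L)])
    p_le <- sum(null[seq_len(w2 + 1L)])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "Wilcoxon signed-rank test (exact sign-flip enumeration)"
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5  # continuity correction toward the mean
    z_g <- (W - mu - cc) / sqrt(sigma2)
    z_l <- (W - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two_sided = min(1, 2 * min(
                  stats::pnorm(z_g, lower.tail = FALSE),
                  stats::pnorm(z_l))))
    method <- "Wilcoxon signed-rank test (normal approximation, tie-corrected)"
    exact <- FALSE
  }
  .new_test_result(W, p, n, alternative, method, exact = exact, mu0 = mu0)
}

#' Test per-bee statistics against an enumerated chance level
#'
#' Signed-rank test of a vector of per-bee statistics (accuracies or
#' conditional probabilities) against the chance constant supplied by
#' [chance_level()]; the chance level is an argument, never hard-coded, so
#' the arena composition flows through the inference.
#'
#' @param values Per-bee statistic values (NAs dropped).
#' @param chance Chance level from [chance_level()].
#' @param alternative Defaults to `"greater"` (above chance).
#' @param ... Passed to [signed_rank_test()].
#' @return A `test_result`.
#' @export
test_above_chance <- function(values, chance, alternative = "greater", ...) {
  res <- signed_rank_test(values, mu0 = chance, alternative = alternative,
                          ...)
  res$method <- sprintf("%s vs chance level %.4g", res$method, chance)
  res$chance <- chance
  res
}

#' Spearman rank correlation with exact permutation p-value
#'
#' rho is the Pearson correlation of mean ranks. For `n <= exact_max` the
#' p-value comes from the full permutation distribution of the rank
#' statistic (exhaustive enumeration, tie-aware); above that, the t
#' approximation on `n - 2` degrees of freedom is used.
#'
#' @param x,y Paired observations, `n >= 3`.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @param exact_max Largest n enumerated exactly (default 10).
#' @return A `test_result` with `rho` attached.
#' @export
spearman_correlation <- function(x, y,
                                 alternative = c("two_sided", "greater",
                                                 "less"),
                                 exact_max = 10L) {
  alternative <- match.arg(alternative)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant input vector: rho undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    s_obs <- sum(rx * ry)
    cnt <- spearman_perm_counts(rx, ry, s_obs, 1e-9)
    p <- switch(alternative,
                greater = cnt[2] / cnt[1],
                less = cnt[3] / cnt[1],
                two_sided = cnt[4] / cnt[1])
    method <- "Spearman rank correlation (exact permutation)"
    exact <- TRUE
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- switch(alternative,
                greater = stats::pt(t_stat, n - 2, lower.tail = FALSE),
                less = stats::pt(t_stat, n - 2),
                two_sided = 2 * stats::pt(abs(t_stat), n - 2,
                                          lower.tail = FALSE))
    method <- "Spearman rank correlation (t approximation)"
    exact <- FALSE
  }
  .new_test_result(rho, p, n, alternative, method, rho = rho, exact = exact)
}

#' Detect a strategy switch across training blocks
#'
#' Per block, across bees: \emph{rule evidence} is first-choice accuracy
#' significantly above the unconditioned chance level; \emph{WSLS evidence}
#' is both conditional probabilities significantly above their enumerated
#' chance levels (win-stay vs the after-correct level, lose-switch vs the
#' after-incorrect level). Blocks are labelled `rule`, `wsls`, `mixed`
#' (both), `random` (neither) or `indeterminate` (insufficient data). The
#' inferred switch block is the first block showing WSLS evidence without
#' rule evidence, provided some earlier block showed rule evidence.
#'
#' @param summaries Per-bee, per-block data.frame from [block_summaries()].
#' @param arena The [arena_config()] the data come from (supplies the chance
#'   levels through [chance_level()]).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiplicity correction applied across all per-block
#'   p-values before thresholding: `"none"` (default, mirroring the
#'   uncorrected block analyses this procedure reproduces) or any method of
#'   [stats::p.adjust()], e.g. `"holm"`.
#' @return A list of class `switch_report`: `blocks` (per-block evidence
#'   table with p-values), `switch_block` (integer or NA), `alpha`.
#' @export
detect_strategy_switch <- function(summaries, arena = arena_config(),
                                   alpha = 0.05, p_adjust = "none") {
  need <- c("bee_id", "block_index", "accuracy_first", "p_win_stay",
            "p_lose_switch")
  if (!all(need %in% names(summaries)))
    stop("`summaries` must come from block_summaries()", call. = FALSE)
  blocks <- sort(unique(summaries$block_index))
  if (length(blocks) < 2L)
    stop("need at least 2 blocks to infer a switch", call. = FALSE)
  ch_first <- chance_level(arena$n_discs, arena$n_rewarded, "none")
  ch_ws <- chance_level(arena$n_discs, arena$n_rewarded, "correct")
  ch_ls <- chance_level(arena$n_discs, arena$n_rewarded, "incorrect")
  rows <- lapply(blocks, function(b) {
    sb <- summaries[summaries$block_index == b, , drop = FALSE]
    tst <- function(vals, chance) {
      vals <- vals[!is.na(vals)]
      if (length(vals) < 2L) return(NA_real_)
      suppressWarnings(test_above_chance(vals, chance))$p_value
    }
    data.frame(block_index = b, n_bees = nrow(sb),
               p_rule = tst(sb$accuracy_first, ch_first),
               p_win_stay = tst(sb$p_win_stay, ch_ws),
               p_lose_switch = tst(sb$p_lose_switch, ch_ls),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (p_adjust != "none") {
    p_cols <- c("p_rule", "p_win_stay", "p_lose_switch")
    adj <- stats::p.adjust(unlist(tab[p_cols]), method = p_adjust)
    tab[p_cols] <- matrix(adj, nrow = nrow(tab))
  }
  ind <- is.na(tab$p_rule) | is.na(tab$p_win_stay) |
    is.na(tab$p_lose_switch)
  tab$rule_evidence <- ifelse(ind, NA, tab$p_rule < alpha)
  tab$wsls_evidence <- ifelse(ind, NA, tab$p_win_stay < alpha &
                                tab$p_lose_switch < alpha)
  tab$label <- ifelse(ind, "indeterminate",
               ifelse(tab$rule_evidence & tab$wsls_evidence, "mixed",
               ifelse(tab$rule_evidence, "rule",
               ifelse(tab$wsls_evidence, "wsls", "random"))))
  switch_block <- NA_integer_
  for (i in seq_len(nrow(tab))) {
    if (isTRUE(tab$wsls_evidence[i]) && isFALSE(tab$rule_evidence[i]) &&
        any(tab$rule_evidence[seq_len(i - 1L)] %in% TRUE)) {
      switch_block <- tab$block_index[i]
      break
    }
  }
  structure(list(blocks = tab, switch_block = switch_block, alpha = alpha),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  print(x$blocks, row.names = FALSE)
  cat(if (is.na(x$switch_block)) "No strategy switch detected.\n"
      else sprintf("Strategy switch inferred at block %d (alpha = %g).\n",
                   x$switch_block, x$alpha))
  invisible(x)
}

#' Per-bee accuracy in a phase
#'
#' @param log A choice-log data.frame.
#' @param phase Phase(s) to pool (default the learning test).
#' @return Named numeric vector of per-bee proportions correct.
#' @export
test_accuracy <- function(log, phase = "learning_test") {
  .check_log(log)
  sub <- log[log$phase %in% phase, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no choices in the requested phase(s)",
                            call. = FALSE)
  out <- tapply(sub$correct, sub$bee_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Split-half comparison of unrewarded test performance
#'
#' Per bee and test bout, the choice sequence is split at its midpoint (an
#' odd middle choice goes to the first half); each bee's first-half and
#' second-half accuracies are pooled over the supplied test bouts and
#' compared by a one-sided signed-rank test (second half greater).
#'
#' @param log A choice-log data.frame.
#' @param phase Test phase(s) to pool (default all three tests).
#' @return A list: `per_bee` (first/second-half accuracies), `test` (the
#'   paired `test_result`), `mean_first`, `mean_second`.
#' @export
split_half_test_performance <- function(log,
                                        phase = c("learning_test",
                                                  "novel_shape_test",
                                                  "novel_color_test")) {
  .check_log(log)
  sub <- log[log$phase %in% phase, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no test-phase choices", call. = FALSE)
  key <- interaction(sub$bee_id, sub$bout_index, drop = TRUE)
  lens <- tapply(sub$choice_index, key, max)
  sub$bout_len <- as.integer(lens[as.character(key)])
  short <- sub$bout_len < 2L
  if (any(short)) {
    warning(sprintf("%d test bout(s) with < 2 choices excluded",
                    length(unique(key[short]))), call. = FALSE)
    sub <- sub[!short, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no test bouts with >= 2 choices",
                              call. = FALSE)
  }
  in_first <- sub$choice_index <= ceiling(sub$bout_len / 2)
  agg <- function(mask) tapply(sub$correct[mask], sub$bee_id[mask], mean)
  first <- agg(in_first)
  second <- agg(!in_first)
  bees <- intersect(names(first), names(second))
  per_bee <- data.frame(bee_id = bees,
                        first_half = as.numeric(first[bees]),
                        second_half = as.numeric(second[bees]),
                        stringsAsFactors = FALSE)
  res <- signed_rank_test(per_bee$second_half - per_bee$first_half,
                          alternative = "greater")
  res$method <- paste(res$method, "(second half - first half)")
  list(per_bee = per_bee, test = res,
       mean_first = mean(per_bee$first_half),
       mean_second = mean(per_bee$second_half))
}

#' Correlation between mid-training first-choice accuracy and test accuracy
#'
#' Spearman correlation of each bee's first-choice accuracy in a chosen
#' training block (default block 2, the mid-training window before a late
#' strategy switch) with its accuracy in the unrewarded learning test.
#'
#' @param summaries Per-bee, per-block data.frame from [block_summaries()].
#' @param test_acc Named per-bee test accuracies from [test_accuracy()].
#' @param block Which training block to use (default 2).
#' @return A `test_result` from [spearman_correlation()].
#' @export
training_test_correlation <- function(summaries, test_acc, block = 2L) {
  sb <- summaries[summaries$block_index == block, , drop = FALSE]
  if (nrow(sb) == 0L) stop(sprintf("no block %d in `summaries`", block),
                           call. = FALSE)
  bees <- intersect(sb$bee_id, names(test_acc))
  if (length(bees) < 3L)
    stop("need at least 3 bees present in both inputs", call. = FALSE)
  x <- sb$accuracy_first[match(bees, sb$bee_id)]
  spearman_correlation(x, as.numeric(test_acc[bees]))
}
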