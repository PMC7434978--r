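# Independent oracles used by the tests. Each is deliberately written as a
# brute-force/enumeration alternative to the package's own code paths.

# Chance level by exhaustive enumeration over all rewarded-set assignments
# and ordered disc pairs: an uninformed chooser picks disc 1 uniformly and
# its next disc uniformly among the others.
chance_enum <- function(n_discs, n_rewarded,
                        first_outcome = c("none", "correct", "incorrect")) {
  first_outcome <- match.arg(first_outcome)
  sets <- utils::combn(n_discs, n_rewarded, simplify = FALSE)
  num <- 0L; den <- 0L
  for (S in sets) {
    for (d1 in seq_len(n_discs)) {
      if (first_outcome == "none") {
        den <- den + 1L
        num <- num + (d1 %in% S)
      } else {
        want <- if (first_outcome == "correct") d1 %in% S else !(d1 %in% S)
        if (!want) next
        for (d2 in setdiff(seq_len(n_discs), d1)) {
          den <- den + 1L
          num <- num + (d2 %in% S)
        }
      }
    }
  }
  num / den
}

# Exact signed-rank tail probability by enumerating all 2^n sign vectors
# (independent of the DP in the package). Returns P(W+ >= w) and P(W+ <= w).
signed_rank_enum <- function(ranks, w) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% ranks)
  c(ge = mean(W >= w - 1e-9), le = mean(W <= w + 1e-9))
}

# All permutations of 1..n (recursive; for small n only).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Exact two-sided Spearman permutation p-value by brute force in R.
spearman_enum_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  P <- all_perms(length(x))
  S <- apply(P, 1, function(p) sum(rx[p] * ry))
  s_obs <- sum(rx * ry)
  s_mean <- mean(S)
  mean(abs(S - s_mean) >= abs(s_obs - s_mean) - 1e-9)
}

# Expected nearest-disc rate and mean rank for a spatially uniform chooser,
# computed directly from grid coordinates (no package geometry helpers).
uniform_rank_enum <- function(cols = 3, rows = 2, dx = 14, dy = 9.3) {
  xy <- expand.grid(cx = seq_len(cols), ry = seq_len(rows))
  x <- (xy$cx - 1) * dx; y <- (xy$ry - 1) * dy
  n <- nrow(xy)
  ranks <- c()
  for (p in seq_len(n)) {
    o <- setdiff(seq_len(n), p)
    d <- sqrt((x[o] - x[p])^2 + (y[o] - y[p])^2)
    ranks <- c(ranks, rank(d))
  }
  list(nearest_rate = mean(ranks == 1), mean_rank = mean(ranks))
}

# Build a choice log from explicit per-bout correctness vectors; disc ids
# alternate so consecutive landings are on distinct discs.
make_log <- function(bouts, bee_id = "b1", phase = "training",
                     reward_follows_correct = TRUE) {
  pos_x <- c(0, 14, 28, 0, 14, 28)
  pos_y <- c(0, 0, 0, 9.3, 9.3, 9.3)
  rows <- lapply(seq_along(bouts), function(b) {
    corr <- as.logical(bouts[[b]])
    k <- length(corr)
    disc <- rep(c(1L, 2L), length.out = k)
    rewarded <- if (reward_follows_correct && phase == "training")
      corr & cumsum(corr) <= 3 else rep(FALSE, k)
    data.frame(bee_id = bee_id, group = "larger", phase = phase,
               bout_index = b, choice_index = seq_len(k), disc_id = disc,
               disc_x = pos_x[disc], disc_y = pos_y[disc],
               size_class_chosen = ifelse(corr, "larger", "smaller"),
               correct = corr, reward_received = rewarded & corr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Several bees at once: `bee_bouts` is a named list of bout lists.
make_cohort_log <- function(bee_bouts, phase = "training") {
  do.call(rbind, lapply(names(bee_bouts), function(b)
    make_log(bee_bouts[[b]], bee_id = b, phase = phase)))
}
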