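# Independent oracles used across the suite: brute-force counterparts of
# the package's closed-form or greedy computations.

# AUC as the tie-adjusted probability that a positive outranks a negative.
pair_counting_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Silhouette from the full record-level pairwise distance matrix.
brute_silhouette <- function(records, labels, space) {
  n <- nrow(records)
  singles <- lapply(seq_len(n), function(i)
    cluster_summary(records[i, , drop = FALSE], space))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    D[i, j] <- D[j, i] <- loglik_distance(singles[[i]], singles[[j]], space)
  s <- vapply(seq_len(n), function(i) {
    mine <- labels == labels[i]
    if (sum(mine) <= 1) return(0)
    a <- sum(D[i, mine]) / (sum(mine) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# All set partitions of 1..n (restricted growth strings).
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(assign, next_max) {
    if (length(assign) == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (g in seq_len(next_max + 1L))
      grow(c(assign, g), max(next_max, g))
  }
  grow(integer(0), 0L)
  out
}

# Exact two-sided signed-rank p value by enumerating all sign vectors.
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  ev <- sum(r) / 2
  mean(abs(v_null - ev) >= abs(v_obs - ev) - 1e-12)
}

# Small crafted cohort rows in the canonical schema.
blank_episode <- function(n = 1) {
  coh <- generate_cohort(cohort_params(n_episodes = n, seed = 999,
                                       death_rate = 0))
  coh
}
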