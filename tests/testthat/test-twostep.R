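# Two-step clustering engine: distance, preclustering, agglomeration,
# criterion-based selection, quality, rule derivation.

cat_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df[] <- lapply(df, as.character)
  df
}

test_that("log-likelihood distance matches hand-computed entropies", {
  df <- cat_df(x = c("0", "0", "1"))
  sp <- make_cluster_space(df)
  s <- function(i) cluster_summary(df[i, , drop = FALSE], sp)
  # identical singletons merge at zero cost
  expect_equal(loglik_distance(s(1), s(2), sp), 0)
  # one differing binary variable: merged entropy mass 2*ln 2
  expect_equal(loglik_distance(s(1), s(3), sp), 2 * log(2))
})

test_that("distance is symmetric and nonnegative on random summaries", {
  set.seed(101)
  for (rep in 1:20) {
    df <- cat_df(a = sample(0:2, 8, TRUE), b = sample(0:1, 8, TRUE))
    sp <- make_cluster_space(df)
    g1 <- cluster_summary(df[1:4, ], sp)
    g2 <- cluster_summary(df[5:8, ], sp)
    d12 <- loglik_distance(g1, g2, sp)
    expect_gte(d12, 0)
    expect_equal(d12, loglik_distance(g2, g1, sp))
  }
})

test_that("summaries are mergeable: union equals elementwise sum", {
  set.seed(7)
  df <- cat_df(a = sample(0:2, 10, TRUE), b = sample(0:1, 10, TRUE))
  sp <- make_cluster_space(df)
  ab <- merge_summaries(cluster_summary(df[1:4, ], sp),
                        cluster_summary(df[5:10, ], sp))
  expect_equal(ab, cluster_summary(df, sp))
})

test_that("distance on mixed continuous data uses the pooled offset", {
  df <- data.frame(x = c(1, 1, 5, 5))
  sp <- make_cluster_space(df, continuous = "x")
  a <- cluster_summary(df[1:2, , drop = FALSE], sp)
  b <- cluster_summary(df[3:4, , drop = FALSE], sp)
  # hand computation: pooled ML variance 4; within-cluster variances 0;
  # merged cluster has variance 4
  xi_a <- -2 * 0.5 * log(4 + 0)
  xi_ab <- -4 * 0.5 * log(4 + 4)
  expect_equal(loglik_distance(a, b, sp), 2 * xi_a - xi_ab)
  expect_gt(loglik_distance(a, b, sp), 0)
})

test_that("preclustering separates distinct profiles and honors +Inf", {
  df <- cat_df(x = rep(c("0", "1"), 10), y = rep(c("a", "b"), 10))
  expect_equal(length(precluster(df)$summaries), 2L)
  same <- cat_df(x = rep("0", 5))
  expect_equal(length(precluster(same)$summaries), 1L)
  # any threshold accepts every merge when infinite
  expect_equal(length(precluster(df, distance_threshold = Inf)$summaries),
               1L)
  expect_error(precluster(df[0, , drop = FALSE]), "empty")
})

test_that("precluster rebuild caps the precluster count", {
  set.seed(33)
  df <- cat_df(a = sample(0:2, 40, TRUE), b = sample(0:2, 40, TRUE),
               c = sample(0:1, 40, TRUE))
  pre <- precluster(df, distance_threshold = 0, max_preclusters = 5)
  expect_lte(length(pre$summaries), 5)
  expect_gt(pre$threshold, 0)
  # every record still belongs to exactly one precluster
  expect_setequal(unlist(pre$members), seq_len(nrow(df)))
})

test_that("greedy agglomeration merges the closest pair first", {
  # three profile groups on a line of separations (small, large):
  # a and b share one of two variables, c differs in both
  df <- cat_df(x = c("0", "0", "0", "0", "1", "1"),
               y = c("0", "0", "1", "1", "2", "2"))
  pre <- precluster(df)
  expect_equal(length(pre$summaries), 3L)
  trace <- agglomerate(pre)
  first <- trace$merges[1, ]
  expect_setequal(c(first$a, first$b), c(1L, 2L))
  expect_equal(nrow(trace$merges), 2L)
  # single precluster: empty trace
  one <- precluster(cat_df(x = rep("0", 4)))
  expect_equal(nrow(agglomerate(one)$merges), 0L)
})

test_that("each greedy merge is the global minimum pair (<= 8 preclusters)", {
  set.seed(55)
  for (rep in 1:5) {
    df <- cat_df(a = sample(0:2, 30, TRUE), b = sample(0:1, 30, TRUE))
    pre <- precluster(df)
    if (length(pre$summaries) > 8) next
    space <- pre$space
    trace <- agglomerate(pre)
    # replay: at each step the recorded distance equals the brute-force
    # minimum over all active pairs
    active <- pre$summaries
    names(active) <- seq_along(active)
    for (i in seq_len(nrow(trace$merges))) {
      labs <- names(active)
      dmin <- Inf
      for (p in seq_len(length(active) - 1))
        for (q in seq.int(p + 1, length(active)))
          dmin <- min(dmin, loglik_distance(active[[p]], active[[q]],
                                            space))
      m <- trace$merges[i, ]
      expect_equal(m$distance, dmin, tolerance = 1e-12)
      merged <- merge_summaries(active[[as.character(m$a)]],
                                active[[as.character(m$b)]])
      active[as.character(c(m$a, m$b))] <- NULL
      active[[as.character(m$new)]] <- merged
    }
  }
})

test_that("BIC matches hand computation and rewards true structure", {
  df4 <- cat_df(x = c("0", "0", "1", "1"))
  sp4 <- make_cluster_space(df4)
  expect_equal(bic(list(cluster_summary(df4, sp4)), sp4),
               8 * log(2) + log(4))
  # zero-entropy data: BIC is exactly the parameter penalty
  dfc <- cat_df(x = rep("0", 6))
  spc <- make_cluster_space(dfc)
  expect_equal(bic(list(cluster_summary(dfc, spc)), spc), 0)
  # splitting two well-separated groups lowers the criterion
  df <- cat_df(x = rep(c("0", "1"), each = 20),
               y = rep(c("a", "b"), each = 20))
  sp <- make_cluster_space(df)
  b1 <- bic(list(cluster_summary(df, sp)), sp)
  b2 <- bic(list(cluster_summary(df[1:20, ], sp),
                 cluster_summary(df[21:40, ], sp)), sp)
  expect_lt(b2, b1)
})

test_that("select_k finds true group counts and honors k_fixed", {
  df <- cat_df(x = rep(c("0", "1"), each = 20),
               y = rep(c("a", "b"), each = 20))
  fit <- twostep(df)
  expect_equal(fit$k, 2L)
  expect_equal(twostep(cat_df(x = rep("0", 10)))$k, 1L)
  set.seed(9)
  df3 <- cat_df(a = sample(0:2, 30, TRUE), b = sample(0:2, 30, TRUE))
  expect_equal(twostep(df3, k_fixed = 3)$k, 3L)
  pre <- precluster(df)
  expect_error(select_k(agglomerate(pre), k_fixed = 10),
               "exceeds")
})

test_that("BIC-selected k agrees with exhaustive partition search", {
  # on clearly structured data the greedy cut at the BIC-optimal k must
  # coincide with the best partition over all set partitions of the
  # distinct profiles
  df <- cat_df(x = c(rep("0", 12), rep("1", 10), rep("2", 11)),
               y = c(rep("a", 12), rep("b", 10), rep("b", 11)))
  pre <- precluster(df)
  P <- length(pre$summaries)
  expect_lte(P, 8)
  trace <- agglomerate(pre)
  k_greedy <- select_k(trace, k_max = P)
  best_bic <- Inf
  best_k <- NA
  for (part in all_set_partitions(P)) {
    summ <- lapply(split(seq_len(P), part), function(g)
      Reduce(merge_summaries, pre$summaries[g]))
    b <- bic(unname(summ), pre$space)
    if (b < best_bic - 1e-9) {
      best_bic <- b
      best_k <- length(summ)
    }
  }
  expect_equal(k_greedy, best_k)
  expect_equal(min(trace$bic_by_k), best_bic, tolerance = 1e-9)
})

test_that("quality is 1 for perfectly separated clusters and matches
           brute-force silhouette", {
  df <- cat_df(x = rep(c("0", "1"), each = 5),
               y = rep(c("a", "b"), each = 5))
  fit <- twostep(df, k_fixed = 2)
  expect_equal(fit$quality, 1.0)

  # 6-record crafted instance with imperfect clusters
  df6 <- cat_df(x = c("0", "0", "1", "1", "1", "2"),
                y = c("a", "a", "a", "b", "b", "b"))
  sp <- make_cluster_space(df6)
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  part <- structure(list(assignment = labels, k = 2L),
                    class = "cluster_partition")
  expect_equal(quality(part, df6, sp),
               brute_silhouette(df6, labels, sp), tolerance = 1e-12)
  expect_error(quality(structure(list(assignment = rep(1L, 6), k = 1L),
                                 class = "cluster_partition"), df6, sp),
               "fewer than 2")
})

test_that("random labels on homogeneous data give near-zero quality", {
  set.seed(17)
  qs <- replicate(10, {
    df <- cat_df(a = sample(0:1, 24, TRUE), b = sample(0:1, 24, TRUE))
    sp <- make_cluster_space(df)
    part <- structure(list(assignment = sample(1:2, 24, TRUE), k = 2L),
                      class = "cluster_partition")
    if (length(unique(part$assignment)) < 2) NA_real_
    else quality(part, df, sp)
  })
  expect_lte(mean(qs, na.rm = TRUE), 0.1)
})

test_that("derived rule tables order clusters by severity", {
  df <- cat_df(a = c(rep("0", 10), rep("1", 8), rep("2", 9)),
               b = c(rep("0", 10), rep("1", 8), rep("2", 9)),
               c = c(rep("0", 10), rep("0", 8), rep("2", 9)),
               d = c(rep("0", 10), rep("0", 8), rep("2", 9)))
  fit <- twostep(df, k_fixed = 3)
  rt <- derive_dimension_rules(fit$partition, df, 3)
  expect_equal(apply_rule_table(rt, c("0", "0", "0", "0")), 0L)
  expect_equal(apply_rule_table(rt, c("1", "1", "0", "0")), 1L)
  expect_equal(apply_rule_table(rt, c("2", "2", "2", "2")), 2L)
  # unseen combinations map to the worst score
  expect_equal(apply_rule_table(rt, c("2", "0", "1", "2")), 2L)
  # single-combination clusters make the table a bijection
  expect_equal(nrow(rt), 3L)
  expect_setequal(rt$score, 0:2)
  expect_error(derive_dimension_rules(fit$partition, df, 4), "clusters")
})

test_that("clustering from summaries equals clustering from raw rows", {
  set.seed(23)
  df <- cat_df(a = sample(0:2, 40, TRUE), b = sample(0:1, 40, TRUE))
  sp <- make_cluster_space(df)
  pre <- precluster(df, sp)
  # every precluster summary equals the summary of its member rows
  for (p in seq_along(pre$summaries))
    expect_equal(pre$summaries[[p]],
                 cluster_summary(df[pre$members[[p]], , drop = FALSE], sp))
  # BIC by k from the trace equals direct evaluation of the cut partition
  trace <- agglomerate(pre)
  for (k in seq_len(min(4, length(pre$summaries)))) {
    part <- cut_assignment(pre, trace, k)
    direct <- lapply(split(seq_len(nrow(df)), part$assignment),
                     function(i) cluster_summary(df[i, , drop = FALSE], sp))
    expect_equal(unname(trace$bic_by_k[[k]]), bic(unname(direct), sp),
                 tolerance = 1e-9)
  }
})
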