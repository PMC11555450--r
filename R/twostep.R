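# Two-step mixed-type clustering: sequential preclustering, hierarchical
# agglomeration of precluster summaries under a log-likelihood distance,
# cluster-count selection by the Schwarz-Bayesian criterion, and a
# silhouette-based quality coefficient.
#
# Clusters are carried as sufficient summaries (per-variable category
# counts; sums and sums of squares for continuous variables), so the
# summary of a merged cluster is the elementwise sum of its parts and
# all distances are computable without revisiting the raw rows.

# ---- cluster space and summaries -------------------------------------

#' Describe the variable space of a clustering run
#'
#' Records the declared levels of every categorical variable and the
#' pooled (whole-sample, maximum-likelihood) variance of every continuous
#' variable. The pooled variance offsets the within-cluster variance in
#' the distance's continuous term so a constant cluster never takes
#' `log(0)`.
#'
#' @param records data frame of clustering variables.
#' @param continuous names of columns to treat as continuous; all others
#'   are categorical.
#' @return A list of class `cluster_space`.
#' @export
make_cluster_space <- function(records, continuous = character()) {
  stopifnot(is.data.frame(records))
  bad <- setdiff(continuous, names(records))
  if (length(bad)) stop("unknown continuous variable: ",
                        paste(bad, collapse = ", "))
  cat_vars <- setdiff(names(records), continuous)
  cat_levels <- lapply(records[cat_vars], function(x)
    sort(unique(as.character(x[!is.na(x)]))))
  names(cat_levels) <- cat_vars
  pooled_var <- vapply(records[continuous], function(x) {
    x <- x[!is.na(x)]
    sum((x - mean(x))^2) / length(x)
  }, numeric(1))
  structure(list(cat_levels = cat_levels,
                 cont_vars = continuous,
                 pooled_var = pooled_var),
            class = "cluster_space")
}

#' Summarize a set of records as one cluster
#'
#' @param records data frame of clustering variables (rows = members).
#' @param space a [make_cluster_space()] object for the full dataset.
#' @return A `cluster_summary`: member count, per-variable category
#'   counts (missing values excluded), and per-continuous-variable
#'   (n, sum, sum of squares).
#' @export
cluster_summary <- function(records, space) {
  if (nrow(records) == 0) stop("empty cluster")
  cat <- lapply(names(space$cat_levels), function(v) {
    x <- as.character(records[[v]])
    x <- x[!is.na(x)]
    tab <- table(factor(x, levels = space$cat_levels[[v]]))
    as.vector(tab)
  })
  names(cat) <- names(space$cat_levels)
  cont <- lapply(space$cont_vars, function(v) {
    x <- records[[v]]
    x <- x[!is.na(x)]
    c(n = length(x), sum = sum(x), sumsq = sum(x^2))
  })
  names(cont) <- space$cont_vars
  structure(list(n = nrow(records), cat = cat, cont = cont),
            class = "cluster_summary")
}

#' Merge two cluster summaries
#'
#' The summary of a union is the elementwise sum of the parts.
#'
#' @param a,b `cluster_summary` objects over the same variable space.
#' @return The merged `cluster_summary`.
#' @export
merge_summaries <- function(a, b) {
  check_same_space(a, b)
  structure(list(
    n = a$n + b$n,
    cat = Map(`+`, a$cat, b$cat),
    cont = Map(`+`, a$cont, b$cont)
  ), class = "cluster_summary")
}

check_same_space <- function(a, b) {
  if (!identical(names(a$cat), names(b$cat)) ||
      !identical(names(a$cont), names(b$cont)) ||
      !identical(lengths(a$cat), lengths(b$cat)))
    stop("summaries are over different variable sets")
}

# Log-likelihood term xi_v of one cluster: minus (categorical entropy
# mass + continuous half-log-variance mass). Each categorical variable's
# entropy is weighted by its own non-missing count (missing values are
# excluded from the denominator, never imputed).
cluster_xi <- function(s, space) {
  xi <- 0
  for (v in names(s$cat)) {
    cnt <- s$cat[[v]]
    nv <- sum(cnt)
    if (nv > 0) {
      p <- cnt[cnt > 0] / nv
      xi <- xi - nv * (-sum(p * log(p)))
    }
  }
  for (v in names(s$cont)) {
    st <- s$cont[[v]]
    if (st["n"] > 0) {
      varml <- st["sumsq"] / st["n"] - (st["sum"] / st["n"])^2
      varml <- max(varml, 0)
      xi <- xi - st["n"] * 0.5 * log(space$pooled_var[[v]] + varml)
    }
  }
  unname(xi)
}

#' Log-likelihood distance between two clusters
#'
#' `d(a, b) = xi_a + xi_b - xi_{a union b}`, the decrease in log-likelihood
#' when the two clusters are merged, under the working assumption that
#' variables are independent within clusters. Nonnegative (up to 1e-9
#' numerical tolerance) and symmetric.
#'
#' @param a,b `cluster_summary` objects over the same variable space.
#' @param space the [make_cluster_space()] object.
#' @return Nonnegative distance.
#' @export
#' @examples
#' df <- data.frame(x = c("0", "1"))
#' sp <- make_cluster_space(df)
#' s1 <- cluster_summary(df[1, , drop = FALSE], sp)
#' s2 <- cluster_summary(df[2, , drop = FALSE], sp)
#' loglik_distance(s1, s2, sp)   # 2 * log(2)
loglik_distance <- function(a, b, space) {
  check_same_space(a, b)
  d <- cluster_xi(a, space) + cluster_xi(b, space) -
    cluster_xi(merge_summaries(a, b), space)
  if (d < -1e-9) stop("negative log-likelihood distance: ", d)
  max(d, 0)
}

# ---- step one: sequential preclustering ------------------------------

profile_key <- function(records) {
  apply(as.matrix(records), 1, function(r)
    paste(ifelse(is.na(r), "<NA>", r), collapse = "|"))
}

#' Precluster records in one sequential pass
#'
#' Each record joins its nearest existing precluster when the merge
#' distance is within the threshold, otherwise it founds a new one. If
#' the precluster count exceeds `max_preclusters`, the threshold is
#' raised by half and the preclusters are rebuilt from their summaries.
#' With the default zero threshold and categorical variables this yields
#' one precluster per distinct observed profile (the merge distance is
#' zero exactly for identical profiles).
#'
#' @param records data frame of clustering variables.
#' @param space a [make_cluster_space()] object; built from `records`
#'   when omitted.
#' @param distance_threshold merge acceptance threshold (default 0).
#' @param max_preclusters rebuild trigger (default 200).
#' @return A list of class `precluster_set`: `summaries` (list of
#'   `cluster_summary`), `members` (list of row-index vectors),
#'   `threshold` (final threshold), `space`.
#' @export
precluster <- function(records, space = NULL, distance_threshold = 0,
                       max_preclusters = 200) {
  if (!nrow(records)) stop("empty input")
  if (is.null(space)) space <- make_cluster_space(records)
  all_cat <- length(space$cont_vars) == 0

  fast <- NULL
  if (all_cat && distance_threshold <= 0) {
    # exact fast path: identical profiles are the only zero-distance
    # merges, so the pass lands one precluster per distinct profile in
    # first-appearance order
    keys <- profile_key(records[names(space$cat_levels)])
    first <- !duplicated(keys)
    idx <- split(seq_len(nrow(records)), factor(keys, levels = keys[first]))
    summaries <- lapply(idx, function(i)
      cluster_summary(records[i, , drop = FALSE], space))
    fast <- list(summaries = unname(summaries), members = unname(idx))
    if (length(fast$summaries) <= max_preclusters) {
      out <- c(fast, list(threshold = distance_threshold, space = space))
      class(out) <- "precluster_set"
      return(out)
    }
  }

  pass <- function(items, members, threshold) {
    summaries <- list()
    mem <- list()
    for (j in seq_along(items)) {
      s <- items[[j]]
      if (length(summaries)) {
        d <- vapply(summaries, loglik_distance, numeric(1), b = s,
                    space = space)
        best <- which.min(d)
      } else d <- Inf
      if (length(summaries) && d[best] <= threshold) {
        summaries[[best]] <- merge_summaries(summaries[[best]], s)
        mem[[best]] <- c(mem[[best]], members[[j]])
      } else {
        summaries[[length(summaries) + 1L]] <- s
        mem[[length(mem) + 1L]] <- members[[j]]
      }
    }
    list(summaries = summaries, members = mem)
  }
  threshold <- distance_threshold
  res <- if (is.null(fast)) {
    singletons <- lapply(seq_len(nrow(records)), function(i)
      cluster_summary(records[i, , drop = FALSE], space))
    pass(singletons, as.list(seq_len(nrow(records))), threshold)
  } else fast
  while (length(res$summaries) > max_preclusters) {
    threshold <- if (threshold > 0) threshold * 1.5 else 1e-3
    res <- pass(res$summaries, res$members, threshold)
  }
  structure(list(summaries = res$summaries, members = res$members,
                 threshold = threshold, space = space),
            class = "precluster_set")
}

# ---- step two: hierarchical agglomeration ----------------------------

#' Agglomerate preclusters down to a single cluster
#'
#' Greedy pairwise merging by minimum log-likelihood distance, recording
#' every merge. Ties break on the lowest (a, b) label pair. Labels 1..P
#' are the input preclusters; merge i creates label P + i.
#'
#' @param pre a [precluster()] result (or list with `summaries` and
#'   `space`).
#' @return A list of class `merge_trace`: `merges` (data frame with
#'   columns `a`, `b`, `distance`, `new`), `n_preclusters`, `bic_by_k`
#'   (named numeric, BIC of the partition cut at each k), `space`, and
#'   the input `summaries`.
#' @export
agglomerate <- function(pre) {
  summaries <- pre$summaries
  space <- pre$space
  P <- length(summaries)
  active <- stats::setNames(summaries, seq_len(P))
  ids <- seq_len(P)
  merges <- data.frame(a = integer(0), b = integer(0),
                       distance = numeric(0), new = integer(0))
  next_id <- P + 1L
  while (length(active) > 1) {
    labs <- as.integer(names(active))
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(length(active) - 1)) {
      for (j in seq.int(i + 1, length(active))) {
        d <- loglik_distance(active[[i]], active[[j]], space)
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(labs[i], labs[j])
        }
      }
    }
    merges <- rbind(merges, data.frame(a = best[1], b = best[2],
                                       distance = best_d, new = next_id))
    merged <- merge_summaries(active[[as.character(best[1])]],
                              active[[as.character(best[2])]])
    active[as.character(best)] <- NULL
    active[[as.character(next_id)]] <- merged
    next_id <- next_id + 1L
  }
  trace <- structure(list(merges = merges, n_preclusters = P,
                          summaries = summaries, space = space),
                     class = "merge_trace")
  trace$bic_by_k <- vapply(seq_len(P), function(k)
    bic(cut_partition(trace, k), space), numeric(1))
  names(trace$bic_by_k) <- seq_len(P)
  trace
}

# Partition of the preclusters into k clusters implied by undoing the
# last k-1 merges: list of cluster_summary.
cut_partition <- function(trace, k, members = FALSE) {
  P <- trace$n_preclusters
  stopifnot(k >= 1, k <= P)
  parent <- seq_len(P + nrow(trace$merges))
  n_merges <- P - k
  for (i in seq_len(n_merges)) {
    m <- trace$merges[i, ]
    parent[c(m$a, m$b)] <- m$new
  }
  root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  roots <- vapply(seq_len(P), root, integer(1))
  groups <- split(seq_len(P), roots)
  if (members) return(unname(groups))
  unname(lapply(groups, function(g)
    Reduce(merge_summaries, trace$summaries[g])))
}

#' Schwarz-Bayesian information criterion of a partition
#'
#' `BIC(J) = -2 * sum_v xi_v + m_J * log(N)` with
#' `m_J = J * (2 * K_continuous + sum_k (L_k - 1))` effective parameters
#' (natural logarithms).
#'
#' @param partition list of `cluster_summary`, one per cluster.
#' @param space the [make_cluster_space()] object.
#' @return The criterion value (smaller is better).
#' @export
bic <- function(partition, space) {
  if (!length(partition)) stop("empty partition")
  if (any(vapply(partition, function(s) s$n, numeric(1)) == 0))
    stop("empty cluster in partition")
  N <- sum(vapply(partition, function(s) s$n, numeric(1)))
  J <- length(partition)
  m <- J * (2 * length(space$cont_vars) +
            sum(vapply(space$cat_levels, length, numeric(1)) - 1))
  -2 * sum(vapply(partition, cluster_xi, numeric(1), space = space)) +
    m * log(N)
}

#' Select the number of clusters from a merge trace
#'
#' With `k_fixed` given, returns it (the cluster count defined in
#' advance). Otherwise returns the k in `[1, k_max]` minimizing the
#' Schwarz-Bayesian criterion, refined by the largest ratio of successive
#' merge distances among the k values whose criterion lies within 2% of
#' the minimum.
#'
#' @param trace an [agglomerate()] result.
#' @param k_max largest cluster count to consider.
#' @param k_fixed optional pre-defined cluster count.
#' @return Selected integer k.
#' @export
select_k <- function(trace, k_max = 15, k_fixed = NULL) {
  P <- trace$n_preclusters
  if (!is.null(k_fixed)) {
    if (k_fixed > P) stop("k_fixed exceeds the number of preclusters")
    return(as.integer(k_fixed))
  }
  ks <- seq_len(min(k_max, P))
  bics <- trace$bic_by_k[ks]
  near <- which(bics - min(bics) <= 0.02 * abs(min(bics)) + 1e-12)
  if (length(near) == 1) return(as.integer(ks[near]))
  # merge that reduces k+1 -> k clusters is merge number P - k
  merge_dist <- function(k) {
    i <- P - k
    if (i < 1 || i > nrow(trace$merges)) return(NA_real_)
    trace$merges$distance[i]
  }
  ratio <- vapply(ks[near], function(k) {
    d_here <- merge_dist(k - 1)   # distance of the merge collapsing k
    d_next <- merge_dist(k)       # distance of the previous merge
    if (is.na(d_here) || is.na(d_next)) return(-Inf)
    (d_here + 1e-12) / (d_next + 1e-12)
  }, numeric(1))
  as.integer(ks[near][which.max(ratio)])
}

#' Assign every record to a cluster at a chosen k
#'
#' @param pre the [precluster()] result used to build `trace`.
#' @param trace an [agglomerate()] result.
#' @param k cluster count.
#' @return A list of class `cluster_partition`: `assignment` (integer
#'   label per record, contiguous 1..k), `k`, and `precluster_cluster`
#'   (label per precluster).
#' @export
cut_assignment <- function(pre, trace, k) {
  groups <- cut_partition(trace, k, members = TRUE)
  pc_label <- integer(trace$n_preclusters)
  for (g in seq_along(groups)) pc_label[groups[[g]]] <- g
  n <- max(unlist(pre$members))
  assignment <- integer(n)
  for (p in seq_along(pre$members))
    assignment[pre$members[[p]]] <- pc_label[p]
  structure(list(assignment = assignment, k = length(groups),
                 precluster_cluster = pc_label),
            class = "cluster_partition")
}

#' Quality coefficient of a partition
#'
#' Mean silhouette over records, with the log-likelihood distance
#' between singleton summaries as the dissimilarity. Records sharing a
#' profile are collapsed and weighted, so the computation is quadratic
#' in the number of distinct profiles, not records. Values near 1 mean
#' cohesive, well-separated clusters; the raw value lies in \[-1, 1\]
#' and reports clamp it to \[0, 1\] for comparability with published
#' quality coefficients.
#'
#' @param partition a [cut_assignment()] result (k of at least 2).
#' @param records the clustered records.
#' @param space the [make_cluster_space()] object.
#' @return Mean silhouette in \[-1, 1\].
#' @export
quality <- function(partition, records, space = NULL) {
  if (partition$k < 2) stop("quality undefined for fewer than 2 clusters")
  if (is.null(space)) space <- make_cluster_space(records)
  lab <- partition$assignment
  if (any(!seq_len(partition$k) %in% lab)) stop("empty cluster")
  keys <- profile_key(records[c(names(space$cat_levels), space$cont_vars)])
  uk <- unique(keys)
  prof_idx <- match(keys, uk)
  reps <- match(uk, keys)
  singles <- lapply(reps, function(i)
    cluster_summary(records[i, , drop = FALSE], space))
  p <- length(uk)
  D <- matrix(0, p, p)
  if (p > 1) {
    for (i in seq_len(p - 1)) for (j in seq.int(i + 1, p)) {
      D[i, j] <- D[j, i] <- loglik_distance(singles[[i]], singles[[j]],
                                            space)
    }
  }
  # weight matrix: profiles x clusters
  W <- table(factor(prof_idx, levels = seq_len(p)),
             factor(lab, levels = seq_len(partition$k)))
  W <- matrix(as.numeric(W), nrow = p)
  cluster_n <- colSums(W)
  S <- D %*% W                      # sum of distances profile -> cluster
  sil_total <- 0
  for (q in seq_len(p)) {
    for (cl in which(W[q, ] > 0)) {
      w <- W[q, cl]
      if (cluster_n[cl] <= 1) next  # singleton clusters contribute 0
      a <- S[q, cl] / (cluster_n[cl] - 1)
      b <- min(S[q, -cl, drop = TRUE] / cluster_n[-cl])
      s <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
      sil_total <- sil_total + w * s
    }
  }
  sil_total / length(lab)
}

#' Run the full two-step clustering of a set of records
#'
#' Convenience driver: precluster, agglomerate, select k, assign, score
#' quality.
#'
#' @param records data frame of clustering variables.
#' @param continuous names of continuous columns.
#' @param k_fixed optional pre-defined cluster count.
#' @param k_max largest cluster count considered by automatic selection.
#' @param distance_threshold,max_preclusters passed to [precluster()].
#' @return A list of class `twostep_fit`: `partition`, `trace`, `pre`,
#'   `k`, `quality` (NA when k = 1), `space`.
#' @export
twostep <- function(records, continuous = character(), k_fixed = NULL,
                    k_max = 15, distance_threshold = 0,
                    max_preclusters = 200) {
  space <- make_cluster_space(records, continuous)
  pre <- precluster(records, space, distance_threshold, max_preclusters)
  trace <- agglomerate(pre)
  k <- select_k(trace, k_max = k_max, k_fixed = k_fixed)
  part <- cut_assignment(pre, trace, k)
  q <- if (k >= 2) quality(part, records, space) else NA_real_
  structure(list(partition = part, trace = trace, pre = pre, k = k,
                 quality = q, space = space),
            class = "twostep_fit")
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat(sprintf("two-step clustering: %d preclusters -> k = %d (quality %s)\n",
              x$trace$n_preclusters, x$k,
              ifelse(is.na(x$quality), "NA", sprintf("%.2f", x$quality))))
  invisible(x)
}

# ---- turning clusters into scoring rules -----------------------------

#' Derive an ordered category rule table from a partition
#'
#' Orders the clusters by mean indicator severity (sum of indicator
#' levels, missing read as the worst level) and assigns them scores
#' `0 .. target_levels - 1`. The rule table maps every observed
#' indicator combination to its cluster's score; combinations never seen
#' map to the worst score.
#'
#' @param partition a [cut_assignment()] with k equal to `target_levels`.
#' @param records the clustered indicator records.
#' @param target_levels number of score levels of the dimension.
#' @return A data frame (`combo`, `score`) of class `rule_table` with
#'   attributes `variables` and `worst`.
#' @export
derive_dimension_rules <- function(partition, records, target_levels) {
  if (partition$k != target_levels)
    stop("partition has ", partition$k, " clusters; dimension needs ",
         target_levels)
  # indicator levels as numbers; non-numeric categories fall back to
  # their position in the sorted level set
  lv <- vapply(records, function(x) {
    num <- suppressWarnings(as.numeric(x))
    if (all(is.na(num) == is.na(x))) return(num)
    as.numeric(factor(x, levels = sort(unique(x[!is.na(x)])))) - 1
  }, numeric(nrow(records)))
  lv <- matrix(lv, nrow = nrow(records))
  worst_level <- max(lv, na.rm = TRUE)
  lv[is.na(lv)] <- worst_level
  severity <- rowSums(lv)
  cl_sev <- tapply(severity, partition$assignment, mean)
  ord <- order(cl_sev)                 # mildest cluster first
  score_of_cluster <- integer(partition$k)
  score_of_cluster[ord] <- seq_len(partition$k) - 1L
  keys <- profile_key(records)
  first <- !duplicated(keys)
  rt <- data.frame(combo = keys[first],
                   score = score_of_cluster[partition$assignment[first]],
                   stringsAsFactors = FALSE)
  structure(rt, class = c("rule_table", "data.frame"),
            variables = colnames(records),
            worst = target_levels - 1L)
}

#' Apply a rule table to indicator combinations
#'
#' @param rt a [derive_dimension_rules()] table.
#' @param combos matrix (rows = records) or vector of indicator values.
#' @return Integer scores; unseen combinations get the worst score.
#' @export
apply_rule_table <- function(rt, combos) {
  if (!is.matrix(combos)) combos <- matrix(combos, nrow = 1)
  keys <- profile_key(as.data.frame(combos))
  hit <- match(keys, rt$combo)
  out <- rt$score[hit]
  out[is.na(hit)] <- attr(rt, "worst")
  as.integer(out)
}

#' Write a rule table as delimited text
#' @param rt rule table.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(rt, path, sep = ",") {
  utils::write.table(as.data.frame(rt), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
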