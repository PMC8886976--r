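# Ranking analysis (one pathogenic variant against 99 size-matched controls)
# and permutation feature importance over correlated-feature clusters.

#' Build size-matched ranking batches
#'
#' Bins control variants by size into `n_bins` equal-probability ECDF bins.
#' Each pathogenic variant not larger than the largest control is assigned
#' the bin containing (or, outside the edge range, closest to) its size; if
#' that bin holds at least `batch_size - 1` controls, a batch is formed from
#' the pathogenic variant plus `batch_size - 1` controls sampled without
#' replacement. Pathogenic variants whose bin is smaller are skipped and
#' reported.
#'
#' @param pathogenic data.frame with columns id, size, score.
#' @param controls data.frame with columns id, size, score.
#' @param batch_size total batch size (default 100, i.e. 1 + 99 controls).
#' @param n_bins ECDF bins over control sizes (default 60).
#' @param seed integer seed for control sampling.
#' @return list with `batches` (list of lists: pathogenic_id,
#'   pathogenic_score, control_ids, control_scores, bin) and `skipped`
#'   (data.table of pathogenic ids with the reason: too_large / bin_too_small).
#' @export
build_batches <- function(pathogenic, controls, batch_size = 100,
                          n_bins = 60, seed = 1L) {
  p <- data.table::as.data.table(pathogenic)
  ctl <- data.table::as.data.table(controls)
  stopifnot(all(c("id", "size", "score") %in% names(p)),
            all(c("id", "size", "score") %in% names(ctl)),
            nrow(ctl) > 0L)
  n_controls <- batch_size - 1L
  binning <- ecdf_size_bins(ctl$size, n_bins)
  cb <- assign_size_bins(binning, ctl$size)
  max_ctl <- max(ctl$size)

  batches <- list()
  skipped <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(p))) {
      if (p$size[i] > max_ctl) {
        skipped[[length(skipped) + 1L]] <-
          data.table::data.table(id = p$id[i], reason = "too_large")
        next
      }
      b <- assign_size_bins(binning, p$size[i])
      pool <- which(cb == b)
      if (length(pool) < n_controls) {
        skipped[[length(skipped) + 1L]] <-
          data.table::data.table(id = p$id[i], reason = "bin_too_small")
        next
      }
      pick <- if (length(pool) == n_controls) pool else sample(pool, n_controls)
      batches[[length(batches) + 1L]] <- list(
        pathogenic_id = p$id[i], pathogenic_score = p$score[i],
        control_ids = ctl$id[pick], control_scores = ctl$score[pick],
        bin = b
      )
    }
  })
  list(batches = batches,
       skipped = if (length(skipped) > 0L) data.table::rbindlist(skipped)
                 else data.table::data.table(id = character(), reason = character()))
}

#' Rank of the pathogenic variant within a batch
#'
#' All scores are sorted in decreasing order; the rank is the 1-based
#' position of the pathogenic variant. Ties with control scores are broken
#' uniformly at random (default) or pessimistically (`"pathogenic_last"`,
#' placing the pathogenic variant after all tied controls).
#'
#' @param batch a batch from [build_batches()], or a list with
#'   `pathogenic_score` and `control_scores`.
#' @param tie_rule `"random"` or `"pathogenic_last"`.
#' @return integer rank in `1..batch_size`.
#' @export
rank_in_batch <- function(batch, tie_rule = c("random", "pathogenic_last")) {
  tie_rule <- match.arg(tie_rule)
  s <- batch$pathogenic_score
  ctl <- batch$control_scores
  greater <- sum(ctl > s)
  ties <- sum(ctl == s)
  if (ties == 0L) return(greater + 1L)
  if (tie_rule == "pathogenic_last") return(greater + ties + 1L)
  greater + sample.int(ties + 1L, 1L)
}

#' Summarise ranks over replicates into rank-bin percentages
#'
#' For each replicate (one vector of ranks over all batches) computes the
#' percentage of batches falling in each rank bin, then reports the mean and
#' standard deviation across replicates. Percentages within one replicate sum
#' to 100 when the bins exhaust `1..batch_size`.
#'
#' @param ranks_by_replicate list of integer vectors (one per replicate /
#'   seed), or a single vector for one replicate.
#' @param rank_bins list of `c(lo, hi)` inclusive rank ranges; default the
#'   twenty 5-wide bins covering 1..100.
#' @return data.table with columns rank_lo, rank_hi, mean_pct, sd_pct.
#' @export
ranking_summary <- function(ranks_by_replicate,
                            rank_bins = lapply(seq(1, 96, by = 5), function(l) c(l, l + 4))) {
  if (!is.list(ranks_by_replicate)) ranks_by_replicate <- list(ranks_by_replicate)
  stopifnot(length(ranks_by_replicate) >= 1L)
  pct <- vapply(ranks_by_replicate, function(r) {
    vapply(rank_bins, function(b) 100 * mean(r >= b[1] & r <= b[2]), numeric(1))
  }, numeric(length(rank_bins)))
  pct <- matrix(pct, nrow = length(rank_bins))
  data.table::data.table(
    rank_lo = vapply(rank_bins, `[`, numeric(1), 1L),
    rank_hi = vapply(rank_bins, `[`, numeric(1), 2L),
    mean_pct = rowMeans(pct),
    sd_pct = apply(pct, 1, function(v) if (length(v) > 1L) stats::sd(v) else 0)
  )
}

#' Partial correlation matrix from the inverse covariance
#'
#' Entry (i, j) is the correlation of features i and j conditioned on all
#' remaining features, obtained by normalising the negated precision matrix;
#' the diagonal is exactly 1. A singular covariance is ridge-regularised
#' (`lambda * I`, reported via a message).
#'
#' @param x numeric matrix or feature data.frame (rows = samples).
#' @param ridge ridge added to the covariance when inversion fails
#'   (default 1e-6).
#' @return symmetric p x p matrix with unit diagonal.
#' @export
partial_correlation <- function(x, ridge = 1e-6) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  p <- ncol(m)
  if (nrow(m) < p + 2) stop("need at least p + 2 complete rows for p features")
  s <- stats::cov(m)
  prec <- tryCatch(solve(s), error = function(e) {
    message(sprintf("covariance singular; adding ridge %g to the diagonal", ridge))
    solve(s + diag(ridge, p))
  })
  d <- sqrt(diag(prec))
  pc <- -prec / tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- list(colnames(m), colnames(m))
  pc
}

#' Cluster features by partial correlation
#'
#' Average-linkage hierarchical clustering cut at `max_distance`. Two
#' distances are available: `"absolute"` uses `1 - |pcorr|` (range `[0, 1]`,
#' so at the conventional cut of exactly 1 every feature merges into one
#' cluster -- use a cut below 1 there); `"signed"` uses `1 - pcorr` (range
#' `[0, 2]`, the correlation-distance convention of common scientific
#' clustering stacks), under which a cut of 1 separates positively
#' correlated groups from independent and anti-correlated ones.
#'
#' @param pcorr matrix from [partial_correlation()].
#' @param max_distance flat-cluster cut height (default 1).
#' @param distance `"absolute"` (default) or `"signed"`.
#' @return named integer vector of cluster ids (a partition of the features).
#' @export
cluster_features <- function(pcorr, max_distance = 1,
                             distance = c("absolute", "signed")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(pcorr), nrow(pcorr) == ncol(pcorr))
  if (nrow(pcorr) == 1L) {
    return(stats::setNames(1L, rownames(pcorr)))
  }
  d <- if (distance == "absolute") 1 - abs(pcorr) else 1 - pcorr
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, h = max_distance)
}

#' Permutation importance of correlated feature clusters
#'
#' For each cluster and each of `n_seeds` replicates, the cluster's columns
#' of the (preprocessed) training matrix are jointly permuted with one shared
#' row permutation, the model's out-of-bag accuracy is recomputed on the
#' permuted matrix, and the loss `original - permuted` is recorded. The
#' baseline OOB accuracy is computed once.
#'
#' @param model a `tadcnv_model` (stores its training matrix and OOB
#'   bookkeeping).
#' @param clusters named integer vector from [cluster_features()]; names must
#'   be model features.
#' @param n_seeds number of permutation replicates (default 30).
#' @param seed integer master seed.
#' @return data.table with columns cluster, members, mean_loss, sd_loss,
#'   sorted by decreasing mean loss.
#' @export
cluster_permutation_importance <- function(model, clusters, n_seeds = 30,
                                           seed = 1L) {
  stopifnot(inherits(model, "tadcnv_model"))
  unknown <- setdiff(names(clusters), model$feature_names)
  if (length(unknown) > 0L) {
    stop(sprintf("cluster feature(s) not in model: %s", paste(unknown, collapse = ", ")))
  }
  x <- model$train_x
  base <- oob_accuracy(model)
  ids <- sort(unique(clusters))
  losses <- matrix(NA_real_, nrow = length(ids), ncol = n_seeds)
  with_seed(seed, {
    for (s in seq_len(n_seeds)) {
      for (k in seq_along(ids)) {
        members <- names(clusters)[clusters == ids[k]]
        perm <- sample.int(nrow(x))
        xp <- x
        xp[, members] <- x[perm, members, drop = FALSE]
        losses[k, s] <- base - oob_accuracy(model, xp)
      }
    }
  })
  out <- data.table::data.table(
    cluster = ids,
    members = vapply(ids, function(i) paste(names(clusters)[clusters == i],
                                            collapse = ","), character(1)),
    mean_loss = rowMeans(losses),
    sd_loss = apply(losses, 1, function(v) if (length(v) > 1L) stats::sd(v) else 0)
  )
  out[order(-mean_loss)]
}

#' Full ranking analysis over seed replicates
#'
#' Convenience wrapper: builds batches and computes ranks for each of
#' `n_replicates` sampling seeds, then summarises rank-bin percentages.
#'
#' @inheritParams build_batches
#' @param n_replicates number of sampling replicates (default 30).
#' @param rank_bins see [ranking_summary()].
#' @param tie_rule see [rank_in_batch()].
#' @return list with `summary` (see [ranking_summary()]), `ranks`
#'   (list per replicate) and `skipped` from the first replicate.
#' @export
ranking_analysis <- function(pathogenic, controls, batch_size = 100,
                             n_bins = 60, n_replicates = 30, seed = 1L,
                             rank_bins = lapply(seq(1, 96, by = 5), function(l) c(l, l + 4)),
                             tie_rule = "random") {
  ranks <- vector("list", n_replicates)
  skipped <- NULL
  for (r in seq_len(n_replicates)) {
    bb <- build_batches(pathogenic, controls, batch_size, n_bins,
                        seed = seed + r - 1L)
    if (is.null(skipped)) skipped <- bb$skipped
    ranks[[r]] <- with_seed((seed %% 1000003L) + 7919L * r, {
      vapply(bb$batches, rank_in_batch, integer(1), tie_rule = tie_rule)
    })
  }
  list(summary = ranking_summary(ranks, rank_bins), ranks = ranks,
       skipped = skipped)
}
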