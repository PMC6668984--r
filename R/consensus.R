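#' Resampling consensus clustering of samples
#'
#' Monti-style consensus clustering: for each of `n_resamples` draws of
#' `ceiling(subsample_frac * n)` samples without replacement, the base
#' clusterer partitions the drawn samples at each k in `k_range`; the
#' consensus index of a sample pair at k is the number of times they
#' co-clustered divided by the number of times they were co-sampled
#' (0, with a flagged count, for pairs never co-sampled). k is selected by
#' the CDF/relative-delta-AUC rule ([select_k()]) and final labels come
#' from average-linkage hierarchical clustering of 1 - consensus at the
#' selected k.
#'
#' @param expr_sub An `ExpressionMatrix` (typically one module's genes).
#' @param k_range Consecutive integers starting at 2.
#' @param n_resamples Number of resampling draws (>= 2; default 1000).
#' @param subsample_frac Fraction of samples drawn each time, in (0, 1\];
#'   default 0.8.
#' @param seed Integer seed; results are reproducible from it.
#' @param base Base clusterer: `"hclust"` (average linkage on Euclidean
#'   sample distances; default) or `"kmeans"`.
#' @param delta_threshold Passed to [select_k()].
#' @return Object of class `consensus_result`: `consensus` (list k ->
#'   samples x samples matrix), `auc` (named numeric per k), `delta_auc`,
#'   `k_selected`, `labels` (named integer vector), `never_cosampled`
#'   (count of pairs with no co-sampling, over all k).
#' @export
consensus_cluster <- function(expr_sub, k_range = 2:6, n_resamples = 1000L,
                              subsample_frac = 0.8, seed = 1L,
                              base = c("hclust", "kmeans"),
                              delta_threshold = 0.1) {
  base <- match.arg(base)
  k_range <- as.integer(k_range)
  if (!length(k_range) || k_range[1L] != 2L ||
      any(diff(k_range) != 1L)) {
    stop("`k_range` must be consecutive integers starting at 2")
  }
  if (n_resamples < 2L) stop("`n_resamples` must be >= 2")
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop("`subsample_frac` must lie in (0, 1]")
  }
  vals <- expr_sub$values
  n <- ncol(vals)
  if (n < max(k_range) + 1L) {
    stop("need at least max(k_range) + 1 samples")
  }
  samples <- colnames(vals)
  n_draw <- ceiling(subsample_frac * n)

  co_sample <- matrix(0, n, n, dimnames = list(samples, samples))
  co_cluster <- lapply(stats::setNames(nm = as.character(k_range)),
                       function(k) co_sample)
  set.seed(seed)
  for (b in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, n_draw))
    sub <- vals[, idx, drop = FALSE]
    if (all(apply(sub, 2L, function(col) identical(col, sub[, 1L])))) {
      stop("degenerate subsample: all drawn sample columns identical")
    }
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    d <- stats::dist(t(sub))
    hc <- if (base == "hclust") stats::hclust(d, method = "average")
    for (k in k_range) {
      labels <- if (base == "hclust") {
        stats::cutree(hc, k = k)
      } else {
        stats::kmeans(t(sub), centers = k, nstart = 5L)$cluster
      }
      same <- outer(labels, labels, `==`) * 1
      kk <- as.character(k)
      co_cluster[[kk]][idx, idx] <- co_cluster[[kk]][idx, idx] + same
    }
  }

  never <- sum(co_sample[upper.tri(co_sample)] == 0)
  if (never > 0L) {
    message(never, " sample pair(s) never co-sampled; consensus set to 0")
  }
  consensus <- lapply(co_cluster, function(cc) {
    cm <- ifelse(co_sample > 0, cc / pmax(co_sample, 1), 0)
    diag(cm) <- 1
    cm[(cm < 0) | (cm > 1)] <- pmin(pmax(cm[(cm < 0) | (cm > 1)], 0), 1)
    stopifnot(isTRUE(all.equal(cm, t(cm))))
    cm
  })

  auc <- vapply(consensus, function(cm) consensus_cdf_and_auc(cm)$auc,
                numeric(1L))
  names(auc) <- names(consensus)
  sel <- select_k(stats::setNames(auc, k_range), threshold = delta_threshold)

  final <- stats::hclust(stats::as.dist(1 - consensus[[as.character(sel$k_selected)]]),
                         method = "average")
  labels <- stats::cutree(final, k = sel$k_selected)
  if (length(unique(labels)) < sel$k_selected) {
    warning("fewer than k_selected distinct clusters in final labels")
  }
  structure(list(consensus = consensus,
                 auc = stats::setNames(unname(auc), k_range),
                 delta_auc = sel$delta_auc,
                 k_selected = sel$k_selected,
                 labels = labels,
                 never_cosampled = never),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus clustering over k = %s; selected k = %d\n",
              paste(range(as.integer(names(x$consensus))), collapse = ".."),
              x$k_selected))
  invisible(x)
}

#' Empirical CDF and area under it for a consensus matrix
#'
#' The CDF is the right-continuous empirical distribution of the
#' n(n-1)/2 upper-triangle consensus indices; the AUC is its exact
#' integral over \[0, 1\] (the step-function integral over the sorted
#' values augmented with endpoints 0 and 1). A matrix of all ones gives
#' AUC 0 (perfect consensus), all zeros gives AUC 1.
#'
#' @param cm Square symmetric consensus matrix with unit diagonal,
#'   entries in \[0, 1\], n >= 2.
#' @return List: `cdf` (data frame `value`, `cumulative`), `auc`.
#' @export
consensus_cdf_and_auc <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) < 2L) {
    stop("`cm` must be a square matrix with n >= 2")
  }
  v <- cm[upper.tri(cm)]
  if (any(v < 0 | v > 1)) stop("consensus entries must lie in [0, 1]")
  xs <- sort(unique(v))
  cdf <- data.frame(value = xs,
                    cumulative = vapply(xs, function(x) mean(v <= x),
                                        numeric(1L)))
  grid <- unique(c(0, xs, 1))
  cdf_at <- function(x) if (x < min(xs)) 0 else max(cdf$cumulative[cdf$value <= x])
  auc <- 0
  for (j in seq_along(grid)[-1L]) {
    auc <- auc + (grid[j] - grid[j - 1L]) * cdf_at(grid[j - 1L])
  }
  list(cdf = cdf, auc = auc)
}

#' Select the number of clusters by the relative delta-AUC rule
#'
#' Delta(2) = A(2) and Delta(k) = (A(k) - A(k-1)) / A(k-1) for k > 2.
#' The selected k is the smallest k whose next step adds little area:
#' Delta(k+1) < `threshold`. If every step stays large the largest k is
#' returned with a warning.
#'
#' @param aucs Named numeric vector of CDF areas for consecutive k
#'   starting at 2 (names are the k values).
#' @param threshold Relative-increase cut-off (default 0.1).
#' @return List: `k_selected`, `delta_auc` (named numeric per k).
#' @export
select_k <- function(aucs, threshold = 0.1) {
  ks <- as.integer(names(aucs))
  if (anyNA(ks) || !length(ks) || ks[1L] != 2L || any(diff(ks) != 1L)) {
    stop("`aucs` must be named by consecutive k starting at 2")
  }
  delta <- numeric(length(ks))
  delta[1L] <- aucs[[1L]]
  if (length(ks) > 1L) {
    for (i in seq_along(ks)[-1L]) {
      delta[i] <- (aucs[[i]] - aucs[[i - 1L]]) / aucs[[i - 1L]]
    }
  }
  names(delta) <- ks
  k_selected <- NA_integer_
  for (i in seq_along(ks)) {
    if (i < length(ks) && delta[i + 1L] < threshold) {
      k_selected <- ks[i]
      break
    }
  }
  if (is.na(k_selected)) {
    warning("delta-AUC never fell below threshold; returning largest k")
    k_selected <- ks[length(ks)]
  }
  list(k_selected = k_selected, delta_auc = delta)
}

#' Pearson chi-squared test of association between two sample labellings
#'
#' Builds the contingency table of the two labellings over the shared
#' samples and applies the Pearson chi-squared test without continuity
#' correction; empty rows/columns are dropped with a warning, and a
#' warning is emitted when any expected count is below 5.
#'
#' @param labels_a,labels_b Named vectors (same sample names) with at
#'   least 2 distinct classes each after dropping empties.
#' @return List: `statistic`, `df`, `p`, `table`.
#' @export
chi_squared_association <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b))) {
    stop("both labellings must be named by sample")
  }
  common <- intersect(names(labels_a), names(labels_b))
  if (!length(common)) stop("no shared samples")
  tab <- table(a = as.character(labels_a[common]),
               b = as.character(labels_b[common]))
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("empty row(s)/column(s) dropped from contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need >= 2 classes in both labellings")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected count(s) below 5; chi-squared approximation is rough")
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}
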