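#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from the t transform t = r sqrt((n-2)/(1-r^2)) with
#' n - 2 degrees of freedom. A numerically perfect correlation (|r| = 1)
#' gets the smallest representable positive p rather than 0. A constant
#' vector is a degenerate case: `r` and `p` are returned as `NA` with a
#' warning, so callers can exclude the pair from an edge family without
#' aborting a whole run.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with elements `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined, returning NA")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, p = pearson_p(r, n))
}

pearson_p <- function(r, n) {
  p <- ifelse(abs(r) >= 1, .Machine$double.xmin, {
    tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  })
  pmin(p, 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment over one family; a thin validated front-end to
#' [stats::p.adjust()]. `method = "BY"` gives the Benjamini-Yekutieli
#' variant for dependent tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p_values)) stop("`p_values` must be non-empty")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Correlation tests for every gene pair
#'
#' Computes Pearson r, its two-sided p and the BH q over the single family
#' of all tested pairs. Genes are ordered lexicographically first so the
#' output (and hence everything downstream) is invariant to input gene and
#' sample order. Constant genes are excluded from pairing with a message.
#'
#' @param expr An `ExpressionMatrix` with >= 3 samples.
#' @param fdr_method Passed to [bh_fdr()].
#' @return Data frame: `gene1`, `gene2` (gene1 < gene2), `r`, `p`, `q`,
#'   in lexicographic pair order.
#' @export
correlation_table <- function(expr, fdr_method = "BH") {
  vals <- expr$values
  if (ncol(vals) < 3L) stop("need at least 3 samples")
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant gene(s) excluded from correlation")
    vals <- vals[sds > 0, , drop = FALSE]
  }
  if (nrow(vals) < 2L) stop("fewer than 2 non-constant genes")
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  n <- ncol(vals)
  cm <- stats::cor(t(vals))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  r <- cm[idx]
  # clamp tiny numerical overshoot from BLAS
  r <- pmin(pmax(r, -1), 1)
  p <- pearson_p(r, n)
  data.frame(gene1 = rownames(vals)[idx[, 1L]],
             gene2 = rownames(vals)[idx[, 2L]],
             r = r, p = p, q = bh_fdr(p, method = fdr_method),
             stringsAsFactors = FALSE)
}

#' Build the thresholded co-expression network
#'
#' An edge joins two genes iff |r| > `r_min` and BH q < `fdr_max`, with q
#' computed over the family of all tested pairs (both conditions applied
#' jointly). Edge weight is the signed r. The node set is edge-induced:
#' genes without a surviving edge do not appear.
#'
#' @param expr An `ExpressionMatrix` with >= 3 samples.
#' @param r_min Minimum absolute correlation (strict), default 0.3.
#' @param fdr_max Maximum BH q (strict), default 0.05.
#' @param fdr_method `"BH"` or `"BY"`.
#' @return Weighted undirected igraph graph (possibly empty).
#' @export
build_coexpression_network <- function(expr, r_min = 0.3, fdr_max = 0.05,
                                       fdr_method = "BH") {
  if (r_min < 0) stop("`r_min` must be >= 0")
  tab <- correlation_table(expr, fdr_method = fdr_method)
  keep <- abs(tab$r) > r_min & tab$q < fdr_max
  make_network(data.frame(from = tab$gene1[keep], to = tab$gene2[keep],
                          weight = tab$r[keep]))
}

#' Restrict a co-expression network to PPI-supported edges
#'
#' Keeps the co-expression edges whose (unordered) gene pair also appears
#' in the PPI network; co-expression weights are retained and the node set
#' is edge-induced (isolated nodes dropped).
#'
#' @param coexpr Weighted co-expression igraph graph.
#' @param ppi PPI igraph graph.
#' @return Weighted undirected igraph graph.
#' @export
intersect_with_ppi <- function(coexpr, ppi) {
  ce <- network_edges(coexpr)
  pe <- network_edges(ppi)
  key <- function(df) paste(df$from, df$to, sep = "\t")
  keep <- key(ce) %in% key(pe)
  make_network(ce[keep, c("from", "to",
                          intersect("weight", names(ce))),
                  drop = FALSE])
}

#' Degree distribution of a network
#'
#' @param net Non-empty igraph graph.
#' @return Named integer vector: names are degrees, values are node
#'   counts; counts sum to the number of nodes.
#' @export
degree_distribution_table <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  tab <- table(igraph::degree(net))
  stats::setNames(as.integer(tab), names(tab))
}

#' Log-log power-law fit to a degree distribution
#'
#' Ordinary least squares of log10(count) on log10(degree), degree 0
#' excluded. With only two distinct degrees the fit is exact (R^2 = 1) by
#' construction — a documented caveat, not evidence of scale-freeness.
#'
#' @param dist Named vector as returned by [degree_distribution_table()].
#' @return Object of class `power_law_fit`: `slope`, `intercept`,
#'   `r_squared`, and `points` (data frame of log10 degree / log10 count).
#' @export
power_law_fit <- function(dist) {
  deg <- as.numeric(names(dist))
  cnt <- as.numeric(dist)
  keep <- deg > 0 & cnt > 0
  deg <- deg[keep]; cnt <- cnt[keep]
  if (length(unique(deg)) < 2L) {
    stop("need >= 2 distinct positive degrees to fit")
  }
  pts <- data.frame(log_degree = log10(deg), log_count = log10(cnt))
  fit <- stats::lm(log_count ~ log_degree, data = pts)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 points = pts),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: log10(count) = %.4f %+.4f log10(degree), R^2 = %.4f\n",
    x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Highest-degree genes of a network
#'
#' @param net igraph graph.
#' @param k Number of hubs requested (>= 1). When `k` exceeds the node
#'   count all nodes are returned, with a message.
#' @return Character vector of gene ids, degree descending, ties broken
#'   lexicographically.
#' @export
top_hub_genes <- function(net, k) {
  if (k < 1L) stop("`k` must be >= 1")
  deg <- igraph::degree(net)
  if (k > length(deg)) {
    message("k exceeds node count; returning all ", length(deg), " nodes")
    k <- length(deg)
  }
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(k)]
}
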