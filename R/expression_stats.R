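#' Fraction of gene pairs co-expressed above thresholds
#'
#' Over all C(m, 2) gene pairs of a (module) expression matrix, the
#' fraction whose |Pearson r| exceeds each threshold. Constant genes are
#' excluded with a message. Fractions are non-increasing in the threshold
#' by construction.
#'
#' @param expr_sub An `ExpressionMatrix` with >= 2 genes.
#' @param thresholds Numeric thresholds (default 0.5 and 0.7).
#' @return Named numeric vector of fractions, one per threshold.
#' @export
pairwise_coexpr_fraction <- function(expr_sub, thresholds = c(0.5, 0.7)) {
  vals <- expr_sub$values
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant gene(s) excluded")
    vals <- vals[sds > 0, , drop = FALSE]
  }
  if (nrow(vals) < 2L) stop("need >= 2 non-constant genes")
  cm <- stats::cor(t(vals))
  r <- abs(cm[upper.tri(cm)])
  stats::setNames(vapply(thresholds, function(t) mean(r > t), numeric(1L)),
                  thresholds)
}

#' Per-gene two-group differential expression (Welch t-test)
#'
#' Vectorised Welch (unequal-variance) two-sample t-test for every gene,
#' case vs control; `pooled = TRUE` switches to the classic pooled-variance
#' Student test. Degenerate genes (zero variance in both groups) get p = 1
#' when the group means are equal, or the smallest representable p when
#' they differ; both cases are counted in a message.
#'
#' @param expr An `ExpressionMatrix` with group labels, >= 2 samples per
#'   group.
#' @param pooled Use pooled-variance Student t instead of Welch.
#' @return Data frame: `gene`, `t`, `df`, `p`, `direction` (sign of
#'   case mean - control mean), `mean_case`, `mean_control`.
#' @export
per_gene_t_test <- function(expr, pooled = FALSE) {
  if (is.null(expr$groups)) stop("expression matrix has no group labels")
  vals <- expr$values
  case <- vals[, expr$groups == "case", drop = FALSE]
  ctrl <- vals[, expr$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1L, stats::var); v2 <- apply(ctrl, 1L, stats::var)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    message(sum(degenerate), " zero-variance gene(s) handled degenerately")
    equal <- degenerate & (m1 == m2)
    p[equal] <- 1; t_stat[equal] <- 0; df[equal] <- n1 + n2 - 2
    unequal <- degenerate & (m1 != m2)
    p[unequal] <- .Machine$double.xmin
    t_stat[unequal] <- sign(m1 - m2)[unequal] * Inf
    df[unequal] <- n1 + n2 - 2
  }
  data.frame(gene = rownames(vals), t = t_stat, df = df, p = p,
             direction = sign(m1 - m2), mean_case = m1, mean_control = m2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` from a universe
#' of `N` containing `K` successes. Exact via [stats::phyper()].
#'
#' @param k Observed overlap (successes drawn).
#' @param K Successes in the universe.
#' @param n Draws.
#' @param N Universe size.
#' @return The tail probability in \[0, 1\].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of one gene set in a query
#'
#' Tests whether `de_genes` (the query, e.g. all differentially expressed
#' genes) over-represents `module_genes` within `background`:
#' k = |query intersect set|, K = |set|, n = |query|, N = |background|.
#'
#' @param de_genes,module_genes Character vectors, both subsets of
#'   `background`.
#' @param background Character vector, the gene universe.
#' @return One-row data frame: `set_size`, `query_size`, `overlap`,
#'   `background_size`, `p`.
#' @export
module_de_enrichment <- function(de_genes, module_genes, background) {
  bad <- setdiff(c(de_genes, module_genes), background)
  if (length(bad)) {
    stop("gene(s) outside the background universe: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  de_genes <- unique(de_genes); module_genes <- unique(module_genes)
  background <- unique(background)
  k <- length(intersect(de_genes, module_genes))
  data.frame(set_size = length(module_genes),
             query_size = length(de_genes),
             overlap = k,
             background_size = length(background),
             p = hypergeometric_tail(k, length(module_genes),
                                     length(de_genes), length(background)))
}

#' Over-representation analysis against a gene-set collection
#'
#' One hypergeometric upper-tail test per set (sets intersected with the
#' background first; empty intersections are kept with p = 1), BH
#' adjustment across the tested family, sorted by p ascending with ties
#' broken by set name.
#'
#' @param query Non-empty character vector, subset of `background`.
#' @param collection A `GeneSetCollection`.
#' @param background Character vector, the gene universe.
#' @param q_max Significance cut-off on the BH q (default 0.05).
#' @return Data frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p`, `q`, `significant`.
#' @export
ora <- function(query, collection, background, q_max = 0.05) {
  query <- unique(query); background <- unique(background)
  if (!length(query)) stop("empty query gene set")
  bad <- setdiff(query, background)
  if (length(bad)) {
    stop("query gene(s) outside the background universe: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], background)
    k <- length(intersect(query, s))
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = n, background_size = N,
               p = hypergeometric_tail(k, length(s), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < q_max
  out[order(out$p, out$set), , drop = FALSE]
}

#' Expression summary of a module
#'
#' Combines the pairwise co-expression fractions, the per-gene Welch
#' tests and the module's majority expression direction.
#'
#' @param expr Full `ExpressionMatrix` with groups.
#' @param module A `module_cluster` (or any object with a `genes` field).
#' @param thresholds Co-expression thresholds (default 0.5 and 0.7).
#' @param de_p Per-gene significance cut-off on the unadjusted p
#'   (default 0.05).
#' @return List: `fraction_gt` (named fractions), `de_table` (per-gene
#'   data frame), `n_de`, `module_direction` (majority sign of the
#'   case - control difference over member genes).
#' @export
module_expression_summary <- function(expr, module,
                                      thresholds = c(0.5, 0.7),
                                      de_p = 0.05) {
  sub <- subset_genes(expr, module$genes)
  de <- per_gene_t_test(sub)
  list(fraction_gt = pairwise_coexpr_fraction(sub, thresholds),
       de_table = de,
       n_de = sum(de$p < de_p),
       module_direction = sign(sum(sign(de$direction))))
}
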