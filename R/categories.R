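category_levels <- c("disease_and_immune", "disease_only", "immune_only",
                     "other")

#' Assign every network gene to an exclusive annotation category
#'
#' The four exclusive labels partition the network's genes by membership
#' in the disease and immune annotation sets. The two overlapping views
#' the analysis also reports — all disease-associated genes and all
#' immune-associated genes — are unions of these labels, available via
#' [category_members()].
#'
#' @param net igraph graph.
#' @param ann A `GeneAnnotation`.
#' @return Named factor over the network's genes with levels
#'   `disease_and_immune`, `disease_only`, `immune_only`, `other`.
#' @export
classify_genes <- function(net, ann) {
  genes <- igraph::V(net)$name
  in_d <- genes %in% ann$disease_genes
  in_i <- genes %in% ann$immune_genes
  lab <- ifelse(in_d & in_i, "disease_and_immune",
         ifelse(in_d, "disease_only",
         ifelse(in_i, "immune_only", "other")))
  stats::setNames(factor(lab, levels = category_levels), genes)
}

#' Genes belonging to a category, including the derived overlapping groups
#'
#' @param assignment Factor from [classify_genes()].
#' @param category One of the four exclusive labels, or the derived
#'   `disease_all` (= disease_and_immune + disease_only) or `immune_all`
#'   (= disease_and_immune + immune_only).
#' @return Character vector of gene ids.
#' @export
category_members <- function(assignment, category) {
  members <- switch(category,
    disease_all = names(assignment)[assignment %in%
                                      c("disease_and_immune", "disease_only")],
    immune_all = names(assignment)[assignment %in%
                                     c("disease_and_immune", "immune_only")],
    {
      if (!category %in% category_levels) {
        stop("unknown category: ", category)
      }
      names(assignment)[assignment == category]
    })
  members
}

#' First-neighbour subnetwork around a seed gene set
#'
#' Node set: the seeds found in the network plus all their first
#' neighbours. By default the edge set is the full induced subgraph on
#' those nodes (so neighbour-neighbour edges are kept); with
#' `edges = "seed_incident"` only edges touching a seed survive.
#'
#' @param net igraph graph.
#' @param seeds Non-empty character vector of seed gene ids.
#' @param edges `"induced"` (default) or `"seed_incident"`.
#' @return igraph graph; weights preserved. Empty (with a warning) when no
#'   seed is present in the network.
#' @export
extract_neighbor_subnetwork <- function(net, seeds,
                                        edges = c("induced",
                                                  "seed_incident")) {
  edges <- match.arg(edges)
  if (!length(seeds)) stop("`seeds` must be non-empty")
  present <- intersect(seeds, igraph::V(net)$name)
  if (!length(present)) {
    warning("no seed gene present in the network; returning empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(net, present),
                             function(vs) vs$name)))
  nodes <- union(present, nb)
  sub <- igraph::induced_subgraph(net, nodes)
  if (edges == "seed_incident") {
    el <- igraph::as_edgelist(sub)
    keep <- el[, 1L] %in% present | el[, 2L] %in% present
    sub <- igraph::subgraph_from_edges(sub, which(keep),
                                       delete.vertices = FALSE)
  }
  sub
}

#' Degree (first-neighbour count) distributions per gene category
#'
#' @param net igraph graph.
#' @param assignment Factor from [classify_genes()] covering `net`'s nodes.
#' @return List with `degrees` (list: category -> numeric vector of node
#'   degrees) and `summary` (data frame: category, n, median, q1, q3).
#'   Empty categories yield empty distributions, with a message.
#' @export
neighbor_count_by_category <- function(net, assignment) {
  genes <- igraph::V(net)$name
  missing <- setdiff(genes, names(assignment))
  if (length(missing)) {
    stop("assignment does not cover gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  deg <- igraph::degree(net)
  degs <- lapply(stats::setNames(nm = levels(assignment)), function(cat) {
    unname(deg[genes[assignment[genes] == cat]])
  })
  empty <- names(degs)[lengths(degs) == 0L]
  if (length(empty)) {
    message("empty categor(ies): ", paste(empty, collapse = ", "))
  }
  summ <- do.call(rbind, lapply(names(degs), function(cat) {
    d <- degs[[cat]]
    data.frame(category = cat, n = length(d),
               median = if (length(d)) stats::median(d) else NA_real_,
               q1 = if (length(d)) unname(stats::quantile(d, 0.25)) else NA_real_,
               q3 = if (length(d)) unname(stats::quantile(d, 0.75)) else NA_real_)
  }))
  list(degrees = degs, summary = summ)
}

#' Incident-edge absolute weights of a category
#'
#' The |r| values of every network edge touching at least one gene of the
#' category; an edge joining two categories contributes to both.
#'
#' @inheritParams neighbor_count_by_category
#' @param category Exclusive label or derived `disease_all` / `immune_all`.
#' @return Numeric vector of absolute edge weights.
#' @export
category_edge_weights <- function(net, assignment, category) {
  members <- category_members(assignment, category)
  el <- igraph::as_edgelist(net)
  keep <- el[, 1L] %in% members | el[, 2L] %in% members
  if (!any(keep)) stop("category has no incident edges: ", category)
  abs(igraph::E(net)$weight[keep])
}

#' Empirical CDF of a category's incident-edge |r| values
#'
#' @inheritParams category_edge_weights
#' @return A right-continuous step function of class `ecdf`.
#' @export
edge_weight_cdf <- function(net, assignment, category) {
  stats::ecdf(category_edge_weights(net, assignment, category))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by exhaustive enumeration of rank assignments when the combined
#' sample size is at most `exact_max` and there are no ties; otherwise the
#' normal approximation with tie correction and no continuity correction.
#' Two-sided p doubles the smaller exact tail, capped at 1. When every
#' value across both samples is identical the test is degenerate and p = 1
#' is returned with a warning.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max Largest combined size for the exact branch (default 12).
#' @return List: `statistic` (rank sum of `a`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  v <- c(a, b)
  if (length(unique(v)) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = sum(rank(v)[seq_len(m)]), p = 1,
                method = "degenerate"))
  }
  rk <- rank(v)
  w <- sum(rk[seq_len(m)])
  ties <- anyDuplicated(v) > 0L
  if (!ties && N <= exact_max) {
    combs <- utils::combn(N, m)
    wdist <- colSums(matrix(seq_len(N)[combs], nrow = m))
    p_lo <- mean(wdist <= w)
    p_hi <- mean(wdist >= w)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = w, p = p, method = "exact"))
  }
  mu <- m * (N + 1) / 2
  tie_tab <- table(v)
  sig2 <- m * n * (N + 1) / 12 -
    m * n * sum(tie_tab^3 - tie_tab) / (12 * N * (N - 1))
  z <- (w - mu) / sqrt(sig2)
  list(statistic = w, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Pearson correlations between two gene sets
#'
#' @param expr An `ExpressionMatrix` containing every requested gene.
#' @param genes_a,genes_b Character vectors of gene ids.
#' @return Numeric matrix of Pearson r, rows `genes_a`, columns `genes_b`.
#' @export
cross_category_correlation_matrix <- function(expr, genes_a, genes_b) {
  missing <- setdiff(c(genes_a, genes_b), gene_ids(expr))
  if (length(missing)) {
    stop("gene(s) not in expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  stats::cor(t(expr$values[genes_a, , drop = FALSE]),
             t(expr$values[genes_b, , drop = FALSE]))
}

#' Pairwise Wilcoxon comparison of category co-expression levels
#'
#' Compares the incident-edge |r| distributions of every pair of
#' categories with [wilcoxon_rank_sum()].
#'
#' @inheritParams neighbor_count_by_category
#' @param categories Categories to compare (defaults to the non-empty
#'   exclusive labels).
#' @return Symmetric matrix of two-sided p-values (diagonal `NA`).
#' @export
category_wilcoxon_matrix <- function(net, assignment,
                                     categories = NULL) {
  if (is.null(categories)) {
    categories <- levels(assignment)[
      vapply(levels(assignment), function(cat) {
        members <- category_members(assignment, cat)
        el <- igraph::as_edgelist(net)
        any(el[, 1L] %in% members | el[, 2L] %in% members)
      }, logical(1L))]
  }
  k <- length(categories)
  pm <- matrix(NA_real_, k, k, dimnames = list(categories, categories))
  weights <- lapply(stats::setNames(nm = categories), function(cat) {
    category_edge_weights(net, assignment, cat)
  })
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        p <- wilcoxon_rank_sum(weights[[i]], weights[[j]])$p
        pm[i, j] <- pm[j, i] <- p
      }
    }
  }
  pm
}
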