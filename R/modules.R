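#' Mine dense gene modules from a weighted network
#'
#' Community detection (greedy modularity maximisation by default, label
#' propagation as alternative) on the network weighted by |r|, followed by
#' a minimum-size filter and, where a community's induced subgraph is
#' disconnected, a split into connected components. Surviving modules are
#' ranked by internal edge density (edges / possible edges) descending,
#' ties by smallest member gene id, and capped at `max_modules`.
#'
#' @param net igraph graph, optionally weighted by signed r.
#' @param min_size Minimum module size (default 5).
#' @param max_modules Maximum number of modules returned (default 10).
#' @param seed Integer seed (label propagation is stochastic; greedy
#'   modularity is deterministic but the seed is set regardless so the
#'   contract is uniform).
#' @param algorithm `"fast_greedy"` (default) or `"label_prop"`.
#' @return List of `module_cluster` objects (possibly empty, with a
#'   message): each has `id`, `genes` (sorted), `graph` (induced
#'   subgraph), `size`, `density`.
#' @export
mine_modules <- function(net, min_size = 5L, max_modules = 10L, seed = 1L,
                         algorithm = c("fast_greedy", "label_prop")) {
  algorithm <- match.arg(algorithm)
  if (igraph::vcount(net) == 0L) stop("empty network")
  w <- if ("weight" %in% igraph::edge_attr_names(net)) {
    abs(igraph::E(net)$weight)
  } else NULL
  set.seed(seed)
  comm <- switch(algorithm,
    fast_greedy = igraph::cluster_fast_greedy(net, weights = w),
    label_prop = igraph::cluster_label_prop(net, weights = w))
  groups <- igraph::communities(comm)
  # split any disconnected community into components, then size-filter
  parts <- list()
  for (g in groups) {
    sub <- igraph::induced_subgraph(net, g)
    comp <- igraph::components(sub)
    for (cid in seq_len(comp$no)) {
      parts[[length(parts) + 1L]] <-
        names(comp$membership)[comp$membership == cid]
    }
  }
  parts <- parts[lengths(parts) >= min_size]
  if (!length(parts)) {
    message("no community reaches min_size = ", min_size)
    return(list())
  }
  density <- vapply(parts, function(g) {
    sub <- igraph::induced_subgraph(net, g)
    igraph::ecount(sub) / choose(length(g), 2L)
  }, numeric(1L))
  first_gene <- vapply(parts, function(g) min(g), character(1L))
  ord <- order(-density, first_gene)
  parts <- parts[ord][seq_len(min(length(parts), max_modules))]
  density <- density[ord][seq_len(length(parts))]
  lapply(seq_along(parts), function(i) {
    genes <- sort(parts[[i]])
    structure(list(id = i, genes = genes,
                   graph = igraph::induced_subgraph(net, genes),
                   size = length(genes), density = density[i]),
              class = "module_cluster")
  })
}

#' @export
print.module_cluster <- function(x, ...) {
  cat(sprintf("module %d: %d genes, %d edges, density %.3f\n",
              x$id, x$size, igraph::ecount(x$graph), x$density))
  invisible(x)
}

#' Category composition of a module
#'
#' @param module A `module_cluster`.
#' @param assignment Factor from [classify_genes()] covering the module's
#'   genes.
#' @return Named integer vector of counts per exclusive category, summing
#'   to the module size.
#' @export
module_category_profile <- function(module, assignment) {
  missing <- setdiff(module$genes, names(assignment))
  if (length(missing)) {
    stop("assignment does not cover gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  tab <- table(assignment[module$genes])
  stats::setNames(as.integer(tab), names(tab))
}

#' Score recovery of planted modules by mined modules
#'
#' Each planted module is matched to the mined module containing most of
#' its genes; recovery is the fraction of all planted genes that land in
#' their planted module's matched mined module.
#'
#' @param modules List of `module_cluster`s from [mine_modules()].
#' @param module_of Named integer vector mapping gene -> planted module id
#'   (`NA` for background), as in the simulator's ground truth.
#' @return Recovery fraction in \[0, 1\].
#' @export
planted_recovery <- function(modules, module_of) {
  planted <- split(names(module_of)[!is.na(module_of)],
                   module_of[!is.na(module_of)])
  if (!length(planted)) stop("no planted modules in ground truth")
  total <- sum(lengths(planted))
  recovered <- 0L
  for (pg in planted) {
    hits <- vapply(modules, function(m) length(intersect(m$genes, pg)),
                   integer(1L))
    if (length(hits) && max(hits) > 0L) recovered <- recovered + max(hits)
  }
  recovered / total
}
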