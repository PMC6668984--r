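#' Read a genes x samples expression table
#'
#' Expects tab-separated text: first column gene id, header row of sample
#' ids. Readers reject malformed input rather than repairing it: duplicate
#' identifiers and non-numeric or non-finite rows are hard errors naming
#' the offender.
#'
#' @param path Path to the expression TSV.
#' @param groups_path Optional path to a two-column TSV (sample id, group)
#'   with groups `case`/`control` and no header.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, groups_path = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("expression table needs >= 1 sample column")
  gid <- tab[[1L]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) vals <- matrix(vals, nrow = 1L,
                                      dimnames = list(NULL, names(tab)[-1L]))
  bad <- gid[apply(vals, 1L, function(v) any(!is.finite(v)))]
  if (length(bad)) {
    stop("non-numeric or non-finite value(s) in gene row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  rownames(vals) <- gid
  groups <- if (!is.null(groups_path)) read_sample_groups(groups_path)
  expression_matrix(vals, groups)
}

#' @rdname read_expression
#' @export
read_sample_groups <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("sample group file needs 2 columns")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write an expression matrix (and optionally its group labels) as TSV
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(em))`
#' reproduces `em` bit-exactly for finite inputs written at full precision.
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param groups_path Optional output path for the two-column group file.
#' @export
write_expression <- function(em, path, groups_path = NULL) {
  df <- data.frame(gene = gene_ids(em),
                   format(em$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    if (is.null(em$groups)) stop("no group labels to write")
    utils::write.table(
      data.frame(sample = names(em$groups), group = as.character(em$groups)),
      groups_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an undirected edge list (e.g. HPRD-style PPI pairs)
#'
#' Tab-separated, at least two columns (extra columns ignored), no header.
#' Self-loops are dropped and duplicate edges (unordered) collapsed; both
#' are reported via [message()] with counts.
#'
#' @param path Path to the edge list.
#' @return An undirected, simple [igraph::graph] whose vertices are the
#'   edge endpoints.
#' @export
read_edge_list <- function(path) {
  if (!length(readLines(path, n = 1L))) stop("empty edge list: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty edge list: ", path)
  if (ncol(tab) < 2L) stop("edge list needs >= 2 columns")
  a <- tab[[1L]]; b <- tab[[2L]]
  loops <- a == b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped from ", path)
    a <- a[!loops]; b <- b[!loops]
  }
  key <- paste(pmin(a, b), pmax(a, b), sep = "\t")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed from ", path)
    a <- a[!dup]; b <- b[!dup]
  }
  if (!length(a)) stop("edge list contains no valid edges: ", path)
  make_network(data.frame(from = a, to = b))
}

#' Build a network from an edge data frame
#'
#' @param edges Data frame with columns `from`, `to` and optionally a
#'   numeric `weight` in \[-1, 1\] (a signed Pearson r).
#' @param nodes Optional character vector of vertex names (a superset of
#'   the endpoints); by default the endpoints themselves.
#' @return Undirected simple igraph graph.
#' @export
make_network <- function(edges, nodes = NULL) {
  if (!is.null(edges$weight) && any(abs(edges$weight) > 1 + 1e-12)) {
    stop("edge weights must lie in [-1, 1]")
  }
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  if (!length(nodes)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")
  if (any(igraph::which_multiple(g))) stop("duplicate edges are not allowed")
  g
}

#' Edge table of a network
#'
#' @param net igraph graph (undirected).
#' @return Data frame `from`, `to` (with `from < to` lexicographically) and
#'   `weight` when present, ordered lexicographically by pair.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(from = pmin(el[, 1L], el[, 2L]),
                   to = pmax(el[, 1L], el[, 2L]),
                   stringsAsFactors = FALSE)
  if ("weight" %in% igraph::edge_attr_names(net)) {
    df$weight <- igraph::E(net)$weight
  }
  df[order(df$from, df$to), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Lines with fewer than three fields are a hard error naming the line.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  gene_set_collection(sets)
}

#' Write a gene-set collection as GMT
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, description, collection[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a network in SIF and weighted-TSV form
#'
#' SIF: one `node1 <relation> node2` line per edge. The weighted TSV has
#' columns `gene1`, `gene2`, `r` (empty `r` when unweighted).
#'
#' @param net igraph graph.
#' @param path Output path.
#' @param relation Relation token for the SIF middle column.
#' @export
write_sif <- function(net, path, relation = "co_expr") {
  df <- network_edges(net)
  writeLines(paste(df$from, relation, df$to, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_network_tsv <- function(net, path) {
  df <- network_edges(net)
  out <- data.frame(gene1 = df$from, gene2 = df$to,
                    r = if (is.null(df$weight)) "" else
                      format(df$weight, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_network_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "character"))
  edges <- data.frame(from = tab$gene1, to = tab$gene2)
  if (any(nzchar(tab$r))) edges$weight <- as.numeric(tab$r)
  make_network(edges)
}
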