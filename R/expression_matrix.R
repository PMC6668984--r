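#' Construct an expression matrix with optional two-group sample labels
#'
#' The central container of the pipeline: a genes x samples real matrix with
#' unique gene and sample identifiers, and optionally a case/control label
#' for every sample.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be finite.
#' @param groups Optional named character vector or factor mapping every
#'   sample id to `"case"` or `"control"`; both groups must be non-empty.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `groups` (a named factor or `NULL`).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' em <- expression_matrix(m, groups = setNames(
#'   rep(c("case", "control"), each = 2), colnames(m)))
#' dim(em)
#' @export
expression_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must have gene rownames and sample colnames")
  }
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g)) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s)) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- gid[apply(values, 1L, function(v) any(!is.finite(v)))]
    stop("non-finite expression value(s) in gene(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!is.null(groups)) {
    groups <- validate_groups(groups, sid)
  }
  structure(list(values = values, groups = groups),
            class = "ExpressionMatrix")
}

validate_groups <- function(groups, sample_ids) {
  if (is.null(names(groups))) stop("`groups` must be named by sample id")
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing)) {
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  }
  groups <- factor(as.character(groups[sample_ids]),
                   levels = c("case", "control"))
  names(groups) <- sample_ids
  if (anyNA(groups)) stop("group labels must be 'case' or 'control'")
  if (any(table(groups) == 0L)) {
    stop("both 'case' and 'control' groups must be non-empty")
  }
  groups
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat(sprintf("  groups: %d case / %d control\n",
                tab[["case"]], tab[["control"]]))
  }
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param em An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(em) rownames(em$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(em) colnames(em$values)

#' Restrict an expression matrix to a gene subset
#'
#' @param em An `ExpressionMatrix`.
#' @param genes Character vector of gene ids; all must be present.
#' @return An `ExpressionMatrix` over `genes`, group labels preserved.
#' @export
subset_genes <- function(em, genes) {
  missing <- setdiff(genes, gene_ids(em))
  if (length(missing)) {
    stop("gene(s) not in expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  expression_matrix(em$values[genes, , drop = FALSE], em$groups)
}

#' Named gene annotation sets (immune- and disease-associated)
#'
#' @param immune_genes,disease_genes Character vectors of gene ids; the two
#'   sets may overlap.
#' @return An object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(immune_genes, disease_genes) {
  structure(list(immune_genes = unique(as.character(immune_genes)),
                 disease_genes = unique(as.character(disease_genes))),
            class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf("GeneAnnotation: %d immune, %d disease (%d shared)\n",
              length(x$immune_genes), length(x$disease_genes),
              length(intersect(x$immune_genes, x$disease_genes))))
  invisible(x)
}

#' Named collection of gene sets (e.g. pathways)
#'
#' @param sets Named list of character vectors; names unique, sets non-empty.
#' @return An object of class `GeneSetCollection` (a validated named list).
#' @export
gene_set_collection <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a fully named list of gene id vectors")
  }
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup)) stop("duplicate set name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  structure(sets, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}
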