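#' Configuration of the synthetic study generator
#'
#' Defaults describe the study design the pipeline targets: a small
#' two-group microarray cohort (7 cases vs 7 controls), a handful of
#' planted co-expression modules riding on a scale-free PPI overlay, and
#' immune/disease annotation sets whose overlap is controlled.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per planted module (>= 3).
#' @param within_module_r Target expected pairwise Pearson correlation
#'   within a module, in (0, 1).
#' @param disease_effect Mean shift added to case samples of disease-module
#'   genes, in units of the within-group marginal SD (which is 1).
#' @param n_disease_modules How many planted modules carry the disease
#'   effect (the first ones).
#' @param ppi_attach Preferential-attachment edges added per node when
#'   growing the PPI overlay.
#' @param frac_module_edges_in_ppi Fraction of each planted module's gene
#'   pairs additionally wired into the PPI overlay, in \[0, 1\].
#' @param immune_frac,disease_frac Target sizes of the immune and disease
#'   annotation sets, as fractions of `n_genes`.
#' @param overlap_frac Fraction of disease-annotated genes that are also
#'   immune-annotated.
#' @param n_decoy_sets Random decoy gene sets added to the pathway
#'   collection alongside the planted-module sets.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_case = 7L, n_control = 7L,
                       n_modules = 5L, module_size = 10L,
                       within_module_r = 0.8, disease_effect = 2,
                       n_disease_modules = 1L, ppi_attach = 2L,
                       frac_module_edges_in_ppi = 0.8,
                       immune_frac = 0.15, disease_frac = 0.02,
                       overlap_frac = 0.7, n_decoy_sets = 20L,
                       seed = 1L) {
  if (missing(n_disease_modules)) {
    n_disease_modules <- min(1L, as.integer(n_modules))
  }
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              within_module_r = within_module_r,
              disease_effect = disease_effect,
              n_disease_modules = as.integer(n_disease_modules),
              ppi_attach = as.integer(ppi_attach),
              frac_module_edges_in_ppi = frac_module_edges_in_ppi,
              immune_frac = immune_frac, disease_frac = disease_frac,
              overlap_frac = overlap_frac,
              n_decoy_sets = as.integer(n_decoy_sets),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, n_case >= 1L, n_control >= 1L,
              n_modules >= 0L, ppi_attach >= 1L, n_decoy_sets >= 0L)
    if (n_modules > 0L && module_size < 3L) {
      stop("`module_size` must be >= 3")
    }
    if (n_modules * module_size > n_genes) {
      stop("infeasible: n_modules * module_size exceeds n_genes")
    }
    if (n_modules > 0L &&
        (within_module_r <= 0 || within_module_r >= 1)) {
      stop("`within_module_r` must lie in (0, 1)")
    }
    if (n_disease_modules < 0L || n_disease_modules > n_modules) {
      stop("`n_disease_modules` must lie in [0, n_modules]")
    }
    for (f in c(frac_module_edges_in_ppi, immune_frac, disease_frac,
                overlap_frac)) {
      if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a full synthetic study
#'
#' Generates the four inputs the pipeline consumes, plus the ground truth
#' needed to score recovery. Module genes follow a shared-latent-factor
#' model: for module m with factor f_m ~ N(0,1) per sample,
#' x_g = sqrt(rho) f_m + sqrt(1-rho) eps with rho = `within_module_r`, so
#' the expected pairwise Pearson correlation within the module is rho and
#' the marginal SD is 1. Disease modules add `disease_effect` to the case
#' samples of every member gene. Background genes are independent N(0,1).
#' The PPI overlay is a Barabasi-Albert preferential-attachment graph over
#' all genes (gene ids assigned to vertices at random) plus a fraction
#' `frac_module_edges_in_ppi` of each planted module's gene pairs.
#'
#' @param config A [sim_config()].
#' @return List with elements `expr` (ExpressionMatrix with groups),
#'   `ppi` (igraph), `annotation` (GeneAnnotation), `pathways`
#'   (GeneSetCollection: planted-module sets named `planted_module_<m>`
#'   plus decoys), and `truth` (list: `module_of` named integer vector with
#'   `NA` for background genes, `is_disease_module` logical per module,
#'   `immune_genes`, `disease_genes`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  n_s <- config$n_case + config$n_control
  genes <- sprintf("G%05d", seq_len(n_g))
  samples <- sprintf("S%02d", seq_len(n_s))
  groups <- stats::setNames(
    rep(c("case", "control"), c(config$n_case, config$n_control)), samples)

  module_of <- stats::setNames(rep(NA_integer_, n_g), genes)
  n_mod <- config$n_modules
  module_genes <- list()
  if (n_mod > 0L) {
    picked <- sample(genes, n_mod * config$module_size)
    module_genes <- split(picked, rep(seq_len(n_mod),
                                      each = config$module_size))
    for (m in seq_len(n_mod)) module_of[module_genes[[m]]] <- m
  }
  is_disease_module <- seq_len(n_mod) <= config$n_disease_modules

  vals <- matrix(stats::rnorm(n_g * n_s), n_g, n_s,
                 dimnames = list(genes, samples))
  rho <- config$within_module_r
  for (m in seq_len(n_mod)) {
    f <- stats::rnorm(n_s)
    mg <- module_genes[[m]]
    vals[mg, ] <- sqrt(rho) * matrix(f, length(mg), n_s, byrow = TRUE) +
      sqrt(1 - rho) * vals[mg, , drop = FALSE]
    if (is_disease_module[m]) {
      vals[mg, groups == "case"] <-
        vals[mg, groups == "case"] + config$disease_effect
    }
  }
  expr <- expression_matrix(vals, groups)

  ppi <- simulate_ppi(genes, config$ppi_attach, module_genes,
                      config$frac_module_edges_in_ppi)

  ann <- simulate_annotation(genes, module_genes, is_disease_module, config)

  pathways <- simulate_pathways(genes, module_genes, config)

  list(expr = expr, ppi = ppi, annotation = ann, pathways = pathways,
       truth = list(module_of = module_of,
                    is_disease_module = is_disease_module,
                    immune_genes = ann$immune_genes,
                    disease_genes = ann$disease_genes))
}

simulate_ppi <- function(genes, ppi_attach, module_genes, frac_module) {
  n_g <- length(genes)
  g <- igraph::sample_pa(n_g, power = 1, m = ppi_attach, directed = FALSE)
  igraph::V(g)$name <- sample(genes)
  extra <- NULL
  for (mg in module_genes) {
    pairs <- t(utils::combn(sort(mg), 2L))
    n_take <- round(frac_module * nrow(pairs))
    if (n_take > 0L) {
      extra <- rbind(extra, pairs[sample(nrow(pairs), n_take), ,
                                  drop = FALSE])
    }
  }
  if (!is.null(extra)) {
    g <- igraph::add_edges(g, t(extra))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

simulate_annotation <- function(genes, module_genes, is_disease_module,
                                config) {
  planted_disease <- unlist(module_genes[is_disease_module], use.names = FALSE)
  planted_other <- unlist(module_genes[!is_disease_module], use.names = FALSE)
  n_dis <- max(length(planted_disease),
               round(config$disease_frac * config$n_genes))
  pool <- setdiff(genes, planted_disease)
  disease <- c(planted_disease,
               sample(pool, n_dis - length(planted_disease)))
  # immune set: a controlled share of disease genes, the non-disease
  # planted modules (the "immune modules"), then random fill
  n_imm <- round(config$immune_frac * config$n_genes)
  from_disease <- sample(disease, round(config$overlap_frac * length(disease)))
  immune <- unique(c(from_disease, planted_other))
  fill_pool <- setdiff(genes, c(immune, disease))
  if (length(immune) < n_imm) {
    immune <- c(immune, sample(fill_pool,
                               min(n_imm - length(immune),
                                   length(fill_pool))))
  }
  gene_annotation(immune, disease)
}

simulate_pathways <- function(genes, module_genes, config) {
  sets <- list()
  for (m in seq_along(module_genes)) {
    sets[[sprintf("planted_module_%d", m)]] <- module_genes[[m]]
  }
  size <- max(config$module_size, 5L)
  for (i in seq_len(config$n_decoy_sets)) {
    sets[[sprintf("decoy_%02d", i)]] <- sample(genes, size)
  }
  if (!length(sets)) stop("pathway collection would be empty; ",
                          "set n_modules or n_decoy_sets > 0")
  gene_set_collection(sets)
}

#' Pure-noise expression matrix (null model)
#'
#' I.i.d. standard normal entries with no group structure; used for
#' false-discovery calibration of the network construction step.
#'
#' @param n_genes,n_samples Dimensions; `n_samples >= 3`.
#' @param seed Integer seed.
#' @return An `ExpressionMatrix` without group labels.
#' @export
null_expression <- function(n_genes, n_samples, seed) {
  if (n_samples < 3L) stop("`n_samples` must be >= 3")
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("G%05d", seq_len(n_genes)),
                                 sprintf("S%02d", seq_len(n_samples))))
  expression_matrix(vals)
}

#' Expression matrix with planted sample groups
#'
#' Each sample group receives its own gene-wise mean vector with entries
#' drawn from N(0, effect^2); residual noise is standard normal. Used to
#' exercise consensus clustering with a known number of sample classes.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Integer vector, one entry per planted group.
#' @param effect Between-group SD of the gene-wise group means, in
#'   within-group SD units.
#' @param seed Integer seed.
#' @return List: `expr` (ExpressionMatrix, no case/control labels) and
#'   `groups` (named integer vector of planted group ids per sample).
#' @export
planted_sample_groups <- function(n_genes, group_sizes, effect, seed) {
  stopifnot(length(group_sizes) >= 2L, all(group_sizes >= 1L))
  set.seed(seed)
  n_s <- sum(group_sizes)
  grp <- rep(seq_along(group_sizes), group_sizes)
  samples <- sprintf("S%02d", seq_len(n_s))
  mu <- matrix(stats::rnorm(n_genes * length(group_sizes), sd = effect),
               n_genes, length(group_sizes))
  vals <- mu[, grp, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_s), n_genes, n_s)
  dimnames(vals) <- list(sprintf("G%05d", seq_len(n_genes)), samples)
  list(expr = expression_matrix(vals),
       groups = stats::setNames(grp, samples))
}
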