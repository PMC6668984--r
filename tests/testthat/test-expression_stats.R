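test_that("pairwise co-expression fractions match the all-pairs oracle", {
  # rank-one module: every gene a scalar multiple of one vector
  base <- c(1, 3, 2, 5, 4, 6)
  vals <- outer(c(1, -2, 0.5, 3), base)
  dimnames(vals) <- list(paste0("G", 1:4), paste0("S", 1:6))
  frac <- pairwise_coexpr_fraction(expression_matrix(vals),
                                   thresholds = c(0.5, 0.7, 0.99))
  expect_equal(unname(frac), c(1, 1, 1))

  em <- toy_expression(5L, 10L, seed = 17L)
  frac <- pairwise_coexpr_fraction(em, thresholds = c(0.1, 0.3, 0.5))
  cm <- abs(cor(t(em$values)))
  oracle <- vapply(c(0.1, 0.3, 0.5),
                   function(t) mean(cm[upper.tri(cm)] > t), numeric(1L))
  expect_equal(unname(frac), oracle)
  expect_true(all(diff(frac) <= 0))

  noise <- toy_expression(2L, 12L, seed = 23L)
  expect_equal(unname(pairwise_coexpr_fraction(noise, 0.99)), 0)
})

test_that("per-gene Welch test matches t.test and handles degeneracy", {
  em <- toy_expression(6L, 10L, seed = 3L, groups = TRUE)
  res <- per_gene_t_test(em)
  for (g in gene_ids(em)) {
    ref <- stats::t.test(em$values[g, em$groups == "case"],
                         em$values[g, em$groups == "control"])
    i <- match(g, res$gene)
    expect_equal(res$t[i], unname(ref$statistic))
    expect_equal(res$p[i], ref$p.value)
  }
  # hand case: clear separation, positive direction
  vals <- rbind(G1 = c(10, 11, 12, 1, 2, 3))
  colnames(vals) <- paste0("S", 1:6)
  em2 <- expression_matrix(vals, stats::setNames(
    rep(c("case", "control"), each = 3), colnames(vals)))
  res2 <- per_gene_t_test(em2)
  expect_equal(res2$direction, 1)
  expect_lt(res2$p, 0.05)
  expect_equal(res2$t, 11.0227, tolerance = 1e-4)

  # degenerate: identical groups -> p = 1; flat-but-shifted -> minimal p
  vals3 <- rbind(Geq = rep(1, 6), Gdiff = rep(c(1, 2), each = 3))
  colnames(vals3) <- paste0("S", 1:6)
  em3 <- expression_matrix(vals3, em2$groups)
  res3 <- suppressMessages(per_gene_t_test(em3))
  expect_equal(res3$p[res3$gene == "Geq"], 1)
  expect_equal(res3$p[res3$gene == "Gdiff"], .Machine$double.xmin)
})

test_that("t-test direction flips and p is invariant under label swap", {
  em <- toy_expression(10L, 14L, seed = 19L, groups = TRUE)
  flipped <- expression_matrix(
    em$values,
    stats::setNames(ifelse(em$groups == "case", "control", "case"),
                    names(em$groups)))
  a <- per_gene_t_test(em); b <- per_gene_t_test(flipped)
  expect_equal(a$p, b$p)
  expect_equal(a$direction, -b$direction)
})

test_that("t-test type-I rate at 7v7 is near nominal", {
  # rate per replicate has Monte-Carlo SD ~ 0.005 at 2000 genes; averaging
  # 5 independent null matrices brings it well inside the [0.04, 0.06] band
  rates <- vapply(1:5, function(s) {
    em <- null_expression(2000L, 14L, seed = s)
    em <- expression_matrix(em$values, stats::setNames(
      rep(c("case", "control"), each = 7L), sample_ids(em)))
    mean(per_gene_t_test(em)$p < 0.05)
  }, numeric(1L))
  expect_gte(mean(rates), 0.04)
  expect_lte(mean(rates), 0.06)
})

test_that("hypergeometric tail equals exhaustive draw enumeration", {
  expect_equal(hypergeometric_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeometric_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeometric_tail(4, 12, 4, 12), 1)
  for (N in 5:12) {
    for (K in 1:N) {
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeometric_tail(k, K, n, N),
                       hyper_oracle(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometric_tail(5, 4, 5, 10), "inconsistent")
})

test_that("module DE enrichment parameterises the tail correctly", {
  bg <- paste0("G", 1:100)
  expect_equal(module_de_enrichment(bg[1:10], bg[50:60], bg)$p, 1)
  expect_equal(module_de_enrichment(bg, bg, bg)$p, 1)
  row <- module_de_enrichment(bg[1:20], bg[11:25], bg)
  expect_equal(row$overlap, 10L)
  expect_equal(row$p, hyper_oracle(10, 15, 20, 100))
  expect_error(module_de_enrichment(c(bg[1], "ZZ"), bg[1:5], bg), "ZZ")
})

test_that("planted disease module is enriched in DE genes", {
  hits <- 0L
  for (s in 1:10) {
    study <- simulate_study(sim_config(n_genes = 200L, n_modules = 2L,
                                       module_size = 10L,
                                       disease_effect = 2,
                                       n_disease_modules = 1L, seed = s))
    de <- per_gene_t_test(study$expr)
    dm <- names(study$truth$module_of)[which(study$truth$module_of == 1L)]
    p <- module_de_enrichment(de$gene[de$p < 0.05], dm,
                              gene_ids(study$expr))$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 9L)
})

test_that("ORA ranks a planted pathway first and decoys cannot shift raw p", {
  set.seed(31)
  bg <- paste0("G", 1:200)
  planted <- bg[1:12]
  decoys <- stats::setNames(lapply(1:50, function(i) sample(bg, 12L)),
                            sprintf("decoy%02d", 1:50))
  coll <- gene_set_collection(c(list(planted = planted), decoys))
  res <- ora(planted, coll, bg)
  expect_identical(res$set[1L], "planted")
  expect_lt(res$q[1L], 0.05)
  # raw p per set does not depend on how many decoys are tested
  res_small <- ora(planted, gene_set_collection(list(planted = planted)),
                   bg)
  expect_equal(res$p[res$set == "planted"], res_small$p)
  # a set equal to the whole background is never enriched
  expect_equal(ora(planted, gene_set_collection(list(all = bg)), bg)$p, 1)
  expect_error(ora(character(0), coll, bg), "empty")
})
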