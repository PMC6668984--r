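test_that("pearson matches hand values and degenerates safely", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1))$r, -1)
  # hand computation from the covariance/variance definition
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  # p agrees with cor.test on a generic vector pair
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pearson(x, y)$p,
               stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_warning(res <- pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(res$r))
})

test_that("bh_fdr equals the brute-force step-up", {
  expect_equal(bh_fdr(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1L))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "non-empty")
})

test_that("co-expression network applies |r| and FDR thresholds jointly", {
  set.seed(10)
  g1 <- rnorm(10)
  vals <- rbind(G1 = g1, G2 = g1, G3 = rnorm(10))
  colnames(vals) <- paste0("S", 1:10)
  net <- build_coexpression_network(expression_matrix(vals))
  ed <- network_edges(net)
  expect_identical(ed$from, "G1")
  expect_identical(ed$to, "G2")
  expect_equal(ed$weight, 1)

  # r_min = 1 keeps nothing on noisy input
  noisy <- null_expression(20L, 10L, seed = 2L)
  expect_equal(igraph::ecount(
    build_coexpression_network(noisy, r_min = 1.0)), 0L)
})

test_that("network construction is invariant to gene and sample order", {
  em <- toy_expression(12L, 10L, seed = 21L)
  net1 <- build_coexpression_network(em, r_min = 0.1, fdr_max = 0.9)
  perm <- expression_matrix(
    em$values[sample(nrow(em$values)), sample(ncol(em$values))])
  net2 <- build_coexpression_network(perm, r_min = 0.1, fdr_max = 0.9)
  expect_equal(network_edges(net1), network_edges(net2))
})

test_that("false-edge proportion on null data respects the FDR level", {
  # 20 replicates of 200 x 14 null data; spurious-edge proportion over all
  # tested pairs stays within 2 Monte-Carlo SDs of the nominal 0.05
  props <- vapply(1:20, function(s) {
    em <- null_expression(200L, 14L, seed = 1000L + s)
    igraph::ecount(build_coexpression_network(em)) / choose(200L, 2L)
  }, numeric(1L))
  mc_sd <- stats::sd(props) / sqrt(length(props))
  expect_lte(mean(props), 0.05 + 2 * mc_sd)
})

test_that("PPI intersection is a pure edge intersection keeping weights", {
  coexpr <- make_network(data.frame(from = c("A", "B", "C"),
                                    to = c("B", "C", "D"),
                                    weight = c(0.9, -0.4, 0.5)))
  ppi <- make_network(data.frame(from = c("B", "C", "D"),
                                 to = c("C", "D", "E")))
  both <- intersect_with_ppi(coexpr, ppi)
  ed <- network_edges(both)
  expect_identical(ed$from, c("B", "C"))
  expect_identical(ed$to, c("C", "D"))
  expect_equal(ed$weight, c(-0.4, 0.5))
  # nodes are edge-induced: A is gone
  expect_false("A" %in% igraph::V(both)$name)

  expect_equal(network_edges(intersect_with_ppi(coexpr, coexpr)),
               network_edges(coexpr))
  disjoint <- make_network(data.frame(from = "X", to = "Y"))
  expect_equal(igraph::ecount(intersect_with_ppi(coexpr, disjoint)), 0L)
  # idempotent
  expect_equal(network_edges(intersect_with_ppi(both, ppi)),
               network_edges(both))
})

test_that("degree distribution counts every node once", {
  star <- make_network(data.frame(from = "H", to = paste0("L", 1:5)))
  expect_identical(degree_distribution_table(star),
                   stats::setNames(c(5L, 1L), c("1", "5")))
  tri <- make_network(data.frame(from = c("A", "B", "C"),
                                 to = c("B", "C", "A")))
  expect_identical(degree_distribution_table(tri),
                   stats::setNames(3L, "2"))
  set.seed(3)
  g <- igraph::sample_gnp(10, 0.4)
  igraph::V(g)$name <- paste0("N", 1:10)
  dd <- degree_distribution_table(g)
  expect_equal(sum(dd), 10L)
  # brute-force per-node check
  expect_identical(dd, stats::setNames(as.integer(table(igraph::degree(g))),
                                       names(table(igraph::degree(g)))))
  expect_error(degree_distribution_table(igraph::make_empty_graph(0)),
               "empty")
})

test_that("power-law fit is exact on exact power-law counts", {
  fit <- suppressWarnings(
    power_law_fit(stats::setNames(c(16L, 4L, 1L), c("1", "2", "4"))))
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points: R^2 = 1 by construction (documented caveat)
  two <- suppressWarnings(
    power_law_fit(stats::setNames(c(10L, 2L), c("1", "3"))))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)
  expect_error(power_law_fit(stats::setNames(5L, "2")), "distinct")
})

test_that("preferential-attachment PPI looks scale-free in log-log fit", {
  r2 <- vapply(1:10, function(s) {
    study <- simulate_study(sim_config(n_genes = 2000L, n_modules = 0L,
                                       seed = s))
    power_law_fit(degree_distribution_table(study$ppi))$r_squared
  }, numeric(1L))
  expect_true(all(r2 > 0.8))
})

test_that("top hubs rank by degree with lexicographic ties", {
  star <- make_network(data.frame(from = "H", to = paste0("L", 1:5)))
  expect_identical(top_hub_genes(star, 1L), "H")
  tie <- make_network(data.frame(from = c("B", "B", "B", "A", "A", "A"),
                                 to = c("x", "y", "z", "x", "y", "z")))
  expect_identical(top_hub_genes(tie, 2L), c("A", "B"))
  set.seed(6)
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- sprintf("N%02d", 1:15)
  deg <- igraph::degree(g)
  oracle <- names(deg)[order(-deg, names(deg))]
  expect_identical(top_hub_genes(g, 15L), oracle)
  expect_message(all_nodes <- top_hub_genes(g, 99L), "exceeds")
  expect_identical(all_nodes, oracle)
})
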