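ann_fixture <- gene_annotation(immune_genes = c("A", "B", "E"),
                               disease_genes = c("A", "C"))

test_that("gene classification follows set membership exactly", {
  net <- toy_network()
  a <- classify_genes(net, ann_fixture)
  expect_identical(as.character(a[c("A", "B", "C", "D", "E")]),
                   c("disease_and_immune", "immune_only", "disease_only",
                     "other", "immune_only"))
  expect_setequal(category_members(a, "disease_all"), c("A", "C"))
  expect_setequal(category_members(a, "immune_all"), c("A", "B", "E"))
  # hand-labelled 10-gene fixture via direct set algebra
  genes <- paste0("g", 1:10)
  ann <- gene_annotation(genes[1:4], genes[3:6])
  ring <- make_network(data.frame(from = genes,
                                  to = genes[c(2:10, 1)]))
  a2 <- classify_genes(ring, ann)
  oracle <- ifelse(genes %in% genes[1:4] & genes %in% genes[3:6],
                   "disease_and_immune",
            ifelse(genes %in% genes[3:6], "disease_only",
            ifelse(genes %in% genes[1:4], "immune_only", "other")))
  expect_identical(as.character(a2[genes]), oracle)
})

test_that("first-neighbour subnetwork keeps induced edges", {
  path <- make_network(data.frame(from = c("A", "B", "C"),
                                  to = c("B", "C", "D")))
  sub <- extract_neighbor_subnetwork(path, "A")
  expect_setequal(igraph::V(sub)$name, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1L)

  # depth-1 brute force on a 12-node random graph, 2 seeds
  set.seed(12)
  g <- igraph::sample_gnp(12, 0.25)
  igraph::V(g)$name <- sprintf("N%02d", 1:12)
  seeds <- c("N01", "N07")
  sub <- extract_neighbor_subnetwork(g, seeds)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  oracle_nodes <- union(seeds,
                        colnames(adj)[colSums(adj[seeds, , drop = FALSE]) > 0])
  expect_setequal(igraph::V(sub)$name, oracle_nodes)
  expect_equal(network_edges(sub),
               network_edges(igraph::induced_subgraph(g, oracle_nodes)))

  # seed-incident mode drops neighbour-neighbour edges
  tri <- make_network(data.frame(from = c("S", "S", "X"),
                                 to = c("X", "Y", "Y")))
  star_only <- extract_neighbor_subnetwork(tri, "S",
                                           edges = "seed_incident")
  expect_equal(igraph::ecount(star_only), 2L)

  expect_warning(empty <- extract_neighbor_subnetwork(path, "ZZ"),
                 "no seed")
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("subnetwork extraction is monotone and an identity on all nodes", {
  set.seed(9)
  g <- igraph::sample_gnp(15, 0.2)
  igraph::V(g)$name <- sprintf("N%02d", 1:15)
  s1 <- c("N01", "N02")
  s2 <- c("N01", "N02", "N08")
  expect_true(all(igraph::V(extract_neighbor_subnetwork(g, s1))$name %in%
                  igraph::V(extract_neighbor_subnetwork(g, s2))$name))
  full <- extract_neighbor_subnetwork(g, igraph::V(g)$name)
  expect_equal(network_edges(full), network_edges(g))
})

test_that("per-category degree distributions match brute force", {
  star <- make_network(data.frame(from = "H", to = paste0("L", 1:4)))
  ann <- gene_annotation(immune_genes = character(0), disease_genes = "H")
  a <- classify_genes(star, ann)
  res <- suppressMessages(neighbor_count_by_category(star, a))
  expect_equal(res$degrees$disease_only, 4)
  expect_equal(res$degrees$other, rep(1, 4))
  net <- toy_network()
  a2 <- classify_genes(net, ann_fixture)
  res2 <- suppressMessages(neighbor_count_by_category(net, a2))
  deg <- igraph::degree(net)
  for (cat in levels(a2)) {
    expect_equal(sort(res2$degrees[[cat]]),
                 sort(unname(deg[names(a2)[a2 == cat]])))
  }
})

test_that("category |r| CDFs count incident edges, shared edges twice", {
  net <- toy_network()          # weights 0.9 (AB), -0.5 (BC), 0.4 (CD), 0.7 (CE)
  a <- classify_genes(net, ann_fixture)
  cdf_d <- edge_weight_cdf(net, a, "disease_all")   # edges at A or C
  expect_equal(cdf_d(0.4), 0.25)    # |r| values 0.9, 0.5, 0.4, 0.7
  expect_equal(cdf_d(0.39), 0)
  expect_equal(cdf_d(0.7), 0.75)
  expect_equal(cdf_d(1), 1)
  two <- stats::ecdf(c(0.3, 0.6))
  expect_equal(two(0.4), 0.5)
  one <- make_network(data.frame(from = "A", to = "B", weight = 0.5))
  aa <- classify_genes(one, gene_annotation("A", character(0)))
  cdf1 <- edge_weight_cdf(one, aa, "immune_only")
  expect_equal(cdf1(0.49), 0)
  expect_equal(cdf1(0.5), 1)
  expect_error(edge_weight_cdf(one, aa, "disease_only"), "disease_only")
  # every edge is incident to >= 1 exclusive category, so the summed
  # incident-edge counts cover the edge set at least once
  counts <- vapply(levels(a), function(cat) {
    tryCatch(length(category_edge_weights(net, a, cat)),
             error = function(e) 0L)
  }, integer(1L))
  expect_gte(sum(counts), igraph::ecount(net))
})

test_that("exact rank-sum branch equals exhaustive enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p, 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # exhaustive over all rank subsets for total sizes up to 10
  set.seed(123)
  for (N in 4:10) {
    for (m in 2:(N - 2)) {
      for (rep in 1:3) {
        vals <- sample(100, N)     # distinct -> tie-free
        a <- vals[seq_len(m)]; b <- vals[-seq_len(m)]
        got <- wilcoxon_rank_sum(a, b)
        expect_identical(got$method, "exact")
        expect_equal(got$p, wilcoxon_oracle(a, b))
        # independent cross-check against the exact reference test
        expect_equal(got$p,
                     stats::wilcox.test(a, b, exact = TRUE)$p.value)
      }
    }
  }
})

test_that("normal-approximation rank-sum branch is calibrated", {
  set.seed(77)
  rej <- mean(replicate(1000, {
    wilcoxon_rank_sum(rnorm(30), rnorm(30))$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  expect_warning(res <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(res$p, 1)
})

test_that("cross-category correlation matrix matches pairwise pearson", {
  em <- toy_expression(7L, 8L, seed = 31L)
  m <- cross_category_correlation_matrix(em, c("G1", "G2", "G3"),
                                         c("G4", "G5", "G6", "G7"))
  expect_identical(dim(m), c(3L, 4L))
  for (i in 1:3) for (j in 1:4) {
    expect_equal(m[i, j], cor(em$values[paste0("G", i), ],
                              em$values[paste0("G", j + 3L), ]))
  }
  one <- cross_category_correlation_matrix(em, "G1", "G1")
  expect_equal(unname(one[1, 1]), 1)
  expect_error(cross_category_correlation_matrix(em, "G1", "nope"), "nope")
})
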