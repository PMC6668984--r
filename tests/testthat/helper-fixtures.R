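# Small in-code fixtures shared across test files.

toy_expression <- function(n_genes = 3L, n_samples = 4L, seed = 42L,
                           groups = FALSE) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(paste0("G", seq_len(n_genes)),
                                 paste0("S", seq_len(n_samples))))
  g <- NULL
  if (groups) {
    half <- n_samples %/% 2L
    g <- stats::setNames(rep(c("case", "control"),
                             c(half, n_samples - half)),
                         colnames(vals))
  }
  expression_matrix(vals, g)
}

# path graph A-B-C-D plus an off-path edge C-E, optionally weighted
toy_network <- function(weighted = TRUE) {
  edges <- data.frame(from = c("A", "B", "C", "C"),
                      to = c("B", "C", "D", "E"))
  if (weighted) edges$weight <- c(0.9, -0.5, 0.4, 0.7)
  make_network(edges)
}

random_collection <- function(n_sets = 5L, seed = 1L) {
  set.seed(seed)
  genes <- paste0("G", 1:40)
  gene_set_collection(stats::setNames(
    lapply(seq_len(n_sets), function(i) sample(genes, sample(3:8, 1L))),
    paste0("set", seq_len(n_sets))))
}

# brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exact two-sided rank-sum p by direct enumeration over combn
wilcoxon_oracle <- function(a, b) {
  m <- length(a); N <- m + length(b)
  w <- sum(rank(c(a, b))[seq_len(m)])
  wdist <- colSums(utils::combn(N, m))
  min(1, 2 * min(mean(wdist <= w), mean(wdist >= w)))
}

# hypergeometric upper tail by summing the pmf written out with choose()
hyper_oracle <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

true_group_labels <- function(expr) {
  stats::setNames(as.character(expr$groups), names(expr$groups))
}
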