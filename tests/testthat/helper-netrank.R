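# Shared test utilities: random instances and independent oracles.

# Random weighted undirected graph with n nodes and edge probability p.
random_network <- function(n, p = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("g%03d", seq_len(n))
    ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(ut)) < p
    edges <- data.frame(from = ids[ut[keep, 1L]], to = ids[ut[keep, 2L]],
                        weight = stats::runif(sum(keep), 0.05, 1),
                        stringsAsFactors = FALSE)
    gene_network(edges, nodes = ids)
  })
}

random_prior <- function(net, seed = 1L) {
  withr::with_seed(seed, stats::setNames(stats::runif(net$n_nodes),
                                         net$nodes))
}

# Rank-sum (Mann-Whitney) AUC, independent of the pROC-based implementation.
auc_ranksum <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Element-wise brute-force |cor|^beta adjacency via an explicit double loop.
brute_force_adjacency <- function(x, beta) {
  n <- nrow(x)
  a <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) a[i, j] <- abs(stats::cor(x[i, ], x[j, ]))^beta
    }
  }
  a
}

# Write a small expression TSV and return its path.
write_expr_fixture <- function(mat, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  write_expression(mat, path)
  path
}
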