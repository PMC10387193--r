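test_that("STRING-style edge lists parse with scaling, keep-max and cutoff rules", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "links.txt")
  writeLines(c("protein1 protein2 combined_score",
               "G1 G2 1000",
               "G2 G3 400", "G3 G2 700",
               "G4 G4 900",
               "G4 G5 200"), p)
  net <- read_string_network(p, score_cutoff = 0)
  expect_equal(net$edges$weight[net$edges$from == "G1"], 1.0)
  # duplicate orientations collapse keeping the max score
  e23 <- net$edges[net$edges$from == "G2" & net$edges$to == "G3", ]
  expect_equal(e23$weight, 0.7)
  # self-loop dropped
  expect_false(any(net$edges$from == net$edges$to))

  net700 <- read_string_network(p, score_cutoff = 700)
  expect_false(any(net700$nodes == "G5"))
  expect_equal(net700$n_edges, 2L)
  expect_equal(unname(net700$degree["G3"]), 0.7)
  expect_equal(unname(net700$degree["G2"]), 1.0 + 0.7)

  # node list keeps nodes that only appear in dropped edges
  np <- file.path(dir, "nodes.txt")
  writeLines(paste0("G", 1:5), np)
  net_iso <- read_string_network(p, score_cutoff = 700, nodes_path = np)
  expect_true("G5" %in% net_iso$nodes)
  expect_equal(unname(net_iso$degree["G5"]), 0)

  bad <- file.path(dir, "bad.txt")
  writeLines("G1 G2 1500", bad)
  expect_error(read_string_network(bad), "out of range")
})

test_that("network container enforces weight bounds and the handshake identity", {
  expect_error(gene_network(data.frame(from = "a", to = "b", weight = 1.2)),
               "weights must lie")
  expect_error(gene_network(data.frame(from = "a", to = "b", weight = 0)),
               "weights must lie")
  for (seed in 1:5) {
    net <- random_network(30, p = 0.2, seed = seed)
    expect_equal(sum(net$degree), 2 * sum(net$edges$weight), tolerance = 1e-12)
    expect_equal(unname(net$degree),
                 unname(Matrix::rowSums(net$adjacency)))
    expect_true(Matrix::isSymmetric(net$adjacency))
  }
})

test_that("co-expression adjacency equals |cor|^beta, verified by brute force", {
  withr::with_seed(5, {
    x <- matrix(rnorm(5 * 12), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("S", 1:12)))
  })
  net <- coexpression_network(x, beta = 6, edge_floor = 0)
  a_oracle <- brute_force_adjacency(x, 6)
  for (row in seq_len(nrow(net$edges))) {
    e <- net$edges[row, ]
    expect_equal(e$weight, a_oracle[e$from, e$to], tolerance = 1e-12)
  }
  # every above-floor pair is present
  expect_equal(net$n_edges, sum(a_oracle[upper.tri(a_oracle)] > 0))

  # beta = 1, floor = 0: weights are |c| exactly
  net1 <- coexpression_network(x, beta = 1, edge_floor = 0)
  a1 <- brute_force_adjacency(x, 1)
  e <- net1$edges
  expect_equal(e$weight, a1[cbind(e$from, e$to)], tolerance = 1e-12)

  # duplicated expression vectors give weight 1 for any beta
  x2 <- rbind(x, gDup = x[1, ])
  netd <- coexpression_network(x2, beta = 9, edge_floor = 0)
  ed <- netd$edges
  expect_equal(ed$weight[ed$from == "g1" & ed$to == "gDup"], 1)
})

test_that("co-expression networks respect correlation invariances and beta monotonicity", {
  withr::with_seed(6, {
    x <- matrix(rnorm(10 * 15), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), paste0("S", 1:15)))
  })
  # invariance to per-gene affine transforms
  x_aff <- x * 3.1 + 42
  expect_equal(coexpression_network(x, beta = 4, edge_floor = 0)$edges,
               coexpression_network(x_aff, beta = 4, edge_floor = 0)$edges,
               tolerance = 1e-9)
  # raising beta never increases a weight
  e2 <- coexpression_network(x, beta = 2, edge_floor = 0)$edges
  e8 <- coexpression_network(x, beta = 8, edge_floor = 0)$edges
  shared <- merge(e2, e8, by = c("from", "to"))
  expect_true(all(shared$weight.y <= shared$weight.x + 1e-12))

  # constant gene stays isolated with a warning
  x_const <- rbind(x, gConst = rep(1, ncol(x)))
  expect_warning(net <- coexpression_network(x_const, beta = 2),
                 "constant gene")
  expect_equal(unname(net$degree["gConst"]), 0)
  expect_true("gConst" %in% net$nodes)
})

test_that("soft-threshold choice reproduces an independent scale-free fit", {
  sim <- simulate_netrank_data(n_genes = 120, n_samples = 60, n_cases = 20,
                               n_biomarkers = 5, n_modules = 6,
                               module_cor = 0.4, seed = 21)
  picked <- pick_soft_threshold(sim$expression, candidate_betas = c(2L, 4L, 6L),
                                n_bins = 8L)
  expect_true(picked$beta %in% c(2L, 4L, 6L))
  expect_equal(nrow(picked$fit_table), 3L)

  # recompute the fit index for one power from scratch
  b <- 4L
  cc <- stats::cor(t(sim$expression))
  a <- abs(cc)^b; diag(a) <- 0
  k <- rowSums(a)
  breaks <- seq(min(k), max(k), length.out = 9L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin))
  kmean <- tapply(k, bin, mean)
  ok <- freq > 0 & is.finite(kmean)
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
  expected <- -sign(stats::coef(fit)[[2]]) * summary(fit)$r.squared
  expect_equal(picked$fit_table$fit_rsq[picked$fit_table$beta == b],
               expected, tolerance = 1e-10)

  # a single candidate is returned without choice
  one <- pick_soft_threshold(sim$expression, candidate_betas = 5L)
  expect_equal(one$beta, 5L)

  # identical genes degenerate the connectivity distribution: fallback
  x_id <- matrix(rep(rnorm(20), each = 25), nrow = 25,
                 dimnames = list(sprintf("g%02d", 1:25), sprintf("S%02d", 1:20)))
  expect_warning(fb <- pick_soft_threshold(x_id, candidate_betas = c(2L, 4L)),
                 "falling back")
  expect_equal(fb$beta, 6L)
})

test_that("restricting a network induces the subgraph and pads isolated genes", {
  net <- gene_network(data.frame(from = c("a", "a", "b", "c"),
                                 to = c("b", "c", "c", "d"),
                                 weight = c(0.5, 0.4, 0.3, 0.9)),
                      nodes = c("a", "b", "c", "d", "e"))
  sub <- restrict_network(net, c("a", "b", "c"))
  expect_setequal(sub$nodes, c("a", "b", "c"))
  expect_equal(sub$n_edges, 3L)
  expect_equal(unname(sub$degree["c"]), 0.4 + 0.3)

  sup <- restrict_network(net, c(net$nodes, "zz"))
  expect_equal(sup$n_edges, net$n_edges)
  expect_equal(unname(sup$degree["zz"]), 0)

  disj <- restrict_network(net, c("x1", "x2"))
  expect_equal(disj$n_nodes, 2L)
  expect_equal(disj$n_edges, 0L)
})

test_that("networks round-trip through the edge-list plus node-list format", {
  net <- random_network(15, p = 0.3, seed = 9)
  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "e.tsv"), file.path(dir, "n.txt"))
  back <- read_network(file.path(dir, "e.tsv"), file.path(dir, "n.txt"))
  expect_setequal(back$nodes, net$nodes)
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-10)
})
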