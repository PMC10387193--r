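# A tiny deterministic fit-like object for the selection rules.
toy_fit <- function(scores, p) {
  ids <- names(scores)
  ranking <- data.frame(gene_id = ids, netrank_score = unname(scores),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$netrank_score, ranking$gene_id), ]
  ranking$rank <- seq_len(nrow(ranking))
  ranking$prior_p <- p[ranking$gene_id]
  list(ranking = ranking)
}

test_that("signature selection filters on p then truncates on score with stable ties", {
  scores <- stats::setNames(c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
                            paste0("g", 10:1))
  p <- stats::setNames(c(0.01, 0.2, 0.03, 0.2, 0.04, 0.2, 0.2, 0.2, 0.2, 0.2),
                       paste0("g", 10:1))
  fit <- toy_fit(scores, p)
  expect_warning(sig <- select_signature(fit, k = 100, p_cutoff = 0.05),
                 "only 3")
  expect_equal(nrow(sig), 3L)
  expect_equal(sig$gene_id, c("g10", "g8", "g6"))  # survivors, score order
  expect_true(all(sig$p_value < 0.05))

  # truncation keeps the k best survivors
  sig2 <- select_signature(fit, k = 2, p_cutoff = 0.05)
  expect_equal(sig2$gene_id, c("g10", "g8"))

  # equal scores break ties by gene id, ascending
  p_all <- stats::setNames(rep(0.01, 10), names(scores))
  fit_tie <- toy_fit(stats::setNames(rep(0.5, 10), names(scores)), p_all)
  sig_tie <- select_signature(fit_tie, k = 4)
  expect_equal(sig_tie$gene_id, sort(names(scores))[1:4])

  # no survivors is an error
  expect_error(select_signature(fit, k = 5, p_cutoff = 1e-6),
               "no significant genes")
})

test_that("signature selection is invariant to the order genes enter the fit", {
  withr::with_seed(51, {
    scores <- stats::setNames(runif(30), sprintf("g%02d", 1:30))
    p <- stats::setNames(runif(30, 0, 0.1), names(scores))
  })
  sig1 <- select_signature(toy_fit(scores, p), k = 10)
  shuffle <- withr::with_seed(52, sample(names(scores)))
  sig2 <- select_signature(toy_fit(scores[shuffle], p[shuffle]), k = 10)
  expect_equal(sig1$gene_id, sig2$gene_id)
  expect_equal(sig1$netrank_score, sig2$netrank_score)
})

test_that("first-component AUC separates planted clusters and is orientation-invariant", {
  withr::with_seed(61, {
    n <- 60L
    y <- stats::setNames(rep(c(1L, 0L), each = n / 2), sprintf("S%02d", 1:n))
    x <- matrix(rnorm(5 * n, sd = 0.3), nrow = 5,
                dimnames = list(paste0("g", 1:5), names(y)))
    x[, y == 1] <- x[, y == 1] + 3  # one planted direction, fully separated
  })
  pca <- evaluate_pca(x, y, paste0("g", 1:5))
  expect_equal(pca$component_auc, 1.0)
  # sign-flipping all expression leaves the corrected AUC unchanged
  pca_flip <- evaluate_pca(-x, y, paste0("g", 1:5))
  expect_equal(pca_flip$component_auc, pca$component_auc)
  # a single-gene signature degenerates to that gene's values but still scores
  pca1 <- evaluate_pca(x, y, "g1")
  expect_gte(pca1$component_auc, 0.99)
  # the implementation's AUC agrees with an independent rank-sum computation
  expect_equal(pca$component_auc,
               max(auc_ranksum(pca$scores[, 1], pca$labels),
                   1 - auc_ranksum(pca$scores[, 1], pca$labels)),
               tolerance = 1e-12)
})

test_that("randomly relabelled samples give a near-chance component AUC", {
  aucs <- vapply(1:10, function(i) {
    withr::with_seed(70 + i, {
      n <- 300L
      x <- matrix(rnorm(8 * n), nrow = 8,
                  dimnames = list(paste0("g", 1:8), sprintf("S%03d", 1:n)))
      y <- stats::setNames(sample(rep(c(0L, 1L), n / 2)), colnames(x))
    })
    evaluate_pca(x, y, paste0("g", 1:8))$component_auc
  }, numeric(1))
  # orientation correction folds the null upward of 0.5; stays near chance
  expect_gte(min(aucs), 0.5)
  expect_lt(mean(aucs), 0.6)
})

test_that("SVM evaluation is exact on a separable fixture and internally consistent", {
  withr::with_seed(81, {
    n <- 80L
    y <- stats::setNames(rep(c(1L, 0L), each = n / 2), sprintf("S%03d", 1:n))
    x <- matrix(rnorm(6 * n, sd = 0.2), nrow = 6,
                dimnames = list(paste0("g", 1:6), names(y)))
    x[, y == 1] <- x[, y == 1] + 4
  })
  dev <- list(expression = x[, seq(1, n, 2)], labels = y[seq(1, n, 2)])
  test <- list(expression = x[, seq(2, n, 2)], labels = y[seq(2, n, 2)])
  ev <- evaluate_svm(dev, test, paste0("g", 1:6))
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$f1, 1.0)

  # metric identities recomputed from the exported confusion counts
  cm <- ev$confusion
  expect_equal(ev$precision, cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]))
  expect_equal(ev$recall, cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]))
  expect_equal(ev$f1, 2 * ev$precision * ev$recall / (ev$precision + ev$recall))
  expect_equal(ev$accuracy,
               (cm[["tp"]] + cm[["tn"]]) / sum(cm))
  expect_equal(ev$auc, auc_ranksum(ev$decision_scores,
                                   test$labels[names(ev$decision_scores)]),
               tolerance = 1e-12)

  # identical runs give identical reports
  ev2 <- evaluate_svm(dev, test, paste0("g", 1:6))
  expect_identical(ev[setdiff(names(ev), "decision_scores")],
                   ev2[setdiff(names(ev2), "decision_scores")])
  expect_identical(ev$decision_scores, ev2$decision_scores)

  # a test set the classifier calls all-control zeroes recall and F1
  test_far <- test
  test_far$expression[] <- test_far$expression - 10  # deep in control territory
  ev_deg <- evaluate_svm(dev, test_far, paste0("g", 1:6))
  expect_equal(ev_deg$recall, 0)
  expect_equal(ev_deg$f1, 0)
})

test_that("ranking comparison reproduces an independent correlation", {
  withr::with_seed(91, {
    a <- stats::setNames(runif(50), sprintf("g%02d", 1:50))
    b <- a + rnorm(50, sd = 0.1)
  })
  expect_equal(compare_rankings(a, a)$correlation, 1.0)
  expect_equal(compare_rankings(a, -a)$correlation, -1.0)
  cmp <- compare_rankings(a, b)
  expect_equal(cmp$n_shared, 50L)
  # recompute from the exported pair table
  expect_equal(cmp$correlation,
               stats::cor(cmp$pairs$score_a, cmp$pairs$score_b),
               tolerance = 1e-15)
  expect_error(compare_rankings(a[1:2], b[1:2]), "fewer than 3")
})
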