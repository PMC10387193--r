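#' Select a biomarker signature from a NetRank fit
#'
#' Filter-then-truncate rule: keep genes whose association p-value is below
#' `p_cutoff`, then take the `k` with the highest NetRank scores (ties
#' broken by gene id, ascending). If fewer than `k` genes survive the filter
#' all survivors are returned with a warning; zero survivors is an error.
#'
#' @param fit A `netrank` fit whose prior carries p-values, or any object
#'   with a `ranking` data frame containing `gene_id` and `netrank_score`.
#' @param k Signature size requested (default 100).
#' @param p_cutoff Raw association p-value cutoff (default 0.05; no
#'   multiple-testing correction unless `adjust` is set).
#' @param prior Optional `correlation_prior` supplying p-values when the fit
#'   does not carry them.
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`.
#' @return A `netrank_signature`: data frame `gene_id`, `netrank_score`,
#'   `rank`, `p_value` in descending score order, with attributes
#'   `k_requested` and `p_cutoff`.
#' @export
select_signature <- function(fit, k = 100L, p_cutoff = 0.05, prior = NULL,
                             adjust = "none") {
  stopifnot(k >= 1L, p_cutoff > 0, p_cutoff <= 1)
  tab <- fit$ranking
  if (is.null(tab$prior_p)) {
    if (is.null(prior) || is.null(prior$p_value))
      stop("no p-values available: supply a correlation_prior via 'prior'")
    tab$prior_p <- prior$p_value[match(tab$gene_id, prior$gene_id)]
  }
  p <- stats::p.adjust(tab$prior_p, method = adjust)
  keep <- !is.na(p) & p < p_cutoff
  if (!any(keep)) stop("no significant genes at cutoff ", p_cutoff)
  surv <- tab[keep, , drop = FALSE]
  surv <- surv[order(-surv$netrank_score, surv$gene_id), , drop = FALSE]
  if (nrow(surv) < k)
    warning("only ", nrow(surv), " gene(s) pass p < ", p_cutoff,
            "; requested ", k)
  sig <- utils::head(surv, k)
  out <- data.frame(gene_id = sig$gene_id, netrank_score = sig$netrank_score,
                    rank = seq_len(nrow(sig)), p_value = sig$prior_p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "k_requested") <- as.integer(k)
  attr(out, "p_cutoff") <- p_cutoff
  class(out) <- c("netrank_signature", "data.frame")
  out
}

#' @export
#' @method print netrank_signature
print.netrank_signature <- function(x, ...) {
  cat("NetRank signature:", nrow(x), "gene(s) (requested ",
      attr(x, "k_requested"), ", p < ", attr(x, "p_cutoff"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE,
                   digits = 4L)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more genes\n")
  invisible(x)
}

#' Write a signature as a gene list plus a score table
#'
#' @param signature A `netrank_signature`.
#' @param genes_path Output path for the one-id-per-line gene list.
#' @param table_path Optional output path for the full TSV (scores,
#'   p-values).
#' @return `genes_path`, invisibly.
#' @export
write_signature <- function(signature, genes_path, table_path = NULL) {
  writeLines(signature$gene_id, genes_path)
  if (!is.null(table_path))
    utils::write.table(as.data.frame(signature), table_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(genes_path)
}

# Rank-sum ROC AUC of a score against 0/1 labels via pROC, oriented so that
# higher scores favour the case class.
roc_auc <- function(score, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Evaluate a signature by principal-component separation
#'
#' Restricts the expression matrix to the signature genes, fits a PCA on the
#' mean-centred samples-by-genes matrix, and scores the first principal
#' component against the labels by ROC AUC. The sign of a component is
#' arbitrary, so the AUC is orientation-corrected to `max(auc, 1 - auc)` and
#' the chosen orientation recorded.
#'
#' @param x Expression matrix (genes in rows) containing all signature
#'   genes, typically the held-out test split.
#' @param labels Named 0/1 vector covering the columns of `x`.
#' @param signature A `netrank_signature` (or character vector of gene ids).
#' @param n_components Number of component scores to return (default 2).
#' @return A `netrank_pca` list: `scores` (samples x components),
#'   `component_auc` (first component, orientation-corrected),
#'   `orientation` (+1 or -1), `sdev` and `labels`.
#' @export
evaluate_pca <- function(x, labels, signature, n_components = 2L) {
  genes <- if (is.data.frame(signature)) signature$gene_id else
    as.character(signature)
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0L)
    stop("signature gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  y <- labels[colnames(x)]
  pc <- stats::prcomp(t(x[genes, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  n_keep <- min(n_components, ncol(pc$x))
  auc1 <- roc_auc(pc$x[, 1L], y)
  orientation <- if (!is.na(auc1) && auc1 < 0.5) -1 else 1
  structure(list(scores = pc$x[, seq_len(n_keep), drop = FALSE],
                 component_auc = if (is.na(auc1)) NA_real_ else max(auc1, 1 - auc1),
                 orientation = orientation,
                 sdev = pc$sdev, labels = y),
            class = "netrank_pca")
}

#' @export
#' @method print netrank_pca
print.netrank_pca <- function(x, ...) {
  cat("PCA evaluation on", nrow(x$scores), "samples,",
      length(x$sdev), "signature gene(s)\n")
  cat(sprintf("  first-component AUC %.4f (orientation %+d)\n",
              x$component_auc, x$orientation))
  invisible(x)
}

#' Train and evaluate an SVM on a signature
#'
#' Trains a support vector machine on the development split restricted to
#' the signature genes and reports held-out metrics on the test split:
#' precision, recall and F1 for the case class, accuracy, ROC AUC from the
#' decision values, and the confusion counts they derive from.
#'
#' @param dev,test Lists with elements `expression` (genes x samples) and
#'   `labels` (named 0/1 vector); both splits must contain both classes for
#'   training (a single-class test split yields `auc = NA` with a note).
#' @param signature A `netrank_signature` or character vector of gene ids.
#' @param kernel SVM kernel, `"radial"` (default) or `"linear"`.
#' @param cost Regularisation constant C (default 1).
#' @param gamma RBF kernel width; `NULL` uses the 1/n_features default.
#' @param seed Seed guarding any stochastic sub-procedure (default 1).
#' @return A `netrank_eval` list: `precision`, `recall`, `f1`, `accuracy`,
#'   `auc`, `confusion` (named counts `tp`, `fp`, `fn`, `tn`), `n_test`,
#'   `note` and the `config` used.
#' @export
evaluate_svm <- function(dev, test, signature, kernel = c("radial", "linear"),
                         cost = 1, gamma = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  genes <- if (is.data.frame(signature)) signature$gene_id else
    as.character(signature)
  if (length(genes) == 0L) stop("empty signature")
  for (split in list(dev, test)) {
    missing <- setdiff(genes, rownames(split$expression))
    if (length(missing) > 0L)
      stop("signature gene(s) absent from split: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  y_dev <- factor(dev$labels[colnames(dev$expression)], levels = c(0, 1))
  if (nlevels(droplevels(y_dev)) < 2L)
    stop("development split must contain both classes")
  x_dev <- t(dev$expression[genes, , drop = FALSE])
  x_test <- t(test$expression[genes, , drop = FALSE])
  y_test <- as.integer(as.character(
    factor(test$labels[colnames(test$expression)], levels = c(0, 1))))
  args <- list(x = x_dev, y = y_dev, kernel = kernel, cost = cost,
               scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  model <- withr::with_seed(seed, do.call(e1071::svm, args))
  pred <- stats::predict(model, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients decision values toward the first label of the colname
  score_case <- dv[, 1L] * if (startsWith(colnames(dv)[1L], "1")) 1 else -1
  pred <- as.integer(as.character(pred))
  tp <- sum(pred == 1L & y_test == 1L)
  fp <- sum(pred == 1L & y_test == 0L)
  fn <- sum(pred == 0L & y_test == 1L)
  tn <- sum(pred == 0L & y_test == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  auc <- roc_auc(score_case, y_test)
  note <- if (is.na(auc)) "test split single-class: AUC undefined" else NULL
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / length(y_test), auc = auc,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 n_test = length(y_test), note = note,
                 decision_scores = stats::setNames(score_case,
                                                   colnames(test$expression)),
                 config = list(kernel = kernel, cost = cost, gamma = gamma,
                               seed = seed, n_features = length(genes))),
            class = "netrank_eval")
}

#' @export
#' @method print netrank_eval
print.netrank_eval <- function(x, ...) {
  cat("Held-out SVM evaluation (", x$config$kernel, " kernel, ",
      x$config$n_features, " gene(s), n = ", x$n_test, ")\n", sep = "")
  cat(sprintf("  %-10s %-10s %-10s %-10s %-10s\n",
              "Precision", "Recall", "F1_score", "Accuracy", "AUC"))
  cat(sprintf("  %-10.3f %-10.3f %-10.3f %-10.3f %-10s\n",
              x$precision, x$recall, x$f1, x$accuracy,
              if (is.na(x$auc)) "NA" else sprintf("%-10.3f", x$auc)))
  cat(sprintf("  confusion: tp %d fp %d fn %d tn %d\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["fn"],
              x$confusion["tn"]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param eval A `netrank_eval` from [evaluate_svm()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval <- function(eval, path) {
  jsonlite::write_json(list(precision = eval$precision, recall = eval$recall,
                            f1_score = eval$f1, accuracy = eval$accuracy,
                            auc = eval$auc,
                            confusion = as.list(eval$confusion),
                            n_test = eval$n_test, config = eval$config),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Correlate two gene rankings
#'
#' Pearson correlation of two score vectors over their shared genes, the
#' comparison used to ask whether rankings from different networks (e.g. a
#' curated interaction network versus a co-expression network) agree.
#'
#' @param a,b `netrank` fits or named numeric score vectors.
#' @return List with `correlation`, `n_shared` and `pairs` (data frame
#'   `gene_id`, `score_a`, `score_b` for plotting).
#' @export
compare_rankings <- function(a, b) {
  sa <- if (inherits(a, "netrank")) a$scores else a
  sb <- if (inherits(b, "netrank")) b$scores else b
  shared <- intersect(names(sa), names(sb))
  if (length(shared) < 3L)
    stop("fewer than 3 shared genes between the rankings")
  pairs <- data.frame(gene_id = shared, score_a = as.numeric(sa[shared]),
                      score_b = as.numeric(sb[shared]),
                      stringsAsFactors = FALSE)
  list(correlation = stats::cor(pairs$score_a, pairs$score_b),
       n_shared = length(shared), pairs = pairs)
}
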