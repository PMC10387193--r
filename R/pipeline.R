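#' Run the full biomarker-discovery pipeline
#'
#' Chains the stages end to end: clean, min-max normalise, stratified
#' development/test split, correlation prior on the development split, gene
#' network (supplied, or a co-expression network built from the development
#' split), damped score propagation, signature selection, and held-out
#' evaluation by first-principal-component AUC and an SVM.
#'
#' By default normalisation is computed on the full matrix before
#' splitting; `scale_after_split = TRUE` is the stricter alternative that
#' fits the per-gene min/max on the development split only and applies it
#' to both splits (test values may then fall outside \[0, 1\]).
#'
#' @param expression Expression matrix, genes in rows (raw; cleaning and
#'   normalisation are applied here).
#' @param labels Named 0/1 vector covering the samples.
#' @param network Optional [gene_network()]; if `NULL` a co-expression
#'   network is built from the development split with `beta` and
#'   `edge_floor`.
#' @param d,tol,max_iter Propagation parameters, see [netrank()].
#' @param dev_fraction,split_seed Split parameters, see [split_dev_test()].
#' @param beta,edge_floor Co-expression network parameters, see
#'   [coexpression_network()]; used only when `network` is `NULL`.
#' @param k,p_cutoff Signature parameters, see [select_signature()].
#' @param svm_kernel,svm_cost,svm_seed SVM parameters, see [evaluate_svm()].
#' @param signed_prior Keep the sign of the correlation prior (default
#'   `FALSE`).
#' @param scale_after_split Fit the min-max scaler on the development split
#'   only (default `FALSE`, matching normalise-then-split).
#' @param output_dir Optional directory; when given, every stage's output is
#'   written there in the documented TSV/JSON formats together with a
#'   `manifest.json` echoing every effective parameter.
#' @return A `netrank_run` list: `fit` (the [netrank()] object),
#'   `signature`, `prior`, `network`, `split`, `pca`, `svm`, `manifest`.
#' @export
netrank_pipeline <- function(expression, labels, network = NULL,
                             d = 0.5, tol = 1e-9, max_iter = 1000L,
                             dev_fraction = 0.7, split_seed = 1L,
                             beta = 6, edge_floor = 0.01,
                             k = 100L, p_cutoff = 0.05,
                             svm_kernel = "radial", svm_cost = 1,
                             svm_seed = 1L, signed_prior = FALSE,
                             scale_after_split = FALSE, output_dir = NULL) {
  x <- clean_expression(expression)
  cleaning <- cleaning_report(x)
  if (scale_after_split) {
    split <- split_dev_test(x, labels, dev_fraction, split_seed)
    lo <- apply(split$dev$expression, 1L, min)
    hi <- apply(split$dev$expression, 1L, max)
    rng <- ifelse(hi - lo == 0, 1, hi - lo)
    split$dev$expression <- (split$dev$expression - lo) / rng
    split$test$expression <- (split$test$expression - lo) / rng
  } else {
    x <- minmax_normalize(x)
    split <- split_dev_test(x, labels, dev_fraction, split_seed)
  }
  prior <- pearson_prior(split$dev$expression, split$dev$labels,
                         signed = signed_prior)
  net <- if (is.null(network))
    coexpression_network(split$dev$expression, beta = beta,
                         edge_floor = edge_floor)
  else network
  net <- restrict_network(net, rownames(x))
  fit <- netrank(net, prior, d = d, tol = tol, max_iter = max_iter)
  signature <- select_signature(fit, k = k, p_cutoff = p_cutoff)
  pca <- evaluate_pca(split$test$expression, split$test$labels, signature)
  svm <- evaluate_svm(split$dev, split$test, signature,
                      kernel = svm_kernel, cost = svm_cost, seed = svm_seed)
  manifest <- list(d = d, tol = tol, max_iter = max_iter,
                   dev_fraction = dev_fraction, split_seed = split_seed,
                   network_source = if (is.null(network)) "coexpression"
                   else "supplied",
                   beta = beta, edge_floor = edge_floor,
                   k = k, p_cutoff = p_cutoff, svm_kernel = svm_kernel,
                   svm_cost = svm_cost, svm_seed = svm_seed,
                   signed_prior = signed_prior,
                   scale_after_split = scale_after_split,
                   n_genes = nrow(x), n_samples = ncol(x),
                   n_dev = ncol(split$dev$expression),
                   n_test = ncol(split$test$expression),
                   n_removed = if (is.null(cleaning)) 0L else nrow(cleaning))
  run <- structure(list(fit = fit, signature = signature, prior = prior,
                        network = net, split = split, pca = pca, svm = svm,
                        cleaning = cleaning, manifest = manifest),
                   class = "netrank_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
#' @method print netrank_run
print.netrank_run <- function(x, ...) {
  m <- x$manifest
  cat("NetRank pipeline run\n")
  cat(sprintf("  %d genes x %d samples (%d dev / %d test), network: %s\n",
              m$n_genes, m$n_samples, m$n_dev, m$n_test, m$network_source))
  cat(sprintf("  d = %s; signature: %d gene(s) (k = %d, p < %s)\n",
              format(m$d), nrow(x$signature), m$k, format(m$p_cutoff)))
  cat(sprintf("  held-out PCA first-component AUC %.4f\n",
              x$pca$component_auc))
  print(x$svm)
  invisible(x)
}

#' Write every output of a pipeline run
#'
#' @param run A `netrank_run` from [netrank_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ranking(run$fit, file.path(dir, "ranking.tsv"),
                file.path(dir, "netrank_report.json"))
  write_prior(run$prior, file.path(dir, "prior.tsv"))
  write_signature(run$signature, file.path(dir, "signature_genes.txt"),
                  file.path(dir, "signature.tsv"))
  write_network(run$network, file.path(dir, "network_edges.tsv"),
                file.path(dir, "network_nodes.txt"))
  write_eval(run$svm, file.path(dir, "svm_eval.json"))
  pca_tab <- data.frame(sample_id = rownames(run$pca$scores),
                        run$pca$scores, label = run$pca$labels,
                        check.names = FALSE)
  num <- vapply(pca_tab, is.numeric, logical(1L)) & names(pca_tab) != "label"
  pca_tab[num] <- lapply(pca_tab[num], function(v) format(v, digits = 12L))
  utils::write.table(pca_tab, file.path(dir, "pca_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(run$manifest,
                         list(component_auc = run$pca$component_auc)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
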