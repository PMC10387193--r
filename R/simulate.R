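#' Simulate an expression study with planted biomarkers and a companion
#' network
#'
#' Generates a genes-by-samples expression matrix, binary case/control
#' labels, and a weighted gene network with known ground truth, emulating
#' the statistical setting the ranking pipeline targets: correlated gene
#' modules, a minority of truly phenotype-associated genes, and a network
#' whose edges concentrate within modules.
#'
#' The expression model is a latent-factor model. Genes are assigned to
#' `n_modules` contiguous, equal-sized modules; each sample draws one
#' standard-normal factor per module, and gene `g` in module `m` has
#'
#'   `x_gs = lambda * z_ms + effect_size * y_s * [g is a biomarker] + eps`
#'
#' with `eps ~ N(0, noise_sd^2)` and `lambda` set so that two non-biomarker
#' genes of one module correlate at `module_cor`
#' (`lambda = noise_sd * sqrt(module_cor / (1 - module_cor))`). The
#' `n_biomarkers` planted genes are the first genes of module 1, so they
#' form a correlated block whose mean is shifted by `effect_size` noise-SD
#' units in cases.
#'
#' The companion network draws within-module gene pairs as edges with
#' probability `module_density` and cross-module pairs with
#' `background_density`; each edge weight is the model-implied expected
#' correlation magnitude of that pair plus uniform jitter on ±0.05, clipped
#' to \[0.02, 1\].
#'
#' All randomness flows through one seeded generator; the global RNG state
#' is untouched and equal seeds give bit-identical output.
#'
#' @param n_genes,n_samples,n_cases Dimensions of the study (defaults 500
#'   genes, 400 samples, 120 cases).
#' @param n_biomarkers Number of planted phenotype-associated genes, all in
#'   module 1 (default 20; must not exceed the module size).
#' @param effect_size Case-minus-control mean shift of biomarker genes, in
#'   units of `noise_sd` (default 1.5; 0 plants no signal).
#' @param n_modules Number of co-expression modules (default 10).
#' @param module_cor Expected correlation between two non-biomarker genes of
#'   one module (default 0.2).
#' @param noise_sd Independent noise standard deviation (default 1).
#' @param module_density,background_density Edge probabilities within and
#'   across modules (defaults 0.3 and 0.01).
#' @param seed Integer seed (default 1).
#' @return List with `expression` (matrix), `labels` (named 0/1 vector),
#'   `network` (a [gene_network()]) and `truth` (list: `biomarkers`,
#'   `modules`, `params`).
#' @export
simulate_netrank_data <- function(n_genes = 500L, n_samples = 400L,
                                  n_cases = 120L, n_biomarkers = 20L,
                                  effect_size = 1.5, n_modules = 10L,
                                  module_cor = 0.2, noise_sd = 1,
                                  module_density = 0.3,
                                  background_density = 0.01, seed = 1L) {
  problems <- character()
  if (n_cases < 1L || n_cases >= n_samples)
    problems <- c(problems, "n_cases must be in [1, n_samples - 1]")
  if (n_modules < 1L || n_modules > n_genes)
    problems <- c(problems, "n_modules must be in [1, n_genes]")
  if (n_biomarkers > ceiling(n_genes / n_modules))
    problems <- c(problems, "n_biomarkers exceeds the size of one module")
  if (effect_size < 0) problems <- c(problems, "effect_size must be >= 0")
  if (module_cor < 0 || module_cor >= 1)
    problems <- c(problems, "module_cor must be in [0, 1)")
  if (noise_sd <= 0) problems <- c(problems, "noise_sd must be positive")
  if (module_density < 0 || module_density > 1 ||
      background_density < 0 || background_density > 1)
    problems <- c(problems, "densities must be in [0, 1]")
  if (length(problems) > 0L)
    stop("invalid simulation spec:\n  ", paste(problems, collapse = "\n  "))

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  module <- sort(rep_len(seq_len(n_modules), n_genes))
  biomarkers <- which(module == 1L)[seq_len(n_biomarkers)]
  lambda <- noise_sd * sqrt(module_cor / (1 - module_cor))

  withr::with_seed(as.integer(seed), {
    y <- sample(rep(c(1L, 0L), c(n_cases, n_samples - n_cases)))
    z <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    x <- lambda * z[module, , drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
             n_genes, n_samples)
    if (n_biomarkers > 0L && effect_size > 0)
      x[biomarkers, ] <- x[biomarkers, ] +
        effect_size * noise_sd * matrix(y, n_biomarkers, n_samples,
                                        byrow = TRUE)
    dimnames(x) <- list(gene_ids, sample_ids)
    names(y) <- sample_ids

    # network: sample pairs, weight = model-implied expected |cor| + jitter
    ut <- which(upper.tri(diag(n_genes)), arr.ind = TRUE)
    same <- module[ut[, 1L]] == module[ut[, 2L]]
    keep <- stats::runif(nrow(ut)) <
      ifelse(same, module_density, background_density)
    pi_ <- ut[keep, 1L]
    pj <- ut[keep, 2L]
    vy <- mean(y) * (1 - mean(y))
    shift_var <- (effect_size * noise_sd)^2 * vy
    is_bio_i <- pi_ %in% biomarkers
    is_bio_j <- pj %in% biomarkers
    var_i <- lambda^2 + noise_sd^2 + is_bio_i * shift_var
    var_j <- lambda^2 + noise_sd^2 + is_bio_j * shift_var
    cov_ij <- (module[pi_] == module[pj]) * lambda^2 +
      (is_bio_i & is_bio_j) * shift_var
    w <- cov_ij / sqrt(var_i * var_j) +
      stats::runif(length(pi_), -0.05, 0.05)
    w <- pmin(1, pmax(0.02, w))
    net <- gene_network(data.frame(from = gene_ids[pi_], to = gene_ids[pj],
                                   weight = w, stringsAsFactors = FALSE),
                        nodes = gene_ids)
  })

  list(expression = x, labels = y, network = net,
       truth = list(biomarkers = gene_ids[biomarkers],
                    modules = stats::setNames(module, gene_ids),
                    params = list(n_genes = n_genes, n_samples = n_samples,
                                  n_cases = n_cases,
                                  n_biomarkers = n_biomarkers,
                                  effect_size = effect_size,
                                  n_modules = n_modules,
                                  module_cor = module_cor,
                                  noise_sd = noise_sd,
                                  module_density = module_density,
                                  background_density = background_density,
                                  seed = as.integer(seed))))
}

#' Write a simulated dataset in the pipeline's file formats
#'
#' Emits `expression.tsv`, `labels.tsv`, `edges.tsv`, `nodes.txt` and
#' `truth.json` into a directory, the same formats the pipeline consumes.
#'
#' @param dataset A list from [simulate_netrank_data()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  write_labels(dataset$labels, file.path(dir, "labels.tsv"))
  write_network(dataset$network, file.path(dir, "edges.tsv"),
                file.path(dir, "nodes.txt"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a bundled worked fixture
#'
#' Small datasets shipped with the package for documentation and golden
#' tests: `"worked"` is a 20-gene, 30-sample expression table with labels
#' and a companion network; `"two_node"` is the two genes `A - B` joined by
#' one unit edge whose fixed point under `d = 0.5` and prior `(1, 0)` is
#' `(2/3, 1/3)`; `"five_node"` is a 5-node weighted graph with an isolated
#' node. All fixtures are plain text under `inst/extdata/`.
#'
#' @param name One of `"worked"`, `"two_node"`, `"five_node"`.
#' @return For `"worked"`: list `expression`, `labels`, `network`. For the
#'   network fixtures: a [gene_network()].
#' @export
netrank_fixture <- function(name = c("worked", "two_node", "five_node")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "netrank",
                                  mustWork = TRUE)
  switch(name,
         worked = list(
           expression = read_expression(path("worked_expression.tsv")),
           labels = read_labels(path("worked_labels.tsv")),
           network = read_network(path("worked_edges.tsv"),
                                  path("worked_nodes.txt"))),
         two_node = read_network(path("two_node_edges.tsv")),
         five_node = read_network(path("five_node_edges.tsv"),
                                  path("five_node_nodes.txt")))
}
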