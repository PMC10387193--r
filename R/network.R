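#' Construct a weighted, undirected gene network
#'
#' Canonicalises an edge list into the network container used throughout the
#' package: self-loops are dropped, duplicate edges (either orientation) are
#' collapsed keeping the maximum weight, and weights must lie in (0, 1].
#' Degree is the weighted degree, the sum of a node's incident edge weights;
#' it normalises the outgoing score mass during ranking.
#'
#' @param edges Data frame (or 3-column object coercible to one) with
#'   columns `from`, `to`, `weight`.
#' @param nodes Optional character vector of node identifiers; the node set
#'   is the union of `nodes` and all edge endpoints, so isolated nodes can
#'   be retained. Order is preserved (`nodes` first, then new endpoints in
#'   edge order).
#' @return A `gene_network` object: list with `nodes`, `edges` (canonical
#'   data frame `from`, `to`, `weight`), sparse symmetric `adjacency`
#'   (genes x genes, `Matrix::dgCMatrix`), `degree` (named numeric) and
#'   `n_nodes` / `n_edges`.
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3L) stop("edges need columns from, to, weight")
  names(edges)[1:3] <- c("from", "to", "weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # no self-loops
  if (nrow(edges) > 0L) {
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0) ||
        any(edges$weight > 1))
      stop("edge weights must lie in (0, 1]")
    flip <- edges$from > edges$to
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    key <- paste(edges$from, edges$to, sep = "\r")
    edges <- edges[order(key, -edges$weight), , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ,
                   drop = FALSE]
  }
  node_ids <- unique(c(as.character(nodes),
                       rbind(edges$from, edges$to)))
  if (length(node_ids) == 0L) stop("network has no nodes")
  i <- match(edges$from, node_ids)
  j <- match(edges$to, node_ids)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(edges$weight, 2L),
                              dims = c(length(node_ids), length(node_ids)),
                              dimnames = list(node_ids, node_ids))
  rownames(edges) <- NULL
  structure(list(nodes = node_ids, edges = edges, adjacency = adj,
                 degree = stats::setNames(Matrix::rowSums(adj), node_ids),
                 n_nodes = length(node_ids), n_edges = nrow(edges)),
            class = "gene_network")
}

#' @export
#' @method print gene_network
print.gene_network <- function(x, ...) {
  cat("Weighted undirected gene network:", x$n_nodes, "nodes,",
      x$n_edges, "edges\n")
  iso <- sum(x$degree == 0)
  if (iso > 0) cat("  ", iso, " isolated node(s)\n", sep = "")
  if (x$n_edges > 0)
    cat(sprintf("  weight range %.3f..%.3f; mean weighted degree %.3f\n",
                min(x$edges$weight), max(x$edges$weight), mean(x$degree)))
  invisible(x)
}

#' Read a STRING-style edge list
#'
#' Parses whitespace- or tab-delimited lines `id1 id2 combined_score` with
#' scores on the standard 0-1000 confidence scale (a header line is
#' tolerated). Edges with `combined_score >= score_cutoff` are kept with
#' weight `combined_score / 1000`; duplicate orientations collapse to the
#' maximum score and self-loops are dropped.
#'
#' @param path Path to the edge-list file.
#' @param score_cutoff Minimum combined score kept (default 400, the
#'   conventional medium-confidence threshold).
#' @param nodes_path Optional path to a one-identifier-per-line node list so
#'   that nodes appearing only in dropped edges survive as isolated nodes.
#' @return A [gene_network()].
#' @export
read_string_network <- function(path, score_cutoff = 400, nodes_path = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 3L) stop("expected three columns: id1 id2 combined_score")
  if (nrow(tab) > 0L && is.na(suppressWarnings(as.numeric(tab[1L, 3L]))))
    tab <- tab[-1L, , drop = FALSE]  # header line
  score <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(score)) stop("non-numeric combined_score at line ",
                         which(is.na(score))[1L])
  if (any(score < 0 | score > 1000))
    stop("combined_score out of range [0, 1000] at line ",
         which(score < 0 | score > 1000)[1L])
  keep <- score >= score_cutoff & score > 0
  edges <- data.frame(from = tab[[1L]][keep], to = tab[[2L]][keep],
                      weight = score[keep] / 1000, stringsAsFactors = FALSE)
  nodes <- if (!is.null(nodes_path)) readLines(nodes_path) else NULL
  gene_network(edges, nodes = nodes)
}

#' Write a network as an edge list plus node list
#'
#' The edge list is a 3-column TSV `gene_a gene_b weight`; the node list
#' (one identifier per line) preserves isolated nodes across round-trips.
#'
#' @param net A [gene_network()].
#' @param edges_path Output path for the edge list.
#' @param nodes_path Optional output path for the node list.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(net, edges_path, nodes_path = NULL) {
  utils::write.table(
    data.frame(gene_a = net$edges$from, gene_b = net$edges$to,
               weight = format(net$edges$weight, digits = 12L)),
    edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodes_path)) writeLines(net$nodes, nodes_path)
  invisible(edges_path)
}

#' Read back a network written by [write_network()]
#'
#' @param edges_path Path to a 3-column `gene_a gene_b weight` TSV.
#' @param nodes_path Optional node-list path (one id per line).
#' @return A [gene_network()].
#' @export
read_network <- function(edges_path, nodes_path = NULL) {
  tab <- utils::read.table(edges_path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  nodes <- if (!is.null(nodes_path)) readLines(nodes_path) else NULL
  gene_network(data.frame(from = as.character(tab[[1L]]),
                          to = as.character(tab[[2L]]),
                          weight = as.numeric(tab[[3L]])), nodes = nodes)
}

#' Build a soft-thresholded co-expression network
#'
#' Computes all pairwise gene-gene Pearson correlations `c_ij` on the given
#' expression matrix and forms the unsigned weighted adjacency
#' `a_ij = |c_ij|^beta` (or the signed variant `((1 + c_ij) / 2)^beta`).
#' Pairs with adjacency above `edge_floor` become edges; the diagonal is
#' excluded. Optionally the adjacency is transformed to the topological
#' overlap measure (TOM) before thresholding, which rewards shared
#' neighbourhoods.
#'
#' Constant genes have undefined correlations; they are retained as isolated
#' nodes with a warning.
#'
#' @param x Expression matrix, genes in rows, at least 3 samples.
#' @param beta Soft-threshold power (positive; see [pick_soft_threshold()]).
#' @param edge_floor Adjacency below or equal to this is dropped, sparsifying
#'   the otherwise complete graph (default 0.01).
#' @param signed Use the signed adjacency `((1 + c) / 2)^beta` instead of
#'   `|c|^beta` (default `FALSE`).
#' @param tom Apply the topological-overlap transform before thresholding
#'   (default `FALSE`).
#' @return A [gene_network()] over all genes of `x` (constant genes
#'   isolated).
#' @export
coexpression_network <- function(x, beta = 6, edge_floor = 0.01,
                                 signed = FALSE, tom = FALSE) {
  if (ncol(x) < 3L) stop("need at least 3 samples to build a co-expression network")
  stopifnot(beta > 0, edge_floor >= 0, edge_floor < 1)
  undef <- apply(x, 1L, stats::var) == 0
  cc <- suppressWarnings(stats::cor(t(x)))
  if (any(undef))
    warning(sum(undef), " constant gene(s) left isolated: ",
            paste(utils::head(rownames(x)[undef], 5L), collapse = ", "),
            if (sum(undef) > 5L) ", ..." else "")
  cc[!is.finite(cc)] <- 0
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  a[undef, ] <- 0
  a[, undef] <- 0
  if (tom) a <- tom_similarity(a)
  ut <- which(upper.tri(a) & a > edge_floor, arr.ind = TRUE)
  edges <- data.frame(from = rownames(x)[ut[, 1L]],
                      to = rownames(x)[ut[, 2L]],
                      weight = pmin(a[ut], 1),
                      stringsAsFactors = FALSE)
  gene_network(edges, nodes = rownames(x))
}

# Topological overlap of a weighted adjacency (diagonal zero on input).
tom_similarity <- function(a) {
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tomm <- (l + a) / (kmin + 1 - a)
  diag(tomm) <- 0
  tomm
}

# Scale-free-topology fit of a weighted degree vector: regress log10
# frequency on log10 binned connectivity; sign-adjusted R^2 (negative slope
# counts positive).
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins || stats::sd(k) < sqrt(.Machine$double.eps))
    return(list(rsq = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- tapply(k, bin, mean)
  ok <- freq > 0 & is.finite(kmean)
  if (sum(ok) < 3L) return(list(rsq = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
  rsq <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2L]]
  list(rsq = -sign(slope) * rsq, slope = slope)
}

#' Choose the soft-threshold power by scale-free-topology fit
#'
#' For each candidate power, builds the unsigned adjacency `|c|^beta`,
#' computes the weighted connectivity of every gene, and fits a power law by
#' regressing log10 frequency on log10 binned connectivity. The fit index is
#' the regression R^2, sign-adjusted so that an *increasing* frequency-vs-
#' connectivity relationship scores negative. The chosen power is the
#' smallest candidate whose fit reaches `rsq_target` (default 0.8), else the
#' candidate maximising the fit. A degenerate degree distribution (all
#' connectivities equal) makes the fit undefined; the fallback is power 6
#' with a warning.
#'
#' @param x Expression matrix, genes in rows (>= 20 genes recommended).
#' @param candidate_betas Integer powers to scan (default 1..10, 12, 14, 16).
#' @param rsq_target Fit threshold for early acceptance (default 0.8).
#' @param n_bins Histogram bins for the connectivity distribution.
#' @param signed Use the signed adjacency variant.
#' @return List with `beta` (chosen power) and `fit_table`, a data frame of
#'   `beta`, `fit_rsq`, `slope`, `mean_k`, `median_k`, `max_k`.
#' @export
pick_soft_threshold <- function(x, candidate_betas = c(1:10, 12L, 14L, 16L),
                                rsq_target = 0.8, n_bins = 10L,
                                signed = FALSE) {
  stopifnot(length(candidate_betas) >= 1L, all(candidate_betas > 0))
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  tab <- data.frame(beta = candidate_betas, fit_rsq = NA_real_,
                    slope = NA_real_, mean_k = NA_real_,
                    median_k = NA_real_, max_k = NA_real_)
  for (row in seq_along(candidate_betas)) {
    b <- candidate_betas[row]
    a <- if (signed) ((1 + cc) / 2)^b else abs(cc)^b
    diag(a) <- 0
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins = n_bins)
    tab[row, -1L] <- c(fit$rsq, fit$slope, mean(k), stats::median(k), max(k))
  }
  if (length(candidate_betas) == 1L)
    return(list(beta = candidate_betas, fit_table = tab))
  if (all(is.na(tab$fit_rsq))) {
    warning("scale-free fit undefined (degenerate connectivity); falling back to beta = 6")
    return(list(beta = 6L, fit_table = tab))
  }
  hit <- which(!is.na(tab$fit_rsq) & tab$fit_rsq >= rsq_target)
  beta <- if (length(hit) > 0L) tab$beta[hit[1L]] else
    tab$beta[which.max(tab$fit_rsq)]
  list(beta = beta, fit_table = tab)
}

#' Restrict a network to a gene universe
#'
#' Returns the induced subgraph on the genes shared between the network and
#' `gene_ids`; genes of `gene_ids` absent from the network are added as
#' isolated nodes, so every gene to be scored exists in the graph. The node
#' set of the result is exactly `gene_ids`.
#'
#' @param net A [gene_network()].
#' @param gene_ids Character vector of gene identifiers.
#' @return A [gene_network()] whose nodes are `gene_ids`.
#' @export
restrict_network <- function(net, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0L) stop("empty gene universe")
  keep <- net$edges$from %in% gene_ids & net$edges$to %in% gene_ids
  gene_network(net$edges[keep, , drop = FALSE], nodes = gene_ids)
}
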