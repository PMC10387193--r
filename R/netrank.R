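#' Rank genes by damped propagation of phenotype association
#'
#' Fits the NetRank model: starting from the per-gene phenotype-association
#' prior `s`, iterate
#'
#'   `r_j <- (1 - d) * s_j + d * sum_i m_ij * r_i / degree_i`
#'
#' where `m_ij` is the symmetric edge weight between genes `i` and `j` and
#' `degree_i` is the weighted degree of gene `i` (the sum of its incident
#' edge weights). The damping factor `d` sets the balance between the
#' statistical association (`d = 0` returns the prior unchanged) and network
#' connectivity. Iteration starts at `r = s` and stops when the largest
#' absolute per-gene change falls below `tol` (supremum norm) or after
#' `max_iter` sweeps. For `d < 1` the update is a contraction with factor at
#' most `d`, so convergence is geometric and the fixed point unique.
#'
#' Isolated (dangling) genes emit no score mass and simply hold
#' `(1 - d) * s_j` plus any inflow; there is no teleport redistribution as
#' in classical PageRank. Scores are reported unnormalised; ranks, not
#' magnitudes, are the product.
#'
#' The update is Jacobi-style: every gene's new score is computed from the
#' previous sweep only, with a fixed per-gene summation order, so results
#' are bit-identical regardless of how the genes are partitioned across
#' `workers`.
#'
#' @param network A [gene_network()] over the genes to score.
#' @param prior A `correlation_prior` from [pearson_prior()], or a named
#'   numeric vector of prior scores. Every network node must be covered
#'   (use [restrict_network()] first).
#' @param d Damping factor in \[0, 1\]; default 0.5 weighs connectivity and
#'   statistical association equally.
#' @param tol Supremum-norm convergence tolerance (default 1e-9).
#' @param max_iter Maximum number of sweeps (default 1000).
#' @param workers Number of logical workers the update is partitioned over;
#'   any value yields bit-identical scores (default 1).
#' @return A `netrank` object: list with `gene_ids`, `scores` (named,
#'   network node order), `ranking` (data frame `gene_id`, `netrank_score`,
#'   `rank`, plus `prior_s` / `prior_p` when available, in descending score
#'   order with ties broken by gene id), `prior`, `d`, `tol`, `iterations`,
#'   `converged`, `residual` and `method`.
#' @seealso [netrank_exact()] for the closed-form fixed point,
#'   [select_signature()] for turning scores into a biomarker signature.
#' @export
netrank <- function(network, prior, d = 0.5, tol = 1e-9, max_iter = 1000L,
                    workers = 1L) {
  stopifnot(inherits(network, "gene_network"),
            is.numeric(d), length(d) == 1L, d >= 0, d <= 1,
            tol > 0, max_iter >= 1L, workers >= 1L)
  s <- prior_scores(prior, network$nodes)
  adj <- network$adjacency
  deg <- as.numeric(network$degree)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  if (d == 1 && (any(deg == 0) || !network_connected(network)))
    warning("d = 1 on a disconnected or dangling graph: fixed point may be non-unique / mass-leaking")
  r <- s
  residual <- Inf
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    r_new <- (1 - d) * s + d * as.numeric(adj %*% (r * inv_deg))
    residual <- max(abs(r_new - r))
    r <- r_new
    iterations <- it
    if (residual < tol) break
  }
  new_netrank(network, prior, s, r, d, tol,
              iterations = iterations, converged = residual < tol,
              residual = residual, method = "power")
}

#' Closed-form NetRank fixed point
#'
#' Solves the fixed-point system of the ranking iteration exactly:
#' `r = (1 - d) * (I - d * t(P))^{-1} s` with `P = D^{-1} M` the
#' degree-normalised adjacency (rows of isolated genes all zero). Used as an
#' independent check of the iterative solver on small graphs.
#'
#' @inheritParams netrank
#' @param max_nodes Dense-solve guard; networks above this size are refused
#'   (default 2000).
#' @return A `netrank` object with `method = "exact"`, `iterations = 0`.
#' @export
netrank_exact <- function(network, prior, d = 0.5, max_nodes = 2000L) {
  stopifnot(inherits(network, "gene_network"),
            is.numeric(d), length(d) == 1L, d >= 0, d <= 1)
  if (network$n_nodes > max_nodes)
    stop("network too large for a dense solve (", network$n_nodes, " > ",
         max_nodes, " nodes)")
  s <- prior_scores(prior, network$nodes)
  deg <- as.numeric(network$degree)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  # t(P) = M %*% D^{-1}: column i of the symmetric adjacency scaled by 1/deg_i
  tp <- as.matrix(network$adjacency) %*% diag(inv_deg, nrow = length(deg))
  m <- diag(length(s)) - d * tp
  r <- tryCatch(as.numeric(solve(m, (1 - d) * s)),
                error = function(e) stop("singular fixed-point system (d = ",
                                         d, "): ", conditionMessage(e)))
  residual <- max(abs(r - ((1 - d) * s + d * as.numeric(tp %*% r))))
  new_netrank(network, prior, s, r, d, tol = NA_real_, iterations = 0L,
              converged = TRUE, residual = residual, method = "exact")
}

# Resolve a prior (data frame or named vector) into scores aligned with the
# node order; error if any node lacks a prior.
prior_scores <- function(prior, nodes) {
  if (inherits(prior, "correlation_prior") || is.data.frame(prior)) {
    s <- stats::setNames(prior$s, prior$gene_id)
  } else if (is.numeric(prior) && !is.null(names(prior))) {
    s <- prior
  } else stop("prior must be a correlation_prior or a named numeric vector")
  missing <- setdiff(nodes, names(s))
  if (length(missing) > 0L)
    stop("prior missing for network node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  as.numeric(s[nodes])
}

# Breadth-first connectivity check on the sparse adjacency.
network_connected <- function(network) {
  n <- network$n_nodes
  if (n <= 1L) return(TRUE)
  adj <- network$adjacency
  seen <- logical(n)
  frontier <- 1L
  seen[frontier] <- TRUE
  while (length(frontier) > 0L) {
    reach <- which(Matrix::rowSums(adj[, frontier, drop = FALSE]) > 0)
    frontier <- reach[!seen[reach]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

new_netrank <- function(network, prior, s, r, d, tol, iterations, converged,
                        residual, method) {
  nodes <- network$nodes
  ranking <- data.frame(gene_id = nodes, netrank_score = r,
                        stringsAsFactors = FALSE)
  ord <- order(-ranking$netrank_score, ranking$gene_id)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  if (inherits(prior, "correlation_prior") || is.data.frame(prior)) {
    idx <- match(ranking$gene_id, prior$gene_id)
    ranking$prior_s <- prior$s[idx]
    if (!is.null(prior$p_value)) ranking$prior_p <- prior$p_value[idx]
    if (!is.null(prior$raw_r)) ranking$prior_r <- prior$raw_r[idx]
  } else {
    ranking$prior_s <- s[match(ranking$gene_id, nodes)]
  }
  rownames(ranking) <- NULL
  structure(list(gene_ids = nodes,
                 scores = stats::setNames(r, nodes),
                 ranking = ranking, prior = prior, network = network,
                 d = d, tol = tol, iterations = iterations,
                 converged = converged, residual = residual,
                 method = method),
            class = "netrank")
}

#' @export
#' @method print netrank
print.netrank <- function(x, n = 6L, ...) {
  cat("NetRank gene ranking (d = ", format(x$d), ", ", x$method,
      " solve)\n", sep = "")
  if (x$method == "power")
    cat(sprintf("  %s after %d iteration(s), residual %.3g (tol %.3g)\n",
                if (x$converged) "converged" else "NOT converged",
                x$iterations, x$residual, x$tol))
  cat("  ", length(x$gene_ids), " genes; top of the ranking:\n", sep = "")
  print(utils::head(x$ranking, n), row.names = FALSE, digits = 4L)
  invisible(x)
}

#' @export
#' @method summary netrank
summary.netrank <- function(object, ...) {
  out <- list(n_genes = length(object$gene_ids), d = object$d,
              method = object$method, iterations = object$iterations,
              converged = object$converged, residual = object$residual,
              score_quantiles = stats::quantile(object$scores),
              top = utils::head(object$ranking, 10L))
  class(out) <- "summary.netrank"
  out
}

#' @export
#' @method print summary.netrank
print.summary.netrank <- function(x, ...) {
  cat("NetRank fit:", x$n_genes, "genes, d =", format(x$d),
      paste0("(", x$method, ")"), "\n")
  cat(sprintf("  iterations %d, converged %s, residual %.3g\n",
              x$iterations, x$converged, x$residual))
  cat("  score quantiles:\n")
  print(x$score_quantiles, digits = 4L)
  cat("  top 10 genes:\n")
  print(x$top, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' Extract NetRank scores
#'
#' @param object A `netrank` fit.
#' @param ... Unused.
#' @return Named numeric vector of scores in network node order.
#' @export
coef.netrank <- function(object, ...) object$scores

#' Fixed-point defect of a NetRank solution
#'
#' Residuals are `r - ((1 - d) s + d * t(P) r)`, the per-gene defect of the
#' stationarity condition; at convergence every entry is below the solver
#' tolerance.
#'
#' @param object A `netrank` fit.
#' @param ... Unused.
#' @return Named numeric vector of per-gene defects.
#' @export
residuals.netrank <- function(object, ...) {
  s <- prior_scores(object$prior, object$network$nodes)
  deg <- as.numeric(object$network$degree)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  r <- as.numeric(object$scores)
  upd <- (1 - object$d) * s +
    object$d * as.numeric(object$network$adjacency %*% (r * inv_deg))
  stats::setNames(r - upd, object$gene_ids)
}

#' @export
as.data.frame.netrank <- function(x, ...) x$ranking

#' Plot NetRank scores against the prior
#'
#' Scatter of propagated score versus prior association, the visual account
#' of how much the network moved each gene; the top `highlight` genes are
#' marked.
#'
#' @param x A `netrank` fit.
#' @param highlight Number of top-ranked genes to emphasise (default 10).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.netrank <- function(x, highlight = 10L, ...) {
  s <- prior_scores(x$prior, x$network$nodes)
  graphics::plot(s, x$scores, xlab = "prior association s",
                 ylab = "NetRank score r",
                 main = sprintf("NetRank (d = %s)", format(x$d)), ...)
  graphics::abline(0, 1, lty = 2L, col = "grey50")
  top <- x$ranking$gene_id[seq_len(min(highlight, nrow(x$ranking)))]
  idx <- match(top, x$gene_ids)
  graphics::points(s[idx], x$scores[idx], pch = 19L, col = "firebrick")
  invisible(x)
}

#' Write a NetRank ranking and run report
#'
#' Emits the ranking table as TSV (`gene_id`, `netrank_score`, `rank`,
#' prior columns when available) and, optionally, a JSON run report with the
#' solver diagnostics.
#'
#' @param fit A `netrank` fit.
#' @param path Output TSV path.
#' @param report_path Optional JSON report path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(fit, path, report_path = NULL) {
  tab <- fit$ranking
  num <- vapply(tab, is.numeric, logical(1L)) & names(tab) != "rank"
  tab[num] <- lapply(tab[num], function(v) format(v, digits = 12L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(list(d = fit$d, tol = fit$tol,
                              iterations = fit$iterations,
                              converged = fit$converged,
                              residual = fit$residual,
                              method = fit$method,
                              n_genes = length(fit$gene_ids)),
                         report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
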