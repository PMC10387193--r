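#' Per-gene phenotype-association prior
#'
#' Computes, for every gene, the Pearson correlation between its expression
#' vector and the binary 0/1 phenotype (the point-biserial correlation), the
#' two-sided p-value from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and
#' the prior score `s` fed into the ranking iteration. By default
#' `s = |r|`: down-regulation is treated as informative as up-regulation and
#' the prior stays nonnegative, which keeps the random-surfer score
#' nonnegative. `signed = TRUE` preserves the sign for exploration.
#'
#' Genes with zero variance have an undefined correlation and are assigned
#' `s = 0`, `p_value = 1` with a warning; a zero-variance label is an error.
#'
#' @param x Expression matrix, genes in rows.
#' @param labels Named 0/1 vector covering every column of `x`.
#' @param signed If `TRUE`, `s` keeps the sign of the correlation; default
#'   `FALSE` uses the absolute value.
#' @return A `correlation_prior` data frame with columns `gene_id`, `raw_r`,
#'   `s` and `p_value`, one row per gene in matrix order.
#' @export
pearson_prior <- function(x, labels, signed = FALSE) {
  if (ncol(x) < 3L) stop("need at least 3 samples to compute a correlation prior")
  if (!all(colnames(x) %in% names(labels)))
    stop("labels missing for samples: ",
         paste(utils::head(setdiff(colnames(x), names(labels)), 5L), collapse = ", "))
  y <- as.numeric(labels[colnames(x)])
  if (stats::var(y) == 0) stop("labels have zero variance; both classes must be present")
  n <- ncol(x)
  r <- suppressWarnings(as.numeric(stats::cor(t(x), y)))
  undef <- !is.finite(r)
  if (any(undef)) {
    warning(sum(undef), " gene(s) with undefined correlation assigned s = 0, p = 1: ",
            paste(utils::head(rownames(x)[undef], 5L), collapse = ", "),
            if (sum(undef) > 5L) ", ..." else "")
    r[undef] <- 0
  }
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[undef] <- 1
  out <- data.frame(gene_id = rownames(x), raw_r = r,
                    s = if (signed) r else abs(r),
                    p_value = pmin(p, 1), stringsAsFactors = FALSE)
  class(out) <- c("correlation_prior", "data.frame")
  out
}

#' @export
#' @method print correlation_prior
print.correlation_prior <- function(x, ...) {
  cat("Phenotype-association prior for", nrow(x), "genes\n")
  cat(sprintf("  |r| range %.3f..%.3f; %d gene(s) with p < 0.05\n",
              min(abs(x$raw_r)), max(abs(x$raw_r)), sum(x$p_value < 0.05)))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Write a correlation prior as TSV
#'
#' @param prior A `correlation_prior` data frame from [pearson_prior()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prior <- function(prior, path) {
  utils::write.table(as.data.frame(prior), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
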