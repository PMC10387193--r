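#' Read a gene-expression matrix from delimited text
#'
#' Parses a TSV or CSV table with one header row and one leading identifier
#' column into a numeric genes-by-samples matrix. Files written with samples
#' in rows are transposed on load so that downstream code always sees genes
#' in rows.
#'
#' @param path Path to a delimited text file. The separator is sniffed from
#'   the header line (tab wins over comma) unless `sep` is given.
#' @param orientation `"genes"` if genes are in rows (the default), or
#'   `"samples"` if the file stores samples in rows and genes in columns.
#' @param sep Field separator; `NULL` (default) autodetects.
#' @return A numeric matrix, genes in rows, with gene identifiers as
#'   `rownames` and sample identifiers as `colnames`, both preserved verbatim
#'   in file order. Duplicate identifiers are tolerated here and reported;
#'   [clean_expression()] removes them.
#' @seealso [write_expression()], [clean_expression()]
#' @export
read_expression <- function(path, orientation = c("genes", "samples"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("no data rows in '", path, "'")
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("no data rows in '", path, "'")
  if (ncol(tab) < 2L) stop("expected an identifier column plus at least one data column in '", path, "'")
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("NA", "NaN", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  }
  rownames(num) <- ids
  if (orientation == "samples") num <- t(num)
  if (anyDuplicated(rownames(num)))
    message("duplicated gene identifiers: ",
            paste(unique(rownames(num)[duplicated(rownames(num))]), collapse = ", "))
  if (anyDuplicated(colnames(num)))
    message("duplicated sample identifiers: ",
            paste(unique(colnames(num)[duplicated(colnames(num))]), collapse = ", "))
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: genes in rows, header row of sample
#' identifiers, first column `gene_id`.
#'
#' @param x Numeric matrix, genes in rows.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binary phenotype labels
#'
#' Two-column delimited file `sample_id<TAB>label`, labels coded `0`/`1` or
#' `control`/`case` (header optional).
#'
#' @param path Path to the label file.
#' @return Named integer vector of 0/1 labels (1 = case), names = sample ids.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expected two columns: sample_id and label")
  if (tolower(tab[1L, 2L]) %in% c("label", "phenotype")) tab <- tab[-1L, , drop = FALSE]
  lab <- tolower(tab[[2L]])
  map <- c("0" = 0L, "1" = 1L, "control" = 0L, "case" = 1L)
  if (!all(lab %in% names(map)))
    stop("labels must be 0/1 or case/control; saw: ",
         paste(unique(lab[!lab %in% names(map)]), collapse = ", "))
  stats::setNames(unname(map[lab]), tab[[1L]])
}

#' Write binary phenotype labels as TSV
#'
#' @param labels Named 0/1 vector (names = sample ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                label = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove duplicated and incomplete samples (and duplicated genes)
#'
#' Applies the drop-don't-impute cleaning rule: sample columns with a
#' duplicated identifier are removed keeping the first occurrence, as are
#' gene rows with a duplicated identifier; samples with any missing
#' expression value are removed entirely.
#'
#' @param x Numeric expression matrix, genes in rows.
#' @return The cleaned matrix with a `"cleaning"` attribute: a data frame of
#'   removed identifiers with columns `id`, `what` (`"sample"`/`"gene"`) and
#'   `reason` (`"duplicate"`/`"missing"`). Retrieve it with
#'   [cleaning_report()].
#' @export
clean_expression <- function(x) {
  report <- data.frame(id = character(), what = character(),
                       reason = character(), stringsAsFactors = FALSE)
  dup_g <- duplicated(rownames(x))
  if (any(dup_g)) {
    report <- rbind(report, data.frame(id = rownames(x)[dup_g], what = "gene",
                                       reason = "duplicate"))
    x <- x[!dup_g, , drop = FALSE]
  }
  dup_s <- duplicated(colnames(x))
  if (any(dup_s)) {
    report <- rbind(report, data.frame(id = colnames(x)[dup_s], what = "sample",
                                       reason = "duplicate"))
    x <- x[, !dup_s, drop = FALSE]
  }
  has_na <- apply(x, 2L, anyNA)
  if (any(has_na)) {
    report <- rbind(report, data.frame(id = colnames(x)[has_na], what = "sample",
                                       reason = "missing"))
    x <- x[, !has_na, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("empty matrix after cleaning")
  attr(x, "cleaning") <- report
  x
}

#' @rdname clean_expression
#' @export
cleaning_report <- function(x) attr(x, "cleaning")

#' Min-max normalise each gene to \[0, 1\]
#'
#' Maps every gene's values linearly so its minimum becomes 0 and its
#' maximum 1 across all samples. Genes that are constant across samples have
#' an undefined scaler and are mapped to all zeros (with a warning), making
#' them inert in the correlation and network stages.
#'
#' @param x Cleaned numeric expression matrix, genes in rows.
#' @return Matrix of the same shape with every row in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  lo <- apply(x, 1L, min)
  hi <- apply(x, 1L, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) mapped to all zeros: ",
            paste(utils::head(rownames(x)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
    rng[const] <- 1
    lo[const] <- x[const, 1L]
  }
  out <- (x - lo) / rng
  attr(out, "cleaning") <- attr(x, "cleaning")
  out
}

#' Stratified development/test split
#'
#' Randomly partitions samples into a development and a held-out test set,
#' stratified by the binary label: within each class,
#' `round(dev_fraction * n_class)` samples go to the development set. The
#' split is reproducible given `seed` and leaves the global RNG state
#' untouched.
#'
#' @param x Expression matrix, genes in rows.
#' @param labels Named 0/1 vector covering every column of `x`.
#' @param dev_fraction Fraction of each class assigned to the development
#'   set, in (0, 1); default 0.7.
#' @param seed Integer seed controlling the split.
#' @return A list with elements `dev` and `test`, each a list
#'   `(expression, labels)`; column order within each split follows the
#'   input order.
#' @export
split_dev_test <- function(x, labels, dev_fraction = 0.7, seed = 1L) {
  stopifnot(is.numeric(dev_fraction), dev_fraction > 0, dev_fraction < 1)
  if (!all(colnames(x) %in% names(labels)))
    stop("labels missing for samples: ",
         paste(utils::head(setdiff(colnames(x), names(labels)), 5L), collapse = ", "))
  y <- labels[colnames(x)]
  dev_idx <- integer()
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    if (length(idx) < 2L)
      stop("class ", cls, " has fewer than 2 samples; cannot stratify")
    n_dev <- round(dev_fraction * length(idx))
    n_dev <- min(max(n_dev, 1L), length(idx) - 1L)
    dev_idx <- c(dev_idx, withr::with_seed(seed + as.integer(cls),
                                           sample(idx, n_dev)))
  }
  dev_idx <- sort(dev_idx)
  test_idx <- setdiff(seq_along(y), dev_idx)
  list(dev = list(expression = x[, dev_idx, drop = FALSE],
                  labels = y[dev_idx]),
       test = list(expression = x[, test_idx, drop = FALSE],
                   labels = y[test_idx]))
}
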