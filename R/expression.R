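## Co-expression screen: RPKM table IO, log10 transform, the 8-level
## expression binning used for plotting, pairwise Pearson correlation on
## log profiles, and candidate ranking against a reference gene.

#' Gene x sample RPKM expression matrix
#'
#' @param values numeric matrix of non-negative RPKM values with unique
#'   rownames (genes) and colnames (samples).
#' @param dataset_kind `"tissue"` or `"developmental"`.
#' @return an `expression_matrix`: the validated matrix with the kind as an
#'   attribute.
#' @export
expression_matrix <- function(values, dataset_kind = c("tissue", "developmental")) {
  dataset_kind <- match.arg(dataset_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample label: ", colnames(values)[duplicated(colnames(values))][1])
  if (anyNA(values)) stop("missing expression values are not allowed")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative RPKM value at gene '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  structure(values, dataset_kind = dataset_kind,
            class = c("expression_matrix", "matrix", "array"))
}

#' Read a tab-separated RPKM table
#'
#' First column gene id, header row of sample labels, one numeric RPKM cell
#' per gene and sample. Negative, missing, or non-numeric cells and
#' duplicated labels are rejected with the offending cell named.
#'
#' @param path file path.
#' @param dataset_kind `"tissue"` or `"developmental"`.
#' @return an [expression_matrix()].
#' @export
load_rpkm_table <- function(path, dataset_kind = c("tissue", "developmental")) {
  dataset_kind <- match.arg(dataset_kind)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("RPKM table needs a gene column plus >= 1 sample column")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[idx[1]], samples[idx[2]]))
  }
  m <- expression_matrix(vals, dataset_kind = dataset_kind)
  message(sprintf("loaded %d genes x %d samples (%s)", nrow(m), ncol(m),
                  dataset_kind))
  m
}

#' Write an expression matrix as a tab-separated RPKM table
#' @param x an [expression_matrix()] or gene x sample matrix.
#' @param path output file path.
#' @export
write_rpkm_table <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log10-transform expression values
#'
#' `value -> log10(value + offset)`. RPKM tables contain exact zeros
#' (tissues that do not express a gene), so a positive pseudo-count offset
#' is required before taking logs.
#'
#' @param x numeric matrix or vector of non-negative values.
#' @param offset pseudo-count, > 0.
#' @return object of the same shape with transformed values.
#' @export
log_transform <- function(x, offset = 1) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("'offset' must be a single positive number")
  y <- log10(unclass(x) + offset)
  attributes(y) <- attributes(unclass(x))
  y
}

#' Assign expression values to equal-width log-scale bins
#'
#' Reproduces the display convention of classifying each value into one of
#' `n_bins` expression-level bins: the range of the supplied (log-scale)
#' values is split into `n_bins` equal-width intervals; the top edge is
#' inclusive, so the maximum lands in bin `n_bins`. If all values are
#' identical every value goes to bin 1 and a warning is emitted.
#'
#' @param values numeric vector or matrix of log-scale expression values.
#' @param n_bins number of bins, >= 2.
#' @return integer object of the same shape with bin indices in
#'   `1..n_bins`; bin edges in attribute `"edges"` (length `n_bins + 1`).
#' @export
bin_expression <- function(values, n_bins = 8) {
  if (n_bins < 2) stop("'n_bins' must be >= 2")
  v <- unclass(values)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("all expression values identical: every value assigned to bin 1")
    bins <- array(1L, dim = if (is.null(dim(v))) length(v) else dim(v))
    edges <- c(rng[1], rep(rng[2], n_bins))
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bins <- findInterval(v, edges, rightmost.closed = TRUE)
  }
  bins <- as.integer(pmin(bins, n_bins))
  dim(bins) <- dim(v)
  dimnames(bins) <- dimnames(v)
  attr(bins, "edges") <- edges
  bins
}

#' Pairwise Pearson correlation of gene expression profiles
#'
#' Correlates log10(RPKM + offset) profiles for every unordered gene pair.
#' Genes whose log profile has zero variance cannot carry a Pearson
#' coefficient; they are flagged in `degenerate` and their entries hold the
#' explicit marker `NA` rather than being dropped.
#'
#' @param x an [expression_matrix()].
#' @param genes genes to correlate; default all.
#' @param offset pseudo-count for the log transform.
#' @param use_bins correlate the 8-level binned values instead of the log
#'   values (sensitivity check mirroring the plotted representation).
#' @param n_bins bins when `use_bins = TRUE`.
#' @return a `correlation_report`: list with `r` (symmetric matrix, unit
#'   diagonal for non-degenerate genes), `n_samples`, `degenerate` (gene
#'   names), and `dataset_kind`.
#' @export
pairwise_correlation <- function(x, genes = NULL, offset = 1,
                                 use_bins = FALSE, n_bins = 8) {
  stopifnot(inherits(x, "expression_matrix"))
  if (ncol(x) < 3L) stop("need >= 3 samples for Pearson correlation")
  if (is.null(genes)) genes <- rownames(x)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  prof <- log_transform(unclass(x)[genes, , drop = FALSE], offset = offset)
  if (use_bins) prof[] <- bin_expression(prof, n_bins = n_bins)
  v <- apply(prof, 1, var)
  degenerate <- genes[v == 0]
  r <- suppressWarnings(cor(t(prof), method = "pearson"))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r)[!genes %in% degenerate] <- 1
  structure(list(r = r, n_samples = ncol(x), degenerate = degenerate,
                 dataset_kind = attr(x, "dataset_kind")),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Pearson correlation report (", x$dataset_kind, ", n = ",
      x$n_samples, " samples)\n", sep = "")
  print(round(x$r, 3))
  if (length(x$degenerate))
    cat("degenerate (zero-variance) genes:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Rank candidate genes by co-expression with a reference gene
#'
#' Candidates are ordered by the mean of their per-dataset Pearson
#' correlations with the reference (descending); ties break
#' lexicographically by gene id. The per-dataset coefficients are retained
#' so the tissue and developmental evidence can be inspected separately.
#'
#' @param reports a single `correlation_report` or a list of them (e.g. one
#'   tissue, one developmental), all containing the reference gene.
#' @param reference_gene the reference (e.g. `"na"`).
#' @return data frame sorted by `mean_r`: `gene`, one `r_<dataset_kind>`
#'   column per report, `mean_r`, `rank`.
#' @export
rank_candidates <- function(reports, reference_gene) {
  if (inherits(reports, "correlation_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "correlation_report")))
  for (rep in reports) {
    if (!reference_gene %in% rownames(rep$r))
      stop("reference gene '", reference_gene, "' not in report")
    if (reference_gene %in% rep$degenerate)
      stop("reference gene '", reference_gene,
           "' is degenerate (zero variance): ranking undefined")
  }
  kinds <- make.unique(vapply(reports, `[[`, character(1), "dataset_kind"))
  genes <- sort(unique(unlist(lapply(reports, function(r) rownames(r$r)))))
  genes <- setdiff(genes, reference_gene)
  rmat <- sapply(reports, function(rep) {
    out <- rep(NA_real_, length(genes))
    hit <- genes %in% rownames(rep$r)
    out[hit] <- rep$r[genes[hit], reference_gene]
    out
  })
  rmat <- matrix(rmat, nrow = length(genes),
                 dimnames = list(genes, paste0("r_", kinds)))
  mean_r <- rowMeans(rmat, na.rm = FALSE)
  ord <- order(-mean_r, genes)
  out <- data.frame(gene = genes[ord], rmat[ord, , drop = FALSE],
                    mean_r = mean_r[ord], row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  attr(out, "reference") <- reference_gene
  out
}

#' Write a correlation matrix as TSV
#' @param report a `correlation_report`.
#' @param path output path.
#' @export
write_correlation_tsv <- function(report, path) {
  df <- data.frame(gene = rownames(report$r), report$r, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a candidate ranking as JSON
#' @param ranking output of [rank_candidates()].
#' @param path output path.
#' @export
write_ranking_json <- function(ranking, path) {
  jsonlite::write_json(
    list(reference = attr(ranking, "reference"),
         candidates = ranking),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
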