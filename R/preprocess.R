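#' Counts per million
#'
#' `CPM[g, s] = counts[g, s] / colsum_s * 1e6`, on raw library sizes.
#'
#' @param counts a [count_matrix()] or a plain numeric matrix.
#' @return Numeric matrix of CPM values with the input's dimnames.
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero))
    stop("zero library size for sample(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  sweep(m, 2, cs, "/") * 1e6
}

#' Filter genes by CPM support
#'
#' Keeps gene `g` iff strictly more than `threshold` CPM is seen in at least
#' `min_samples` samples — the standard low-expression filter for bulk
#' RNA-seq, applied to raw-count CPM. The counts of genes kept/dropped are
#' recorded in the result's `"provenance"` attribute.
#'
#' @param counts a [count_matrix()].
#' @param threshold CPM cutoff (strict `>`).
#' @param min_samples minimum number of samples exceeding the cutoff.
#' @return The filtered [count_matrix()].
#' @export
filter_by_cpm <- function(counts, threshold = 1, min_samples = 2) {
  stopifnot(inherits(counts, "count_matrix"))
  x <- cpm(counts)
  keep <- rowSums(x > threshold) >= min_samples
  out <- count_matrix(counts$counts[keep, , drop = FALSE], counts$metadata)
  attr(out, "provenance") <- list(
    filter = "cpm", threshold = threshold, min_samples = min_samples,
    n_before = nrow(counts$counts), n_after = sum(keep))
  out
}

#' Median-of-ratios size factors
#'
#' The classical median-of-ratios normalization: a pseudo-reference per gene
#' is the geometric mean of its counts across samples, computed over genes
#' with nonzero counts in every sample; each sample's factor is the median
#' of its count-to-reference ratios over those genes (midpoint convention
#' for even counts).
#'
#' @param counts a [count_matrix()] or numeric matrix.
#' @param positive_fallback if no gene is positive in all samples, compute
#'   the reference over each gene's positive counts only (and take medians
#'   over positive cells) instead of failing.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, positive_fallback = FALSE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    if (!positive_fallback)
      stop("no gene has nonzero counts in every sample; ",
           "set positive_fallback = TRUE to use a positive-counts pseudo-reference")
    lg <- log(m)
    lg[!is.finite(lg)] <- NA
    ref <- exp(rowMeans(lg, na.rm = TRUE))
    use <- is.finite(ref) & ref > 0
    f <- apply(m[use, , drop = FALSE] / ref[use], 2, function(r)
      stats::median(r[r > 0]))
  } else {
    ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
    f <- apply(m[all_pos, , drop = FALSE] / ref, 2, stats::median)
  }
  if (any(!is.finite(f) | f <= 0))
    stop("degenerate size factor for sample(s): ",
         paste(colnames(m)[!is.finite(f) | f <= 0], collapse = ", "))
  stats::setNames(f, colnames(m))
}

#' Log-normalized expression matrix
#'
#' `value[g, s] = log2(counts[g, s] / factor_s + 1)`. The result carries a
#' `"provenance"` attribute with the size factors and, when the input was
#' filtered, the filter record.
#'
#' @param counts a [count_matrix()].
#' @param factors per-sample positive size factors; computed with
#'   [size_factors()] when omitted.
#' @return Numeric genes x samples matrix of log2 normalized expression.
#' @export
log_normalize <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(factors)) factors <- size_factors(counts)
  if (length(factors) != ncol(counts$counts))
    stop("one size factor per sample required")
  if (any(!is.finite(factors) | factors <= 0))
    stop("size factors must be positive and finite")
  expr <- log2(sweep(counts$counts, 2, factors, "/") + 1)
  attr(expr, "provenance") <- c(
    attr(counts, "provenance"),
    list(size_factors = factors, transform = "log2(count/sf + 1)"))
  expr
}

#' Filter, normalize and log-transform a raw count matrix
#'
#' The standard preprocessing chain: CPM filter on raw counts, then
#' median-of-ratios size factors on the filtered matrix, then the log2
#' transform. Set `filter_after_normalization = TRUE` to compute size
#' factors on the unfiltered matrix first and filter afterwards.
#'
#' @inheritParams filter_by_cpm
#' @param filter_after_normalization alternative stage order (see Details).
#' @return Log2 expression matrix with provenance attribute.
#' @export
preprocess_counts <- function(counts, threshold = 1, min_samples = 2,
                              filter_after_normalization = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (filter_after_normalization) {
    f <- size_factors(counts)
    filtered <- filter_by_cpm(counts, threshold, min_samples)
    log_normalize(filtered, f[colnames(filtered$counts)])
  } else {
    filtered <- filter_by_cpm(counts, threshold, min_samples)
    log_normalize(filtered)
  }
}
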