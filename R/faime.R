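#' Rank-exponential FAIME gene weights for one sample
#'
#' Genes are ranked within the sample in ascending order of expression
#' (lowest expression gets rank 1), ties receiving the average rank; the
#' weight of rank `r` among `N` genes is `w(r) = r * exp(-r / N)`.
#' The weighting is deliberately isolated in this one function: every
#' downstream score is conditional on it, and a variant scheme can be
#' substituted here alone.
#'
#' @param expr_column numeric vector of expression values, named by gene.
#' @return Numeric vector of weights, same names and order as the input.
#' @export
rank_weights <- function(expr_column) {
  if (any(!is.finite(expr_column)))
    stop("non-finite expression value(s) in sample")
  n <- length(expr_column)
  if (n < 1) stop("empty expression column")
  r <- rank(expr_column, ties.method = "average")
  w <- r * exp(-r / n)
  names(w) <- names(expr_column)
  w
}

#' FAIME score of one gene set in one sample
#'
#' Mean weight over the member genes present in the universe minus the mean
#' weight over all non-member genes. Genes listed in the set but absent from
#' the weight vector are ignored (intersection semantics).
#'
#' @param weights named weight vector from [rank_weights()].
#' @param member_genes character vector of member gene symbols.
#' @return The score (a single number).
#' @export
faime_score <- function(weights, member_genes) {
  inside <- names(weights) %in% member_genes
  if (!any(inside)) stop("no member gene present in the expression universe")
  if (all(inside)) stop("member set covers the whole universe (empty complement)")
  mean(weights[inside]) - mean(weights[!inside])
}

#' Score every pathway in every sample
#'
#' Computes per-sample rank-exponential weights and the set-vs-complement
#' FAIME score of each pathway. Pathways mapping fewer than `min_genes`
#' genes of the expression universe are dropped (the count is reported via
#' `message()`).
#'
#' @param expr genes x samples expression matrix (any within-sample monotone
#'   scale: the score depends on ranks only).
#' @param sets a [gene_set_collection()].
#' @param min_genes minimum mapped genes for a pathway to be scored.
#' @return A `pathway_scores` object: list with `scores` (pathways x
#'   samples), `n_mapped` (mapped-gene count per retained pathway) and
#'   `view = "raw"`.
#' @export
score_matrix <- function(expr, sets, min_genes = 5) {
  stopifnot(inherits(sets, "gene_set_collection"))
  expr <- as.matrix(expr)
  if (nrow(expr) == 0 || ncol(expr) == 0) stop("empty expression matrix")
  universe <- rownames(expr)
  n <- nrow(expr)
  mapped <- lapply(sets$sets, function(g) which(universe %in% g))
  k <- lengths(mapped)
  keep <- k >= min_genes & k < n
  if (!any(keep))
    stop("no pathway maps at least ", min_genes, " genes of the universe")
  if (any(!keep))
    message(sprintf("score_matrix: dropped %d pathway(s) with fewer than %d mapped genes",
                    sum(!keep), min_genes))
  mapped <- mapped[keep]
  k <- k[keep]
  W <- apply(expr, 2, function(col) {
    r <- rank(col, ties.method = "average")
    r * exp(-r / n)
  })
  # membership-indicator product gives per-pathway member weight sums
  M <- matrix(0, nrow = length(mapped), ncol = n,
              dimnames = list(names(mapped), NULL))
  for (i in seq_along(mapped)) M[i, mapped[[i]]] <- 1
  inside_sum <- M %*% W
  total <- matrix(colSums(W), nrow = length(mapped), ncol = ncol(W),
                  byrow = TRUE)
  scores <- inside_sum / k - (total - inside_sum) / (n - k)
  colnames(scores) <- colnames(expr)
  structure(list(scores = scores, n_mapped = k, view = "raw"),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("pathway_scores (%s view): %d pathways x %d samples\n",
              x$view, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Rescale pathway scores to [-1, 1] per pathway
#'
#' The visualization view: per pathway across samples,
#' `x' = 2 (x - min) / (max - min) - 1`; a constant pathway maps to zeros.
#' Statistics are computed on the raw view; this view feeds heat maps and
#' clustering only.
#'
#' @param scores a raw-view `pathway_scores` object.
#' @return A `pathway_scores` object with `view = "minmax"`.
#' @export
minmax_normalize <- function(scores) {
  stopifnot(inherits(scores, "pathway_scores"))
  if (scores$view != "raw") stop("minmax_normalize expects the raw view")
  m <- scores$scores
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  rng <- hi - lo
  out <- 2 * (m - lo) / ifelse(rng == 0, 1, rng) - 1
  out[rng == 0, ] <- 0
  scores$scores <- out
  scores$view <- "minmax"
  scores
}
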