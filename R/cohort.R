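#' Ward clustering of samples on pathway-score profiles
#'
#' Euclidean distance between sample columns of the (by default
#' minmax-normalized) score matrix, Ward's linkage (`ward.D2`), tree cut to
#' exactly `k` clusters.
#'
#' @param scores a `pathway_scores` object (either view) or pathways x
#'   samples matrix.
#' @param k number of clusters.
#' @return A `cluster_result`: list with the `hclust` linkage, `assignment`
#'   (named integer vector, sample -> cluster label), and `k`.
#' @export
ward_clusters <- function(scores, k = 4) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else as.matrix(scores)
  if (k > ncol(m)) stop("k exceeds the number of samples")
  d <- stats::dist(t(m), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  assignment <- stats::cutree(hc, k = k)
  structure(list(linkage = hc, assignment = assignment, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d samples in %d clusters (sizes %s)\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

#' Per-cluster composition ordered as a disease gradient
#'
#' Counts healthy controls and patients per cluster and orders clusters by
#' ascending patient fraction — the control-like to patient-like gradient.
#'
#' @param assignment named cluster vector from [ward_clusters()].
#' @param metadata sample metadata with `sample_id` and `group`.
#' @return data.frame with columns `cluster`, `n_HC`, `n_PreSSc`,
#'   `frac_PreSSc`, ordered by ascending fraction.
#' @export
cluster_composition <- function(assignment, metadata) {
  idx <- match(names(assignment), metadata$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(names(assignment)[is.na(idx)], collapse = ", "))
  grp <- metadata$group[idx]
  labs <- sort(unique(assignment))
  tab <- data.frame(
    cluster = labs,
    n_HC = vapply(labs, function(cl) sum(grp == "HC" & assignment == cl), 0L),
    n_PreSSc = vapply(labs, function(cl) sum(grp == "PreSSc" & assignment == cl), 0L))
  tab$frac_PreSSc <- tab$n_PreSSc / (tab$n_HC + tab$n_PreSSc)
  tab <- tab[order(tab$frac_PreSSc, tab$cluster), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Collapse pathways to their root category
#'
#' Follows child-to-parent links to their fixed point; a pathway absent
#' from the hierarchy is its own root.
#'
#' @param sets a [gene_set_collection()] with a hierarchy, or a named
#'   child -> parent character vector (then `ids` must name the pathways to
#'   collapse).
#' @param ids pathway ids to map; defaults to the collection's sets.
#' @return Named character vector, pathway id -> root id.
#' @export
collapse_to_root <- function(sets, ids = NULL) {
  if (inherits(sets, "gene_set_collection")) {
    hierarchy <- sets$hierarchy
    if (is.null(ids)) ids <- names(sets$sets)
  } else {
    hierarchy <- sets
    if (is.null(ids)) ids <- names(hierarchy)
  }
  if (length(hierarchy) > 0) assert_acyclic(hierarchy)
  vapply(ids, function(p) {
    node <- p
    while (node %in% names(hierarchy)) node <- unname(hierarchy[[node]])
    node
  }, character(1))
}

#' Exact and chi-square association tests for a 2x2 table
#'
#' Returns both the two-sided Fisher exact p (summing tables with
#' hypergeometric probability no larger than the observed one) and the
#' Pearson chi-square p without continuity correction. For small tables the
#' two can disagree noticeably; both are reported so the caller can state
#' which was used.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return List with `p_exact`, `p_chisq`, and the input `table`.
#' @export
exact_association_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0 | table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margin (a zero row or column sum)")
  p_exact <- stats::fisher.test(table)$p.value
  p_chisq <- suppressWarnings(stats::chisq.test(table, correct = FALSE)$p.value)
  list(p_exact = p_exact, p_chisq = p_chisq, table = table)
}

#' Association of cluster membership with clinical covariates
#'
#' Categorical covariates are tested with a chi-square on the cluster x
#' level contingency table; numeric covariates with a one-way ANOVA F-test
#' across clusters. A covariate constant across samples is flagged
#' degenerate with p = 1.
#'
#' @param assignment named cluster vector.
#' @param covariates data.frame of per-sample covariates, rows aligned with
#'   (or named by) the samples of `assignment`.
#' @return data.frame with `covariate`, `type`, `p`, `degenerate`.
#' @export
cluster_covariate_tests <- function(assignment, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(assignment))
    stop("one covariate row per clustered sample required")
  if (length(unique(assignment)) < 2)
    stop("at least 2 clusters required")
  cl <- factor(assignment)
  rows <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2)
      return(data.frame(covariate = nm, type = "degenerate", p = 1,
                        degenerate = TRUE))
    if (is.numeric(v)) {
      p <- summary(stats::aov(v ~ cl))[[1]][["Pr(>F)"]][1]
      data.frame(covariate = nm, type = "numeric", p = p, degenerate = FALSE)
    } else {
      p <- suppressWarnings(stats::chisq.test(table(cl, v))$p.value)
      data.frame(covariate = nm, type = "categorical", p = p,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
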