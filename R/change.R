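#' ANCOVA change analysis of paired pathway scores
#'
#' Per pathway, the follow-up minus baseline change of each patient is
#' regressed on the outcome group, adjusting for the pathway's baseline
#' score and (optionally) the baseline clinical cluster:
#' `delta_i = b0 + b1 * [evolving]_i + b2 * pre_i + cluster terms + e_i`.
#' `b1`, its two-sided p, and Benjamini-Hochberg q across pathways are
#' reported, with significance at `q < alpha`. A cluster with a single
#' patient is dropped from the adjustment (with a warning). Pathways whose
#' fit is degenerate (zero residual variance, as with noiseless input) get
#' p = 1 and a degenerate flag.
#'
#' @param scores_pre,scores_post pathways x subjects matrices of raw FAIME
#'   scores, with identical row and column names (columns = subject ids).
#' @param outcome per-subject outcome, levels stable / evolving.
#' @param clusters optional per-subject baseline cluster labels.
#' @param alpha FDR significance level.
#' @return A `change_table` data.frame: per pathway `beta_group`, `se`,
#'   `p`, `q`, `significant`, `degenerate`, and the mean change per group
#'   (`mean_change_stable`, `mean_change_evolving`).
#' @export
ancova_change_table <- function(scores_pre, scores_post, outcome,
                                clusters = NULL, alpha = 0.05) {
  pre <- if (inherits(scores_pre, "pathway_scores")) scores_pre$scores else
    as.matrix(scores_pre)
  post <- if (inherits(scores_post, "pathway_scores")) scores_post$scores else
    as.matrix(scores_post)
  if (!identical(dim(pre), dim(post)) ||
      !identical(rownames(pre), rownames(post)))
    stop("pre and post matrices must share pathways")
  if (!setequal(colnames(pre), colnames(post)))
    stop("unpaired subject(s): ",
         paste(union(setdiff(colnames(pre), colnames(post)),
                     setdiff(colnames(post), colnames(pre))), collapse = ", "))
  post <- post[, colnames(pre), drop = FALSE]
  outcome <- as.character(outcome)
  if (length(outcome) != ncol(pre))
    stop("one outcome per subject required")
  if (!all(outcome %in% c("stable", "evolving")))
    stop("outcome must be stable / evolving")
  evolving <- as.numeric(outcome == "evolving")

  cl <- NULL
  if (!is.null(clusters)) {
    cl <- factor(clusters)
    singletons <- names(which(table(cl) < 2))
    if (length(singletons) > 0) {
      warning("dropping single-subject cluster indicator(s): ",
              paste(singletons, collapse = ", "))
      cl <- factor(ifelse(cl %in% singletons, NA, as.character(cl)))
    }
    if (nlevels(cl) < 2) cl <- NULL
  }

  delta <- post - pre
  res <- t(vapply(seq_len(nrow(pre)), function(i) {
    df <- data.frame(delta = delta[i, ], evolving = evolving,
                     pre = pre[i, ])
    if (!is.null(cl)) {
      df$cl <- cl
      fit <- stats::lm(delta ~ evolving + pre + cl, data = df)
    } else {
      fit <- stats::lm(delta ~ evolving + pre, data = df)
    }
    sm <- suppressWarnings(summary(fit)$coefficients)
    beta <- unname(stats::coef(fit)["evolving"])
    if ("evolving" %in% rownames(sm) && is.finite(sm["evolving", 4])) {
      c(beta = beta, se = sm["evolving", 2], p = sm["evolving", 4],
        degenerate = 0)
    } else {
      c(beta = ifelse(is.na(beta), 0, beta), se = NA_real_, p = 1,
        degenerate = 1)
    }
  }, numeric(4)))

  out <- data.frame(
    pathway = rownames(pre),
    beta_group = res[, "beta"], se = res[, "se"], p = res[, "p"],
    stringsAsFactors = FALSE)
  out$q <- benjamini_hochberg(out$p)
  out$significant <- out$q < alpha & res[, "degenerate"] == 0
  out$degenerate <- res[, "degenerate"] == 1
  out$mean_change_stable <- rowMeans(delta[, outcome == "stable", drop = FALSE])
  out$mean_change_evolving <- rowMeans(delta[, outcome == "evolving", drop = FALSE])
  rownames(out) <- NULL
  attr(out, "params") <- list(alpha = alpha,
                              adjusted_for_cluster = !is.null(cl))
  class(out) <- c("change_table", "data.frame")
  out
}

#' Root-category enrichment of change-associated pathways
#'
#' 2x2 table of (pathway root equals `target_root`) against (pathway
#' significant in the change analysis), with a Pearson chi-square p (no
#' continuity correction) and the two proportions, so a directional claim
#' ("the target root is over-represented among significant pathways") can
#' be checked. Degenerate margins are flagged with p = 1.
#'
#' @param significant named logical vector per pathway.
#' @param roots named character vector, pathway -> root id.
#' @param target_root the root category of interest.
#' @return List with `table`, `p`, `prop_significant` (share of target-root
#'   pathways among significant ones), `prop_nonsignificant`, `degenerate`.
#' @export
root_enrichment <- function(significant, roots, target_root) {
  ids <- names(significant)
  if (is.null(ids) || !all(ids %in% names(roots)))
    stop("every pathway needs a root label")
  is_target <- unname(roots[ids] == target_root)
  sig <- as.logical(significant)
  tab <- matrix(c(sum(is_target & sig), sum(is_target & !sig),
                  sum(!is_target & sig), sum(!is_target & !sig)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("target_root", "other_root"),
                                c("significant", "not_significant")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(table = tab, p = p,
       prop_significant = if (sum(sig) > 0) sum(is_target & sig) / sum(sig) else NA,
       prop_nonsignificant = if (sum(!sig) > 0)
         sum(is_target & !sig) / sum(!sig) else NA,
       degenerate = degenerate)
}

#' Group-wise pre/post mean scores of one pathway
#'
#' @param scores_pre,scores_post pathways x subjects raw score matrices.
#' @param outcome per-subject outcome (stable / evolving).
#' @param pathway pathway id.
#' @return Named numeric vector: `stable_pre`, `stable_post`,
#'   `evolving_pre`, `evolving_post`.
#' @export
pre_post_group_means <- function(scores_pre, scores_post, outcome, pathway) {
  pre <- if (inherits(scores_pre, "pathway_scores")) scores_pre$scores else
    as.matrix(scores_pre)
  post <- if (inherits(scores_post, "pathway_scores")) scores_post$scores else
    as.matrix(scores_post)
  if (!pathway %in% rownames(pre) || !pathway %in% rownames(post))
    stop("unknown pathway: ", pathway)
  post <- post[, colnames(pre), drop = FALSE]
  outcome <- as.character(outcome)
  c(stable_pre = mean(pre[pathway, outcome == "stable"]),
    stable_post = mean(post[pathway, outcome == "stable"]),
    evolving_pre = mean(pre[pathway, outcome == "evolving"]),
    evolving_post = mean(post[pathway, outcome == "evolving"]))
}
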