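#' Area under the ROC curve of a score vector
#'
#' Rank (Mann-Whitney) formulation with average ranks for ties.
#'
#' @param score numeric predictions, larger meaning more positive-like.
#' @param is_positive logical vector of true class membership.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, is_positive) {
  is_positive <- as.logical(is_positive)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(score, ties.method = "average")
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment under the current RNG stream: per class,
# shuffled indices dealt round-robin so every fold sees both classes
# whenever sizes permit.
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- sample(which(labels == lev))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

# Fit one binary classifier and return positive-class probabilities on xte.
# `hyper` is the single tunable: ridge lambda (logistic), mtry (random
# forest); the Gaussian naive Bayes has no tunable and ignores it.
fit_predict <- function(model, xtr, ytr, xte, positive, hyper = NULL) {
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  if (model == "logistic") {
    lambda <- if (is.null(hyper)) 1 / nrow(xtr) else hyper
    if (ncol(xtr) >= 2) {
      fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                            lambda = lambda, standardize = TRUE)
      as.numeric(stats::predict(fit, xte, type = "response"))
    } else {
      df <- data.frame(y = ytr == positive, x = xtr[, 1])
      fit <- suppressWarnings(stats::glm(y ~ x, df, family = stats::binomial()))
      as.numeric(stats::predict(fit, data.frame(x = xte[, 1]),
                                type = "response"))
    }
  } else if (model == "naive_bayes") {
    fit <- e1071::naiveBayes(xtr, ytr)
    as.numeric(stats::predict(fit, xte, type = "raw")[, positive])
  } else if (model == "random_forest") {
    mtry <- if (is.null(hyper)) max(1, floor(sqrt(ncol(xtr)))) else
      min(hyper, ncol(xtr))
    fit <- randomForest::randomForest(xtr, ytr, mtry = mtry, ntree = 300)
    as.numeric(stats::predict(fit, xte, type = "prob")[, positive])
  } else stop("unknown model: ", model)
}

#' Repeated cross-validated classification with in-fold pathway selection
#'
#' The baseline patient-vs-control model: over `runs` repetitions of
#' stratified `folds`-fold cross-validation, differential pathways are
#' selected within each training fold by the dual rule (`q < alpha` and
#' `|dR| > dr_threshold`), an L2-penalized logistic regression is fit on the
#' selected pathways, and the AUROC is computed on the held-out fold.
#' When a training fold selects no pathway, the single best by `|dR|` is
#' used (counted in `n_fallback`). Folds whose test set contains one class
#' only are skipped and counted.
#'
#' `select_in_fold = FALSE` performs selection once on the full data before
#' cross-validation — the leaky procedure, provided only to demonstrate the
#' optimism it induces.
#'
#' @param scores raw-view `pathway_scores` or pathways x samples matrix.
#' @param labels two-level factor/character per sample column.
#' @param runs,folds cross-validation design.
#' @param seed master seed; each run draws its folds from a derived stream.
#' @param gamma,alpha,dr_threshold selection parameters (see [dep_table()]).
#' @param lambda ridge penalty of the logistic model.
#' @param positive label treated as the positive class (default: second
#'   level, or `"PreSSc"` when present).
#' @param select_in_fold keep selection inside the training folds (default).
#' @return A `cv_report`: per-run-and-fold AUROCs, selected-pathway counts,
#'   summary mean and SD over all completed folds, design record.
#' @export
repeated_cv_classifier <- function(scores, labels, runs = 20, folds = 10,
                                   seed = 1, gamma = 0.2, alpha = 0.05,
                                   dr_threshold = 0.62897, lambda = NULL,
                                   positive = NULL, select_in_fold = TRUE) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else as.matrix(scores)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two classes required")
  if (is.null(positive)) positive <- if ("PreSSc" %in% lev) "PreSSc" else lev[2]
  y <- factor(labels, levels = c(setdiff(lev, positive), positive))
  if (is.null(lambda)) lambda <- 1 / ncol(m)

  global_sel <- NULL
  if (!select_in_fold) {
    dt <- dep_table(m, labels, gamma, alpha, dr_threshold)
    global_sel <- which(dt$significant)
    if (length(global_sel) == 0) global_sel <- which.max(abs(dt$dR))
  }

  auc <- matrix(NA_real_, runs, folds)
  nsel <- matrix(NA_integer_, runs, folds)
  skipped <- 0L; fallback <- 0L
  for (r in seq_len(runs)) {
    fold_of <- with_seed(seed + r * 1009L, stratified_folds(labels, folds))
    for (f in seq_len(folds)) {
      test <- which(fold_of == f); train <- which(fold_of != f)
      if (length(unique(labels[test])) < 2) { skipped <- skipped + 1L; next }
      if (select_in_fold) {
        dt <- dep_table(m[, train, drop = FALSE], labels[train],
                        gamma, alpha, dr_threshold)
        sel <- which(dt$significant)
        if (length(sel) == 0) {
          sel <- which.max(abs(dt$dR))
          fallback <- fallback + 1L
        }
      } else sel <- global_sel
      prob <- with_seed(seed + r * 1009L + f,
        fit_predict("logistic", t(m[sel, train, drop = FALSE]), y[train],
                    t(m[sel, test, drop = FALSE]), positive, lambda))
      auc[r, f] <- auroc(prob, labels[test] == positive)
      nsel[r, f] <- length(sel)
    }
  }
  vals <- auc[!is.na(auc)]
  structure(list(
    design = list(runs = runs, folds = folds, stratified = TRUE, seed = seed,
                  model = "logistic_l2", lambda = lambda,
                  select_in_fold = select_in_fold,
                  selection = list(gamma = gamma, alpha = alpha,
                                   dr_threshold = dr_threshold)),
    auroc = auc, n_selected = nsel, n_skipped = skipped,
    n_fallback = fallback,
    mean_auroc = mean(vals), sd_auroc = stats::sd(vals)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d runs x %d folds, AUROC %.3f +/- %.3f (%d skipped)\n",
              x$design$runs, x$design$folds, x$mean_auroc, x$sd_auroc,
              x$n_skipped))
  invisible(x)
}

# Univariate pathway ranking on training columns: ascending Yuen p, ties
# broken by descending |dR|.
univariate_rank <- function(m, labels, gamma) {
  lev <- unique(labels)
  ia <- which(labels == lev[1]); ib <- which(labels == lev[2])
  st <- yuen_rows(m, ia, ib, gamma)
  order(st$p, -abs(st$dR))
}

#' Nested cross-validated progression models
#'
#' For each model family and each selection fraction: outer repeated
#' stratified cross-validation; within each outer training fold, pathways
#' are ranked univariately (Yuen p, ties by `|dR|`) and the top
#' `ceiling(k_frac * n_pathways)` retained; an inner cross-validation on the
#' training fold (selection re-done per inner fold) tunes the model's single
#' hyper-parameter; the tuned model's AUROC is recorded on the outer
#' held-out fold.
#'
#' @param scores raw-view `pathway_scores` or matrix (baseline patient
#'   samples).
#' @param labels outcome per sample (e.g. stable / evolving).
#' @param models subset of `"logistic"`, `"naive_bayes"`, `"random_forest"`.
#' @param k_fracs selection fractions of the pathway total.
#' @param runs,folds outer design; `inner_folds` inner design.
#' @param seed master seed.
#' @param gamma trim proportion of the ranking statistic.
#' @param positive positive class (default second level, or `"evolving"`).
#' @return List with `reports` (a `cv_report` per model x k) and `summary`
#'   (data.frame of mean/SD AUROC per combination).
#' @export
nested_cv_progression <- function(scores, labels,
                                  models = c("logistic", "naive_bayes",
                                             "random_forest"),
                                  k_fracs = c(0.01, 0.05, 0.10, 0.20),
                                  runs = 20, folds = 10, seed = 1,
                                  inner_folds = 5, gamma = 0.2,
                                  positive = NULL) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else as.matrix(scores)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two classes required")
  if (is.null(positive)) positive <- if ("evolving" %in% lev) "evolving" else lev[2]
  y <- factor(labels, levels = c(setdiff(lev, positive), positive))
  npath <- nrow(m)

  grids <- list(
    logistic = 10^seq(-3, 1) / ncol(m),
    naive_bayes = list(NULL),
    random_forest = function(p) unique(pmax(1, c(floor(sqrt(p)), floor(p / 3), p))))

  reports <- list()
  summary_rows <- list()
  for (model in models) {
    for (kf in k_fracs) {
      top <- max(1L, ceiling(kf * npath))
      auc <- matrix(NA_real_, runs, folds)
      skipped <- 0L
      for (r in seq_len(runs)) {
        fold_of <- with_seed(seed + r * 1009L, stratified_folds(labels, folds))
        for (f in seq_len(folds)) {
          test <- which(fold_of == f); train <- which(fold_of != f)
          if (length(unique(labels[test])) < 2 ||
              min(table(labels[train])) < 5) { skipped <- skipped + 1L; next }
          grid <- grids[[model]]
          if (is.function(grid)) grid <- grid(top)
          best_hyper <- grid[[1]]
          if (length(grid) > 1) {
            inner_auc <- matrix(NA_real_, inner_folds, length(grid))
            with_seed(seed + r * 1009L + f * 131L, {
              in_fold <- stratified_folds(labels[train], inner_folds)
              for (g in seq_len(inner_folds)) {
                ite <- train[in_fold == g]; itr <- train[in_fold != g]
                if (length(unique(labels[ite])) < 2 ||
                    min(table(labels[itr])) < 5) next
                sel <- univariate_rank(m[, itr, drop = FALSE],
                                       labels[itr], gamma)[seq_len(top)]
                xtr <- t(m[sel, itr, drop = FALSE])
                xte <- t(m[sel, ite, drop = FALSE])
                for (gi in seq_along(grid)) {
                  prob <- fit_predict(model, xtr, y[itr], xte,
                                      positive, grid[[gi]])
                  inner_auc[g, gi] <- auroc(prob, labels[ite] == positive)
                }
              }
            })
            score_by_hyper <- colMeans(inner_auc, na.rm = TRUE)
            if (any(is.finite(score_by_hyper)))
              best_hyper <- grid[[which.max(score_by_hyper)]]
          }
          sel <- univariate_rank(m[, train, drop = FALSE],
                                 labels[train], gamma)[seq_len(top)]
          prob <- with_seed(seed + r * 1009L + f,
            fit_predict(model, t(m[sel, train, drop = FALSE]), y[train],
                        t(m[sel, test, drop = FALSE]), positive, best_hyper))
          auc[r, f] <- auroc(prob, labels[test] == positive)
        }
      }
      vals <- auc[!is.na(auc)]
      key <- sprintf("%s_k%g", model, kf)
      reports[[key]] <- structure(list(
        design = list(runs = runs, folds = folds, stratified = TRUE,
                      seed = seed, model = model, k_frac = kf,
                      inner_folds = inner_folds, n_selected = top),
        auroc = auc, n_skipped = skipped,
        mean_auroc = mean(vals), sd_auroc = stats::sd(vals)),
        class = "cv_report")
      summary_rows[[key]] <- data.frame(
        model = model, k_frac = kf, n_selected = top,
        mean_auroc = mean(vals), sd_auroc = stats::sd(vals),
        n_skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}
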