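test_that("AUROC follows the rank formula and its symmetries", {
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(auroc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(2)
  s <- rnorm(30); y <- rbinom(30, 1, 0.4) == 1
  expect_equal(auroc(s, y) + auroc(-s, y), 1)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(auroc(s, y), ref)
})

test_that("stratified folds keep both classes in every training split", {
  labels <- rep(c("HC", "PreSSc"), c(16, 33))
  set.seed(5)
  f <- pathsig:::stratified_folds(labels, 10)
  for (k in 1:10)
    expect_true(all(table(labels[f != k]) >= 5))
})

test_that("repeated CV is deterministic and perfect on separable scores", {
  set.seed(6)
  m <- matrix(rnorm(40 * 30), nrow = 40,
              dimnames = list(sprintf("p%02d", 1:40), sprintf("s%02d", 1:30)))
  labels <- rep(c("HC", "PreSSc"), each = 15)
  m[1:6, labels == "PreSSc"] <- m[1:6, labels == "PreSSc"] + 4

  a <- repeated_cv_classifier(m, labels, runs = 2, folds = 5, seed = 9)
  b <- repeated_cv_classifier(m, labels, runs = 2, folds = 5, seed = 9)
  expect_identical(a$auroc, b$auroc)
  expect_gte(a$mean_auroc, 0.95)
  expect_true(all(a$n_selected[!is.na(a$n_selected)] >= 1))

  # summary is recomputable from the per-fold entries
  vals <- a$auroc[!is.na(a$auroc)]
  expect_equal(a$mean_auroc, mean(vals))
  expect_equal(a$sd_auroc, sd(vals))
})

test_that("a constant score matrix scores at chance in every fold", {
  m <- matrix(5, nrow = 10, ncol = 24,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:24)))
  labels <- rep(c("HC", "PreSSc"), each = 12)
  cv <- repeated_cv_classifier(m, labels, runs = 2, folds = 4, seed = 3)
  expect_true(all(cv$auroc[!is.na(cv$auroc)] == 0.5))
  expect_gt(cv$n_fallback, 0)
})

test_that("in-fold selection never sees test samples: leaky selection inflates AUROC", {
  set.seed(12)
  m <- matrix(rnorm(200 * 49), nrow = 200,
              dimnames = list(sprintf("pw%03d", 1:200), sprintf("s%02d", 1:49)))
  labels <- rep(c("HC", "PreSSc"), c(16, 33))
  nested <- repeated_cv_classifier(m, labels, runs = 3, folds = 10, seed = 1)
  leaky <- repeated_cv_classifier(m, labels, runs = 3, folds = 10, seed = 1,
                                  select_in_fold = FALSE)
  expect_gte(leaky$mean_auroc - nested$mean_auroc, 0.1)
})

test_that("nested CV stays at chance under permuted outcomes", {
  set.seed(7)
  outcome <- rep(c("stable", "evolving"), c(19, 14))
  m <- matrix(rnorm(200 * 33), nrow = 200,
              dimnames = list(sprintf("pw%03d", 1:200), sprintf("P%02d", 1:33)))
  sums <- NULL
  reps <- 4
  for (r in seq_len(reps)) {
    perm <- pathsig:::with_seed(900 + r, sample(outcome))
    s <- nested_cv_progression(m, perm, runs = 1, folds = 5, seed = r)$summary
    sums <- if (is.null(sums)) s$mean_auroc else sums + s$mean_auroc
  }
  means <- sums / reps
  expect_true(all(means >= 0.35 & means <= 0.65))
})

test_that("nested CV finds outcome driven by a small pathway fraction", {
  set.seed(7)
  outcome <- rep(c("stable", "evolving"), c(19, 14))
  m <- matrix(rnorm(200 * 33), nrow = 200,
              dimnames = list(sprintf("pw%03d", 1:200), sprintf("P%02d", 1:33)))
  m[1:10, outcome == "evolving"] <- m[1:10, outcome == "evolving"] + 2
  res <- nested_cv_progression(m, outcome, runs = 2, folds = 5, seed = 1)
  expect_gte(max(res$summary$mean_auroc), 0.85)
  expect_equal(nrow(res$summary), 12)
  expect_true(all(res$summary$mean_auroc >= 0 & res$summary$mean_auroc <= 1))
})
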