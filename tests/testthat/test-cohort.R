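make_blobs <- function(centers, n_per, ndim = 20, sd = 0.1, seed = 17) {
  set.seed(seed)
  m <- do.call(cbind, lapply(seq_along(centers), function(i)
    matrix(rnorm(ndim * n_per, centers[i], sd), nrow = ndim)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  rownames(m) <- sprintf("p%02d", seq_len(ndim))
  m
}

test_that("Ward clustering separates well-separated blobs exactly", {
  m <- make_blobs(c(0, 10), n_per = 6)
  cl <- ward_clusters(m, k = 2)
  truth <- rep(1:2, each = 6)
  expect_equal(length(unique(paste(cl$assignment, truth))), 2)

  # permuting samples relabels but does not change the partition
  perm <- sample(ncol(m))
  cl2 <- ward_clusters(m[, perm], k = 2)
  agree <- table(cl$assignment[colnames(m)[perm]], cl2$assignment)
  expect_equal(sum(agree > 0), 2)

  expect_error(ward_clusters(m, k = 13), "exceeds")
})

test_that("a four-level gradient is recovered and merge heights are monotone", {
  m <- make_blobs(c(0, 3, 6, 9), n_per = 8, sd = 0.5, seed = 23)
  truth <- rep(1:4, each = 8)
  cl <- ward_clusters(m, k = 4)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(cl$assignment, truth), 0.9)
  expect_true(all(diff(cl$linkage$height) >= -1e-9))
})

test_that("cluster composition reports the patient-fraction gradient", {
  assignment <- c(a1 = 1, a2 = 1, a3 = 1, a4 = 1, b1 = 2, b2 = 2, b3 = 2)
  md <- toy_metadata(names(assignment),
                     c("HC", "HC", "HC", "PreSSc", "PreSSc", "PreSSc", "HC"))
  comp <- cluster_composition(assignment, md)
  expect_equal(comp$frac_PreSSc, c(0.25, 2 / 3))
  expect_equal(comp$n_HC + comp$n_PreSSc, c(4, 3))
  expect_equal(sum(comp$n_HC), 4)

  # pure-control cluster has fraction 0; label permutation keeps the order
  assignment2 <- c(a1 = 2, a2 = 2, a3 = 2, a4 = 2, b1 = 1, b2 = 1, b3 = 1)
  comp2 <- cluster_composition(assignment2, md)
  expect_equal(comp2$frac_PreSSc, comp$frac_PreSSc)
})

test_that("root collapse walks the hierarchy to its fixed point", {
  h <- c(a = "b", b = "root", c = "root")
  expect_equal(collapse_to_root(h),
               c(a = "root", b = "root", c = "root"))
  expect_equal(unname(collapse_to_root(h, ids = c("a", "orphan"))),
               c("root", "orphan"))
  expect_error(collapse_to_root(c(a = "b", b = "a")), "cycle")

  gsc <- gene_set_collection(list(a = c("X", "Y"), b = c("Z", "W")),
                             hierarchy = c(a = "b"))
  expect_equal(collapse_to_root(gsc), c(a = "b", b = "b"))
})

test_that("the 2x2 exact test reproduces hypergeometric enumeration", {
  # all 19 stable vs 9/14 evolving on low-dose aspirin
  res <- exact_association_2x2(matrix(c(19, 0, 9, 5), 2, byrow = TRUE))
  expect_equal(round(res$p_exact, 3), 0.008)
  expect_lt(res$p_chisq, res$p_exact)

  diag5 <- exact_association_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(diag5$p_exact, 2 / choose(10, 5), tolerance = 1e-12)

  prop <- exact_association_2x2(matrix(c(4, 8, 2, 4), 2, byrow = TRUE))
  expect_equal(prop$p_exact, 1)

  # transposition invariance
  t1 <- exact_association_2x2(matrix(c(7, 2, 3, 9), 2))
  t2 <- exact_association_2x2(t(matrix(c(7, 2, 3, 9), 2)))
  expect_equal(t1$p_exact, t2$p_exact)
  expect_equal(t1$p_chisq, t2$p_chisq)

  expect_error(exact_association_2x2(matrix(c(1, 0, 2, 0), 2)), "margin")
  expect_error(exact_association_2x2(matrix(c(1.5, 1, 2, 1), 2)), "integers")
})

test_that("covariate association uses chi-square or ANOVA as appropriate", {
  set.seed(31)
  assignment <- setNames(rep(1:3, each = 10), sprintf("s%02d", 1:30))
  cov <- data.frame(
    flat = rep("x", 30),
    tracks_cluster = rep(1:3, each = 10) + rnorm(30, 0, 1e-4),
    noise_cat = sample(c("u", "v"), 30, replace = TRUE))
  res <- cluster_covariate_tests(assignment, cov)
  expect_equal(res$p[res$covariate == "flat"], 1)
  expect_true(res$degenerate[res$covariate == "flat"])
  expect_lt(res$p[res$covariate == "tracks_cluster"], 1e-6)
  expect_equal(res$type[res$covariate == "noise_cat"], "categorical")
  expect_false(anyNA(res$p))
})
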