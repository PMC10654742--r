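test_that("winsorization replaces tail order statistics", {
  expect_equal(winsorize(c(1, 2, 3, 4, 100), 0.2), c(2, 2, 3, 4, 4))
  expect_equal(winsorize(c(100, 4, 1, 3, 2), 0.2), c(4, 4, 2, 3, 2))
  expect_equal(winsorize(c(5, 1, 9), 0), c(5, 1, 9))
  expect_equal(winsorize(rep(3, 6), 0.2), rep(3, 6))
  expect_error(winsorize(1, 0.2), "at least 2")
  expect_error(winsorize(1:5, 0.5), "gamma")
})

test_that("dR matches hand-computed winsorized algebra", {
  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  # trimmed means 3 and 5; winsorized SS 4 + 4 over 8 df -> s_W = 1
  expect_equal(robust_effect_size_dR(a, b), -1.284, tolerance = 1e-9)
  expect_equal(robust_effect_size_dR(b, a), 1.284, tolerance = 1e-9)
  expect_equal(robust_effect_size_dR(a, a), 0)
  # shift invariance
  expect_equal(robust_effect_size_dR(a + 7, b + 7),
               robust_effect_size_dR(a, b), tolerance = 1e-12)
  # degenerate spread
  expect_identical(robust_effect_size_dR(rep(1, 5), rep(2, 5)), -Inf)
  expect_identical(robust_effect_size_dR(rep(2, 5), rep(2, 5)), 0)
  expect_error(robust_effect_size_dR(1:4, 1:5), "at least 5")
})

test_that("the Yuen test matches the direct formula", {
  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  res <- winsorized_t_test(a, b)
  # h = 3 each, d = 4 * 1 / 6 each, t = -2 / sqrt(4/3) = -sqrt(3), df = 4
  expect_equal(res$t, -sqrt(3), tolerance = 1e-9)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-sqrt(3), 4), tolerance = 1e-9)

  same <- winsorized_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # scale invariance of t
  expect_equal(winsorized_t_test(3 * a, 3 * b)$t, res$t, tolerance = 1e-12)

  # pooled variant reduces to a classical t on winsorized values
  pool <- winsorized_t_test(a, b, variant = "pooled")
  ref <- t.test(winsorize(a, 0.2), winsorize(b, 0.2), var.equal = TRUE)
  expect_equal(pool$t, unname(ref$statistic))
  expect_equal(pool$p, ref$p.value)
})

test_that("BH adjustment follows step-up arithmetic", {
  expect_equal(benjamini_hochberg(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  # permutation equivariance
  p <- c(0.2, 0.001, 0.77, 0.04, 0.04)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(benjamini_hochberg(p[perm]), benjamini_hochberg(p)[perm])
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the vectorized row statistics agree with the scalar functions", {
  set.seed(13)
  m <- matrix(rnorm(40 * 18), nrow = 40)
  ia <- 1:7; ib <- 8:18
  st <- pathsig:::yuen_rows(m, ia, ib, 0.2)
  for (i in c(1, 17, 40)) {
    ref <- winsorized_t_test(m[i, ia], m[i, ib])
    expect_equal(st$t[i], ref$t, tolerance = 1e-12)
    expect_equal(st$df[i], ref$df, tolerance = 1e-12)
    expect_equal(st$p[i], ref$p, tolerance = 1e-12)
    expect_equal(st$dR[i], robust_effect_size_dR(m[i, ia], m[i, ib]),
                 tolerance = 1e-12)
  }
})

test_that("dep_table applies the dual criterion and sensible invariances", {
  set.seed(9)
  m <- matrix(rnorm(30 * 20), nrow = 30,
              dimnames = list(sprintf("p%02d", 1:30), paste0("s", 1:20)))
  labels <- rep(c("HC", "PreSSc"), each = 10)

  # same data in both groups: nothing can be significant
  dup <- cbind(m[, 1:10], m[, 1:10])
  colnames(dup) <- paste0("s", 1:20)
  tab0 <- dep_table(dup, labels)
  expect_equal(sum(tab0$significant), 0)

  # significance flag is exactly the conjunction of the two criteria
  m[1:5, labels == "PreSSc"] <- m[1:5, labels == "PreSSc"] + 2
  tab <- dep_table(m, labels)
  expect_identical(tab$significant, tab$q < 0.05 & abs(tab$dR) > 0.62897)
  expect_true(any(tab$significant))

  # adding a constant to every score leaves t and dR unchanged
  tab_shift <- dep_table(m + 11, labels)
  expect_equal(tab_shift$t, tab$t, tolerance = 1e-9)
  expect_equal(tab_shift$dR, tab$dR, tolerance = 1e-9)

  expect_error(dep_table(m, rep("HC", 20)), "two groups")
  expect_error(dep_table(m[, 1:8], rep(c("a", "b"), each = 4)),
               "at least 5")
})

test_that("a pathway can pass the FDR rule yet fail the effect-size rule", {
  # strong consistency (tiny p) with modest standardized effect
  set.seed(30)
  n <- 500
  a <- rnorm(n, 0, 1); b <- rnorm(n, 0.3, 1)
  tt <- winsorized_t_test(a, b)
  dr <- robust_effect_size_dR(a, b)
  expect_lt(tt$p, 0.001)
  expect_lt(abs(dr), 0.62897)
  m <- rbind(p1 = c(a, b))
  tab <- dep_table(m, rep(c("A", "B"), each = n))
  expect_false(tab$significant[1])
})
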