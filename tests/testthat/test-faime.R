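test_that("rank-exponential weights match direct evaluation", {
  expect_equal(rank_weights(c(g = 5)), c(g = exp(-1)))

  w <- rank_weights(c(a = 5, b = 1, c = 3))
  r <- c(3, 1, 2)
  expect_equal(unname(w), r * exp(-r / 3), tolerance = 1e-12)
  expect_equal(unname(w), c(1.1036, 0.7165, 1.0268), tolerance = 1e-4)

  # ties get the average rank
  wt <- rank_weights(c(a = 2, b = 2, c = 5))
  rt <- c(1.5, 1.5, 3)
  expect_equal(unname(wt), rt * exp(-rt / 3), tolerance = 1e-12)

  expect_error(rank_weights(c(1, NA, 3)), "non-finite")
})

test_that("the set score is the member/complement weight-mean difference", {
  w <- rank_weights(c(g1 = 5, g2 = 1, g3 = 3))
  expect_equal(faime_score(w, "g1"),
               unname(w["g1"] - mean(w[c("g2", "g3")])))
  expect_equal(faime_score(w, "g1"), 0.2320, tolerance = 1e-3)

  # equal weights give a zero score
  expect_equal(faime_score(setNames(rep(2, 4), paste0("g", 1:4)),
                           c("g1", "g2")), 0)

  # antisymmetry under complementation, exactly
  expect_equal(faime_score(w, c("g1", "g3")), -faime_score(w, "g2"))

  expect_error(faime_score(w, c("g1", "g2", "g3")), "complement")
  expect_error(faime_score(w, "absent"), "no member gene")
})

test_that("score_matrix drops under-mapped pathways and respects ranks only", {
  set.seed(21)
  expr <- matrix(rnorm(60), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sets <- gene_set_collection(list(
    big = paste0("g", 1:5),
    small = c("g1", "g2", "g9", "unmapped1", "unmapped2")))
  expect_message(sm <- score_matrix(expr, sets, min_genes = 5),
                 "dropped 1 pathway")
  expect_equal(rownames(sm$scores), "big")

  # a pathway mapping >= 5 genes through the intersection is retained
  sm4 <- suppressMessages(score_matrix(expr, sets, min_genes = 3))
  expect_setequal(rownames(sm4$scores), c("big", "small"))

  # duplicate sample columns give identical score columns
  expr2 <- cbind(expr, dup = expr[, 1])
  sm2 <- score_matrix(expr2, gene_set_collection(list(big = paste0("g", 1:5))))
  expect_equal(unname(sm2$scores[, "dup"]), unname(sm2$scores[, "s1"]))

  # monotone-transform invariance within samples, exact
  sm_lin <- score_matrix(expr, gene_set_collection(list(big = paste0("g", 1:5))))
  sm_exp <- score_matrix(2^expr, gene_set_collection(list(big = paste0("g", 1:5))))
  expect_identical(sm_lin$scores, sm_exp$scores)

  expect_error(score_matrix(expr, gene_set_collection(list(none = "zz"))),
               "no pathway maps")
})

test_that("scores agree with the per-sample scalar computation", {
  set.seed(4)
  expr <- matrix(rnorm(200 * 5), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:5)))
  members <- sprintf("g%03d", sample(200, 20))
  sm <- score_matrix(expr, gene_set_collection(list(S = members)))
  manual <- vapply(1:5, function(j)
    faime_score(rank_weights(expr[, j]), members), numeric(1))
  expect_equal(unname(sm$scores["S", ]), manual, tolerance = 1e-10)
})

test_that("random gene sets score zero on average", {
  set.seed(8)
  expr <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  w <- rank_weights(expr)
  draws <- replicate(1000, faime_score(w, sample(names(expr), 25)))
  expect_lt(abs(mean(draws)), 0.02 * mean(w))
})

test_that("minmax view rescales each pathway to [-1, 1]", {
  raw <- structure(list(
    scores = rbind(p1 = c(1, 2, 4), p2 = c(7, 7, 7), p3 = c(-2, 0, 5)),
    n_mapped = c(p1 = 5, p2 = 5, p3 = 5), view = "raw"),
    class = "pathway_scores")
  mm <- minmax_normalize(raw)
  expect_equal(unname(mm$scores["p1", ]), c(-1, -1 / 3, 1))
  expect_equal(unname(mm$scores["p2", ]), c(0, 0, 0))
  expect_equal(range(mm$scores["p3", ]), c(-1, 1))
  expect_error(minmax_normalize(mm), "raw view")
})
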