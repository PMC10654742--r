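make_paired <- function(npath = 6, seed = 14, noise = 0.3) {
  set.seed(seed)
  subj <- sprintf("P%02d", 1:12)
  outcome <- rep(c("stable", "evolving"), each = 6)
  pre <- matrix(rnorm(npath * 12), nrow = npath,
                dimnames = list(paste0("pw", 1:npath), subj))
  list(pre = pre, outcome = outcome, subjects = subj, noise = noise)
}

test_that("no change means no group coefficient", {
  d <- make_paired()
  tab <- ancova_change_table(d$pre, d$pre, d$outcome)
  expect_true(all(tab$beta_group == 0))
  expect_true(all(!tab$significant))
  expect_true(all(tab$degenerate))
})

test_that("a shared deterministic change cancels out of the group term", {
  d <- make_paired()
  post <- d$pre + 1.5
  tab <- ancova_change_table(d$pre, post, d$outcome)
  expect_equal(tab$beta_group, rep(0, nrow(tab)), tolerance = 1e-9)
  expect_equal(tab$mean_change_stable, rep(1.5, nrow(tab)))
  expect_equal(tab$mean_change_evolving, rep(1.5, nrow(tab)))
})

test_that("without clusters and baseline dependence, beta equals the mean-change difference", {
  d <- make_paired()
  # noiseless group effect plus exact baseline regression term
  post <- d$pre + 0.4 * d$pre +
    matrix(rep(ifelse(d$outcome == "evolving", 2, 0), each = nrow(d$pre)),
           nrow = nrow(d$pre))
  tab <- ancova_change_table(d$pre, post, d$outcome)
  expect_equal(tab$beta_group, rep(2, nrow(tab)), tolerance = 1e-9)
})

test_that("beta is invariant to shifting a pathway's pre and post scores", {
  d <- make_paired()
  post <- d$pre + matrix(rnorm(length(d$pre), 0, d$noise), nrow = nrow(d$pre))
  tab <- ancova_change_table(d$pre, post, d$outcome)
  tab_shift <- ancova_change_table(d$pre + 10, post + 10, d$outcome)
  expect_equal(tab_shift$beta_group, tab$beta_group, tolerance = 1e-9)
})

test_that("pairing and cluster degeneracies are caught", {
  d <- make_paired()
  post <- d$pre
  colnames(post)[1] <- "P99"
  expect_error(ancova_change_table(d$pre, post, d$outcome), "P99")

  post2 <- d$pre + matrix(rnorm(length(d$pre)), nrow = nrow(d$pre))
  cl <- c(rep("c1", 11), "c2")  # singleton cluster dropped with a warning
  expect_warning(tab <- ancova_change_table(d$pre, post2, d$outcome,
                                            clusters = cl),
                 "single-subject")
  expect_false(attr(tab, "params")$adjusted_for_cluster)
})

test_that("group-term p-values are uniform under the null", {
  set.seed(42)
  subj <- sprintf("P%02d", 1:33)
  outcome <- rep(c("stable", "evolving"), c(19, 14))
  pre <- matrix(rnorm(200 * 33), nrow = 200,
                dimnames = list(sprintf("pw%03d", 1:200), subj))
  post <- pre + matrix(rnorm(200 * 33, 0, 0.5), nrow = 200)
  tab <- ancova_change_table(pre, post, sample(outcome))
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # BH q-values never decrease when p increases
  o <- order(tab$p)
  expect_true(all(diff(tab$q[o]) >= -1e-12))
})

test_that("root enrichment builds the right table and chi-square", {
  sig <- setNames(rep(c(TRUE, FALSE), c(50, 50)), sprintf("pw%03d", 1:100))
  roots <- setNames(rep(c("target", "other"), c(40, 60)),
                    sprintf("pw%03d", 1:100))
  # arrange counts [[30,20],[10,40]] wrt target x significant
  roots[] <- "other"
  roots[names(sig)[sig][1:30]] <- "target"
  roots[names(sig)[!sig][1:20]] <- "target"
  res <- root_enrichment(sig, roots, "target")
  expect_equal(unname(res$table), matrix(c(30, 20, 20, 30), 2, byrow = TRUE))
  # direct Pearson formula oracle
  a <- 30; b <- 20; c <- 20; d <- 30; n <- a + b + c + d
  chi <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$p, pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(res$prop_significant, res$prop_nonsignificant)

  none <- root_enrichment(setNames(rep(FALSE, 10), names(sig)[1:10]),
                          roots[1:10], "target")
  expect_true(none$degenerate)
  expect_equal(none$p, 1)
})

test_that("pre/post group means are plain arithmetic", {
  pre <- rbind(pw1 = c(1, 3, 2, 4))
  post <- rbind(pw1 = c(2, 4, 1, 1))
  colnames(pre) <- colnames(post) <- paste0("P", 1:4)
  outcome <- c("stable", "stable", "evolving", "evolving")
  m <- pre_post_group_means(pre, post, outcome, "pw1")
  expect_equal(unname(m), c(2, 3, 3, 1))

  const <- pre; const[] <- 7
  mc <- pre_post_group_means(const, const, outcome, "pw1")
  expect_true(all(mc == 7))
  expect_error(pre_post_group_means(pre, post, outcome, "missing"),
               "unknown pathway")
})
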