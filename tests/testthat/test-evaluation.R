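test_that("filter_sites_min_n applies the threshold", {
  sites <- rep(c("A", "B", "C"), times = c(10, 4, 6))
  bags <- lapply(seq_along(sites), function(i)
    patch_bag(sprintf("s%02d", i), sites[i], matrix(rnorm(8), 4, 2)))
  co <- cohort(bags)
  f <- filter_sites_min_n(co, 5)
  expect_identical(length(f$bags), 16L)
  expect_setequal(unique(site_labels(f)), c("A", "C"))
  expect_identical(length(filter_sites_min_n(co, 4)$bags), 20L)
  co1 <- cohort(bags[1:10])
  expect_error(filter_sites_min_n(co1, 5), "fewer than 2 sites")
})

test_that("bh_adjust matches the step-up definition and reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(33)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bf_bh(p))
    expect_equal(q, p.adjust(p, method = "BH"))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone after sorting
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
})

test_that("auroc equals exhaustive pairwise counting with tie credit", {
  expect_equal(auroc(c(1, 2, 3, 4), c("n", "n", "p", "p"), positive = "p"), 1)
  # 6-point toy with a tie across classes
  s <- c(0.1, 0.4, 0.4, 0.6, 0.8, 0.2)
  l <- c("n", "n", "p", "p", "p", "n")
  expect_equal(auroc(s, l, positive = "p"), bf_auroc(s, l == "p"))
  set.seed(44)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    l <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(auroc(s, l, positive = "b"), bf_auroc(s, l == "b"))
  }
  # null behavior
  set.seed(9)
  s <- runif(4000); l <- sample(c("a", "b"), 4000, replace = TRUE)
  expect_lt(abs(auroc(s, l, positive = "b") - 0.5), 0.05)
  expect_error(auroc(c(1, 2), c("a", "a")), "2 classes")
})

test_that("weighted one-vs-rest AUROC reduces correctly for two classes", {
  set.seed(5)
  n <- 60
  P <- matrix(runif(2 * n), n, 2); P <- P / rowSums(P)
  colnames(P) <- c("x", "y")
  l <- sample(c("x", "y"), n, replace = TRUE, prob = c(0.7, 0.3))
  a_y <- auroc(P[, "y"], l, positive = "y")
  a_x <- auroc(P[, "x"], l, positive = "x")
  # complementary columns: AUROC(class x) = 1 - AUROC(class y vs rest on x)
  expect_equal(a_x, 1 - auroc(P[, "x"], l, positive = "y"))
  nx <- sum(l == "x"); ny <- sum(l == "y")
  expect_equal(auroc(P, l, multiclass = "ovr_weighted"),
               (nx * a_x + ny * a_y) / n)
  # three-class: matches direct weighted computation
  P3 <- matrix(runif(3 * n), n, 3); P3 <- P3 / rowSums(P3)
  colnames(P3) <- c("x", "y", "z")
  l3 <- sample(c("x", "y", "z"), n, replace = TRUE)
  direct <- sum(vapply(c("x", "y", "z"), function(cl)
    sum(l3 == cl) / n * bf_auroc(P3[, cl], l3 == cl), numeric(1)))
  expect_equal(auroc(P3, l3, multiclass = "ovr_weighted"), direct)
})

test_that("make_folds stratifies deterministically", {
  l <- rep(c("a", "b"), c(50, 50))
  f <- make_folds(l, 5, seed = 2)
  expect_identical(as.integer(table(f)), rep(20L, 5))
  for (k in 1:5) expect_identical(as.integer(table(l[f == k])), c(10L, 10L))
  l2 <- rep(c("a", "b"), c(90, 10))
  f2 <- make_folds(l2, 5, seed = 2)
  for (k in 1:5) expect_identical(sum(l2[f2 == k] == "b"), 2L)
  expect_identical(make_folds(l2, 5, seed = 7), make_folds(l2, 5, seed = 7))
  expect_error(make_folds(rep(c("a", "b"), c(20, 3)), 5), "fewer than k")
})

test_that("t_tests covers one-sided, paired and degenerate paths", {
  # hand case: mean 0.5, t = 0, one-sided p = 0.5
  r <- t_tests(c(0.55, 0.45, 0.50))
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)
  expect_identical(r$df, 2)
  # agreement with stats::t.test on a generic case
  a <- c(0.61, 0.58, 0.70, 0.66, 0.59)
  r2 <- t_tests(a)
  ref <- t.test(a, mu = 0.5, alternative = "greater")
  expect_equal(r2$t, unname(ref$statistic))
  expect_equal(r2$p, ref$p.value)
  b <- c(0.52, 0.55, 0.60, 0.64, 0.51)
  r3 <- t_tests(a, b)
  ref3 <- t.test(a, b, paired = TRUE)
  expect_equal(r3$t, unname(ref3$statistic))
  expect_equal(r3$p, ref3$p.value)
  # degenerate: constant folds above the null
  r4 <- t_tests(rep(0.6, 5))
  expect_identical(r4$t, Inf)
  expect_identical(r4$p, 0)
  expect_true(r4$degenerate)
  # paired identical vectors
  r5 <- t_tests(a, a)
  expect_identical(r5$t, 0)
  expect_identical(r5$p, 1)
  expect_error(t_tests(0.5), "folds")
})

test_that("screen_attributes implements the q-and-minority rule", {
  set.seed(6)
  n <- 400
  site <- sample(c("s1", "s2", "s3", "s4"), n, replace = TRUE)
  tab <- data.frame(
    mirror = site,                                     # identical to site
    indep = sample(c("x", "y"), n, replace = TRUE),    # independent
    rare = c(rep("u", 29), rep("v", n - 29)))          # minority 29
  tab$rare <- sample(tab$rare)
  res <- screen_attributes(tab, site)
  expect_identical(nrow(res), 3L)
  m <- res[res$attribute == "mirror", ]
  expect_lt(m$p, 1e-10)
  expect_true(m$included)
  r <- res[res$attribute == "rare", ]
  expect_identical(r$minority_count, 29)
  expect_false(r$included)                 # excluded regardless of q
  expect_true(all(res$q >= res$p))
  # missing values dropped pairwise
  tab$indep[1:50] <- NA
  res2 <- screen_attributes(tab, site)
  expect_identical(nrow(res2), 3L)
})

test_that("bootstrap_ci percentile interval behaves", {
  s <- c(0.1, 0.2, 0.8, 0.9); l <- c("n", "n", "p", "p")
  ci <- bootstrap_ci(s, l, n_boot = 10, seed = 4)
  expect_equal(ci$point, 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
  set.seed(11)
  s2 <- runif(40); l2 <- sample(c("n", "p"), 40, replace = TRUE)
  ci2 <- bootstrap_ci(s2, l2, n_boot = 10, seed = 9)
  ci3 <- bootstrap_ci(s2, l2, n_boot = 10, seed = 9)
  expect_identical(ci2$replicates, ci3$replicates)   # seeded determinism
  expect_lte(ci2$lower, ci2$upper)
  expect_identical(length(ci2$replicates), 10L)
})

test_that("summarize_cohort computes counts, percentages and missingness", {
  # male 246 / 373 with no missing -> 65.95%
  tab <- data.frame(sex = rep(c("Male", "Female"), c(246, 127)))
  s <- summarize_cohort(tab)
  male <- s[!is.na(s$class) & s$class == "Male", ]
  expect_equal(male$n, 246)
  expect_equal(male$pct_nonmissing, 65.95)
  expect_equal(male$pct_total, 65.95)
  miss <- s[is.na(s$class), ]
  expect_equal(miss$pct_missing, 0)
  # 434 slides, 19 missing -> 4.38% missing; denominators differ
  tab2 <- data.frame(age = c(rep(">65", 242), rep("<=65", 173),
                             rep(NA, 19)))
  s2 <- summarize_cohort(tab2)
  expect_equal(s2$pct_missing[is.na(s2$class)], 4.38)
  old <- s2[!is.na(s2$class) & s2$class == ">65", ]
  expect_equal(old$pct_nonmissing, round(100 * 242 / 415, 2))
  expect_equal(old$pct_total, round(100 * 242 / 434, 2))
  # all missing: one row, no class rows
  s3 <- summarize_cohort(data.frame(a = rep(NA_character_, 5)))
  expect_identical(nrow(s3), 1L)
  expect_equal(s3$pct_missing, 100)
  expect_error(summarize_cohort(data.frame()), "empty")
})

test_that("run_experiment pairs conditions on one fold assignment", {
  co <- separable_cohort(n_per_class = 10, P = 10, D = 6, seed = 13)
  cfgf <- function(D, C) fast_amil(D, C, epochs = 3)
  res <- run_experiment(list(a = co, b = co), "lab", k = 2,
                        config_fn = cfgf, seed = 3)
  # identical inputs -> identical fold AUROCs -> degenerate paired t
  expect_identical(res$fold_aurocs$a, res$fold_aurocs$b)
  expect_identical(res$summary$t_vs_baseline[2], 0)
  expect_identical(res$summary$p_vs_baseline[2], 1)
  expect_equal(res$summary$mean_auroc,
               vapply(res$fold_aurocs, mean, numeric(1)),
               ignore_attr = TRUE)
  # one shared fold assignment: out-of-fold score masks coincide
  expect_identical(is.na(res$scores$a), is.na(res$scores$b))
  expect_identical(length(res$fold), 20L)
})
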