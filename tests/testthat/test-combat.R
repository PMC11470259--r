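test_that("drop_degenerate_features drops dataset-wide on per-slide zeros", {
  mk <- function(id, site, X) patch_bag(id, site, X)
  # slide A: feature 1 constant; slide B: feature 2 constant; feature 3 varies
  A <- cbind(rep(1, 3), c(0, 1, 2), c(0.5, 1, 2))
  B <- cbind(c(0, 1, 2), rep(4, 3), c(2, 1, 0))
  co <- cohort(list(mk("a", "s1", A), mk("b", "s2", B)))
  dd <- drop_degenerate_features(co)
  expect_identical(dd$feature_mask, c(FALSE, FALSE, TRUE))
  expect_identical(ncol(dd$cohort$bags[[1]]$features), 1L)

  # no constant features -> identity mask
  co2 <- tiny_cohort()
  expect_true(all(drop_degenerate_features(co2)$feature_mask))

  # all features degenerate -> unusable
  C1 <- matrix(1, 3, 2)
  expect_error(drop_degenerate_features(cohort(list(mk("a", "s1", C1)))),
               "degenerate")
})

test_that("standardize_features matches hand arithmetic", {
  X <- matrix(c(1, 3, 5, 7), 4, 1)
  st <- standardize_features(X, c("A", "A", "B", "B"))
  expect_equal(st$alpha_hat, 4)
  expect_equal(st$sigma_hat, 1)  # pooled var = (1+1+1+1)/4
  expect_equal(as.numeric(st$Z), c(-3, -1, 1, 3))

  # degenerate pooled variance errors
  expect_error(standardize_features(matrix(c(0, 0, 2, 2), 4, 1),
                                    c("A", "A", "B", "B")),
               "zero pooled variance")
  expect_error(standardize_features(matrix(1:4, 4, 1), c("A", "A", "A", "B")),
               "< 2 samples")

  # one-batch reduction: Z centered, sigma = population sd of the batch
  set.seed(1)
  X1 <- matrix(rnorm(20), 10, 2)
  s1 <- standardize_features(X1, rep("A", 10))
  expect_equal(colMeans(s1$Z), c(0, 0))
  expect_equal(s1$sigma_hat, sqrt(colMeans(sweep(X1, 2, colMeans(X1))^2)))
})

test_that("moments_hyperpriors solves the inverse-gamma moment equations", {
  h <- moments_hyperpriors(c(-1, 0, 1), c(0.5, 1.0, 1.5))
  expect_equal(h$gamma_bar, 0)
  expect_equal(h$tau2, 1)            # sample variance of {-1,0,1}
  vbar <- 1; s2 <- 0.25              # sample variance of {0.5,1,1.5}
  expect_equal(h$lambda_hat, (vbar^2 + 2 * s2) / s2)  # = 6
  expect_equal(h$theta_hat, (vbar^3 + vbar * s2) / s2)  # = 5
  # the estimates satisfy the two moment equations
  expect_equal(h$theta_hat / (h$lambda_hat - 1), vbar)
  expect_equal(h$theta_hat^2 / ((h$lambda_hat - 1)^2 * (h$lambda_hat - 2)),
               s2)

  flat <- moments_hyperpriors(c(0, 1, 2), c(1, 1, 1))
  expect_true(flat$flat_delta_prior)
})

test_that("parametric EB shrinkage: limits and fixed-point oracle", {
  set.seed(42)
  ni <- 4; D <- 2
  Z <- matrix(rnorm(ni * D, 0, 1.3), ni, D)
  gh <- colMeans(Z)
  d2h <- apply(Z, 2, var)
  # tau2 -> Inf: no shrinkage of gamma
  hyp_inf <- list(gamma_bar = 10, tau2 = 1e12, lambda_hat = 3, theta_hat = 2,
                  flat_delta_prior = FALSE)
  sh <- eb_shrink_parametric(Z, gh, d2h, hyp_inf, tol = 1e-10)
  expect_equal(sh$gamma_star, gh, tolerance = 1e-6)
  # tau2 = 0: full shrinkage to gamma_bar
  hyp0 <- list(gamma_bar = 0.7, tau2 = 0, lambda_hat = 3, theta_hat = 2,
               flat_delta_prior = FALSE)
  sh0 <- eb_shrink_parametric(Z, gh, d2h, hyp0, tol = 1e-10)
  expect_equal(sh0$gamma_star, rep(0.7, D))

  # toy vs independently coded fixed point iterated to 1e-12
  hyp <- list(gamma_bar = 0.2, tau2 = 0.5, lambda_hat = 4, theta_hat = 3,
              flat_delta_prior = FALSE)
  sh2 <- eb_shrink_parametric(Z, gh, d2h, hyp, tol = 1e-12, max_iter = 10000)
  bf <- bf_eb_parametric(Z, gh, d2h, 0.2, 0.5, 4, 3)
  expect_equal(sh2$gamma_star, bf$gamma_star, tolerance = 1e-8)
  expect_equal(sh2$delta_star2, bf$delta_star2, tolerance = 1e-8)
})

test_that("non-parametric EB matches brute force and is order-invariant", {
  # D = 2 with identical columns: single leave-one-out candidate
  set.seed(7)
  z <- rnorm(6)
  Z2 <- matrix(c(z, z), ncol = 2)
  gh2 <- colMeans(Z2); d2h2 <- apply(Z2, 2, var)
  sh2 <- eb_shrink_nonparametric(Z2, gh2, d2h2)
  expect_equal(sh2$gamma_star, gh2[2:1])
  expect_equal(sh2$delta_star2, d2h2[2:1])

  Z <- matrix(rnorm(15, 0, 1.1), 5, 3)
  gh <- colMeans(Z); d2h <- apply(Z, 2, var)
  sh <- eb_shrink_nonparametric(Z, gh, d2h)
  bf <- bf_eb_nonparametric(Z, gh, d2h)
  expect_equal(sh$gamma_star, bf$gamma_star, tolerance = 1e-10)
  expect_equal(sh$delta_star2, bf$delta_star2, tolerance = 1e-10)

  perm <- c(3, 1, 2)
  shp <- eb_shrink_nonparametric(Z[, perm], gh[perm], d2h[perm])
  expect_equal(shp$gamma_star, sh$gamma_star[perm])
})

test_that("fit_transform repairs means and variances as per mode", {
  set.seed(10)
  n <- 2000
  X <- rbind(matrix(rnorm(n * 3, 0, 1), n, 3),
             sweep(matrix(rnorm(n * 3, 0, 2), n, 3), 2, c(3, -2, 1), `+`))
  b <- rep(c("A", "B"), each = n)

  fit <- combat_fit_transform(X, b)
  gap_pre <- abs(colMeans(X[b == "A", ]) - colMeans(X[b == "B", ]))
  gap_post <- abs(colMeans(fit$X_star[b == "A", ]) -
                    colMeans(fit$X_star[b == "B", ]))
  expect_true(all(gap_post < 0.01 * gap_pre))
  vr_post <- apply(fit$X_star[b == "A", ], 2, var) /
    apply(fit$X_star[b == "B", ], 2, var)
  expect_true(all(abs(vr_post - 1) < 0.1))
  expect_identical(dim(fit$X_star), dim(X))
  expect_true(all(is.finite(fit$X_star)))

  # additive only: means equalized, variance ratio unchanged within 5%
  fa <- combat_fit_transform(X, b, correction_mode = "additive")
  gap_a <- abs(colMeans(fa$X_star[b == "A", ]) -
                 colMeans(fa$X_star[b == "B", ]))
  expect_true(all(gap_a < 0.01 * gap_pre))
  vr_pre <- apply(X[b == "A", ], 2, var) / apply(X[b == "B", ], 2, var)
  vr_a <- apply(fa$X_star[b == "A", ], 2, var) /
    apply(fa$X_star[b == "B", ], 2, var)
  expect_true(all(abs(vr_a / vr_pre - 1) < 0.05))

  # multiplicative only: variances equalized, mean gap stays
  fm <- combat_fit_transform(X, b, correction_mode = "multiplicative")
  vr_m <- apply(fm$X_star[b == "A", ], 2, var) /
    apply(fm$X_star[b == "B", ], 2, var)
  expect_true(all(abs(vr_m - 1) < 0.1))
  gap_m <- abs(colMeans(fm$X_star[b == "A", ]) -
                 colMeans(fm$X_star[b == "B", ]))
  expect_true(all(gap_m > 0.5 * gap_pre))

  expect_error(combat_fit_transform(X, rep("A", 2 * n)), ">= 2 batches")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(combat_fit_transform(Xna, b), "NaN")
})

test_that("reference batch is immutable and external offsets are removed", {
  set.seed(3)
  Xr <- matrix(rnorm(600, 1, 1), 200, 3)
  # same distribution: negligible adjustment
  Xe <- matrix(rnorm(600, 1, 1), 200, 3)
  res <- combat_apply_reference(Xr, Xe)
  se <- 3 / sqrt(200)  # generous bound on a mean shift under no offset
  expect_true(all(abs(colMeans(res$X_ext_star) - colMeans(Xe)) < se))
  expect_identical(dim(res$X_ext_star), dim(Xe))

  # self-reference: approximately identity
  res2 <- combat_apply_reference(Xr, Xr)
  expect_equal(res2$X_ext_star, Xr, tolerance = 1e-6)

  # known constant offset removed to within Monte-Carlo error
  Xo <- sweep(matrix(rnorm(600, 1, 1), 200, 3), 2, c(2, -1, 0.5), `+`)
  res3 <- combat_apply_reference(Xr, Xo)
  expect_true(all(abs(colMeans(res3$X_ext_star) - colMeans(Xr)) < 4 * se))

  # reference rows unchanged in a direct reference-batch fit
  Xall <- rbind(Xr, Xo)
  bt <- rep(c("R", "E"), each = 200)
  fit <- combat_fit_transform(Xall, bt, reference_batch = "R")
  expect_equal(fit$X_star[bt == "R", ], Xr, tolerance = 1e-10)
  expect_equal(fit$model$gamma_star["R", ], rep(0, 3))
  expect_equal(fit$model$delta_star2["R", ], rep(1, 3))

  expect_error(combat_apply_reference(Xr, Xo[1, , drop = FALSE]),
               ">= 2 samples")
})

test_that("one-batch identity fit returns the input", {
  set.seed(8)
  X <- matrix(rnorm(300, 2, 1.5), 100, 3)
  fit <- combat_fit_transform(X, rep("A", 100), allow_single_batch = TRUE)
  expect_equal(fit$X_star, X, tolerance = 1e-10)
})

test_that("harmonize_cohort recovers injected site effects", {
  cfg <- simulation_config(n_sites = 3, slides_per_site = 5,
                           patches_per_slide = 200, n_features = 12,
                           additive_prior = list(mu = c(-2, 0, 2), tau2 = 1),
                           multiplicative_prior = list(lambda = 5, theta = 4),
                           seed = 21)
  sim <- simulate_cohort(cfg)
  h <- harmonize_cohort(sim$cohort)
  # gamma* (converted to raw units) correlates with the centered truth
  gt <- sim$truth$gamma_true
  gt_c <- sweep(gt, 2, colMeans(gt))  # equal batch sizes -> unweighted center
  for (i in 1:3) {
    g_raw <- h$model$sigma_hat * h$model$gamma_star[sprintf("site_%02d", i), ]
    expect_gt(cor(g_raw, gt_c[i, ]), 0.9)
  }
  # delta*^2 tracks the identifiable (relative) multiplicative truth:
  # pooled standardization divides feature g by mean_i delta2_ig
  dt <- sim$truth$delta2_true
  dt_rel <- sweep(dt, 2, colMeans(dt), `/`)
  for (i in 1:3)
    expect_gt(cor(h$model$delta_star2[sprintf("site_%02d", i), ],
                  dt_rel[i, ]), 0.9)
})

test_that("nonparametric prior mode also removes batch structure", {
  # the empirical prior needs a reasonably dense feature set to be useful:
  # each feature borrows the estimates of its (leave-one-out) neighbours
  set.seed(12)
  n <- 300; D <- 40
  off <- rnorm(D, 0, 1.2)
  X <- rbind(matrix(rnorm(n * D, 0, 1), n, D),
             sweep(matrix(rnorm(n * D, 0, 1.4), n, D), 2, off, `+`))
  b <- rep(c("A", "B"), each = n)
  fit <- combat_fit_transform(X, b, prior_mode = "nonparametric")
  gap_pre <- abs(colMeans(X[b == "A", ]) - colMeans(X[b == "B", ]))
  gap_post <- abs(colMeans(fit$X_star[b == "A", ]) -
                    colMeans(fit$X_star[b == "B", ]))
  expect_lt(mean(gap_post), 0.5 * mean(gap_pre))
})
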