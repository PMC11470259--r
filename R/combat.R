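#' Drop features that are constant within any slide
#'
#' A feature whose within-slide variance is exactly zero for at least one
#' slide is removed dataset-wide (degenerate extractor channels break the
#' scale model). The mask is recorded so external data can be aligned to the
#' same retained columns.
#'
#' @param cohort a [cohort()]; every bag must have >= 2 patches.
#' @return list with `feature_mask` (logical over original columns, TRUE =
#'   retained) and `cohort` (masked).
#' @export
drop_degenerate_features <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  D <- ncol(cohort$bags[[1]]$features)
  bad <- rep(FALSE, D)
  for (b in cohort$bags) {
    if (nrow(b$features) < 2L)
      stop("drop_degenerate_features: slide ", b$slide_id, " has < 2 patches")
    v <- colvar_pop(b$features)
    bad <- bad | (v == 0)
  }
  mask <- !bad
  if (!any(mask))
    stop("drop_degenerate_features: all features degenerate; input unusable")
  list(feature_mask = mask,
       cohort = if (all(mask)) cohort else mask_features(cohort, mask))
}

#' Standardize a pooled feature matrix across batches
#'
#' Computes the batch-size-weighted grand mean
#' \eqn{\hat\alpha_g = \sum_i (n_i/N)\,\bar{Y}_{i\cdot g}}, the pooled residual
#' variance after batch-mean removal
#' \eqn{\hat\sigma_g^2 = N^{-1}\sum_{ij}(Y_{ijg}-\bar{Y}_{i\cdot g})^2}
#' (population denominator), and the standardized data
#' \eqn{Z = (Y - \hat\alpha_g)/\hat\sigma_g}.
#'
#' @param X samples x D numeric matrix (rows are pooled patches).
#' @param batches length-nrow(X) batch labels.
#' @return list `Z`, `alpha_hat`, `sigma_hat`, `batch_levels`, `n_per_batch`.
#' @export
standardize_features <- function(X, batches) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("standardize_features: NaN/NA in X")
  batches <- as.character(batches)
  stopifnot(length(batches) == nrow(X))
  lev <- unique(batches)
  n_i <- vapply(lev, function(l) sum(batches == l), integer(1))
  if (any(n_i < 2L))
    stop("standardize_features: batch with < 2 samples: ",
         paste(lev[n_i < 2L], collapse = ", "))
  N <- nrow(X)
  bm <- matrix(NA_real_, length(lev), ncol(X), dimnames = list(lev, NULL))
  for (l in lev) bm[l, ] <- colMeans(X[batches == l, , drop = FALSE])
  alpha_hat <- as.numeric(crossprod(n_i / N, bm))
  R <- X - bm[batches, , drop = FALSE]
  sigma2 <- colSums(R^2) / N
  if (any(sigma2 == 0))
    stop("standardize_features: zero pooled variance; run ",
         "drop_degenerate_features first (features: ",
         paste(which(sigma2 == 0), collapse = ", "), ")")
  sigma_hat <- sqrt(sigma2)
  Z <- sweep(sweep(X, 2L, alpha_hat), 2L, sigma_hat, `/`)
  list(Z = Z, alpha_hat = alpha_hat, sigma_hat = sigma_hat,
       batch_levels = lev, n_per_batch = n_i)
}

#' Method-of-moments hyperprior estimates for one batch
#'
#' Given the per-feature additive effect estimates `gamma_hat_i` and
#' multiplicative estimates `delta2_hat_i` of batch i, returns the empirical
#' prior: \eqn{\bar\gamma_i}, \eqn{\hat\tau_i^2} (across-feature mean and
#' sample variance of gamma_hat), and the inverse-gamma parameters solving
#' mean \eqn{= \Theta/(\lambda-1)} and variance
#' \eqn{= \Theta^2/((\lambda-1)^2(\lambda-2))}:
#' \eqn{\hat\lambda = (\bar V^2 + 2S^2)/S^2},
#' \eqn{\hat\Theta = (\bar V^3 + \bar V S^2)/S^2} with \eqn{\bar V, S^2} the
#' across-feature mean and sample variance of delta2_hat.
#'
#' When `S^2 = 0` the inverse-gamma prior is degenerate; the fit falls back to
#' a flat prior (lambda_hat = theta_hat = NA) under which delta2 is not
#' shrunk.
#'
#' @param gamma_hat_i length-D numeric vector.
#' @param delta2_hat_i length-D positive vector.
#' @return list `gamma_bar`, `tau2`, `lambda_hat`, `theta_hat`,
#'   `flat_delta_prior` (logical).
#' @export
moments_hyperpriors <- function(gamma_hat_i, delta2_hat_i) {
  D <- length(gamma_hat_i)
  if (D < 3L) stop("moments_hyperpriors: need D >= 3 features")
  gamma_bar <- mean(gamma_hat_i)
  tau2 <- stats::var(gamma_hat_i)
  vbar <- mean(delta2_hat_i)
  s2 <- stats::var(delta2_hat_i)
  if (s2 == 0) {
    return(list(gamma_bar = gamma_bar, tau2 = tau2,
                lambda_hat = NA_real_, theta_hat = NA_real_,
                flat_delta_prior = TRUE))
  }
  list(gamma_bar = gamma_bar, tau2 = tau2,
       lambda_hat = (vbar^2 + 2 * s2) / s2,
       theta_hat = (vbar^3 + vbar * s2) / s2,
       flat_delta_prior = FALSE)
}

#' Parametric empirical-Bayes shrinkage for one batch
#'
#' Iterates the coupled posterior-mean updates from the starting values
#' \eqn{(\hat\gamma, \hat\delta^2)}:
#' \deqn{\gamma^*_g \leftarrow \frac{n_i \hat\tau^2 \hat\gamma_g +
#'   \delta^{*2}_g \bar\gamma}{n_i \hat\tau^2 + \delta^{*2}_g},\qquad
#'   \delta^{*2}_g \leftarrow \frac{\hat\Theta + \tfrac12 \sum_j (Z_{jg} -
#'   \gamma^*_g)^2}{n_i/2 + \hat\lambda - 1},}
#' until the largest absolute relative change falls below `tol` or `max_iter`
#' is reached (then the last iterate is returned with `converged = FALSE`).
#'
#' With a flat delta prior (degenerate moments), delta2 is left at its
#' starting value and only gamma is shrunk.
#'
#' @param Z_batch n_i x D standardized data of the batch.
#' @param gamma_hat_i,delta2_hat_i per-feature starting estimates.
#' @param hyper_i output of [moments_hyperpriors()].
#' @param tol relative-change stopping tolerance.
#' @param max_iter iteration cap.
#' @return list `gamma_star`, `delta_star2`, `converged`, `n_iter`.
#' @export
eb_shrink_parametric <- function(Z_batch, gamma_hat_i, delta2_hat_i, hyper_i,
                                 tol = 1e-4, max_iter = 500L) {
  n_i <- nrow(Z_batch)
  if (n_i < 2L) stop("eb_shrink_parametric: batch with < 2 samples")
  g <- gamma_hat_i
  d2 <- delta2_hat_i
  ok <- FALSE
  it <- 0L
  # sum of squares about gamma* decomposes as resid SS + n (gamma_hat-gamma*)^2
  ss0 <- colSums(sweep(Z_batch, 2L, gamma_hat_i)^2)
  for (it in seq_len(max_iter)) {
    g_new <- (n_i * hyper_i$tau2 * gamma_hat_i + d2 * hyper_i$gamma_bar) /
      (n_i * hyper_i$tau2 + d2)
    d2_new <- if (hyper_i$flat_delta_prior) d2 else
      (hyper_i$theta_hat + 0.5 * (ss0 + n_i * (gamma_hat_i - g_new)^2)) /
        (n_i / 2 + hyper_i$lambda_hat - 1)
    change <- max(abs(g_new - g) / pmax(abs(g), 1e-12),
                  abs(d2_new - d2) / pmax(abs(d2), 1e-12))
    g <- g_new
    d2 <- d2_new
    if (change < tol) { ok <- TRUE; break }
  }
  if (any(!is.finite(d2)) || any(d2 <= 0))
    stop("eb_shrink_parametric: non-positive or non-finite delta_star2")
  list(gamma_star = g, delta_star2 = d2, converged = ok, n_iter = it)
}

#' Non-parametric empirical-Bayes shrinkage for one batch
#'
#' Uses the empirical distribution of the other features' estimates as the
#' prior: for feature g, every other feature g' contributes its
#' \eqn{(\hat\gamma_{g'}, \hat\delta^2_{g'})} weighted by the Gaussian
#' likelihood of batch i's data for feature g under those parameters
#' (leave-one-out across features). Weights are computed in log-space and
#' renormalized, so simultaneous underflow of all candidates is handled.
#' Cost is O(D^2 n_i).
#'
#' @inheritParams eb_shrink_parametric
#' @return list `gamma_star`, `delta_star2`.
#' @export
eb_shrink_nonparametric <- function(Z_batch, gamma_hat_i, delta2_hat_i) {
  D <- length(gamma_hat_i)
  if (D < 2L) stop("eb_shrink_nonparametric: need D >= 2")
  n_i <- nrow(Z_batch)
  gamma_star <- numeric(D)
  delta_star2 <- numeric(D)
  for (g in seq_len(D)) {
    z <- Z_batch[, g]
    others <- setdiff(seq_len(D), g)
    # log sum_j N(z_j; gamma_g', delta2_g') for each candidate g'
    sz <- sum(z); sz2 <- sum(z^2)
    gm <- gamma_hat_i[others]; dv <- delta2_hat_i[others]
    logw <- -0.5 * n_i * log(2 * pi * dv) -
      (sz2 - 2 * gm * sz + n_i * gm^2) / (2 * dv)
    logw <- logw - max(logw)
    w <- exp(logw)
    tw <- sum(w)
    if (!is.finite(tw) || tw <= 0)
      stop("eb_shrink_nonparametric: degenerate weights for feature ", g)
    w <- w / tw
    gamma_star[g] <- sum(w * gm)
    delta_star2[g] <- sum(w * dv)
  }
  list(gamma_star = gamma_star, delta_star2 = delta_star2)
}

#' Fit ComBat on a pooled matrix and return the corrected data
#'
#' Full empirical-Bayes pipeline: standardize, estimate per-batch per-feature
#' additive effects (within-batch means of Z) and multiplicative effects
#' (within-batch sample variances of Z), estimate hyperpriors by the method of
#' moments, shrink with parametric or non-parametric priors, and adjust
#' \deqn{Y^*_{ijg} = \hat\sigma_g\,\frac{Z_{ijg} - \gamma^*_{ig}}
#'   {\delta^*_{ig}} + \hat\alpha_g.}
#' `correction_mode = "additive"` forces \eqn{\delta^{*2} \equiv 1} in the
#' adjustment; `"multiplicative"` forces \eqn{\gamma^* \equiv 0}.
#'
#' When `reference_batch` is given, standardization statistics are taken from
#' the reference batch alone, the reference rows are returned unchanged
#' (its gamma* row is 0 and delta*2 row is 1), and only the other batches are
#' adjusted toward it.
#'
#' @param X samples x D matrix (degenerate features already dropped).
#' @param batches per-row batch labels; >= 2 batches of >= 2 samples each,
#'   unless `allow_single_batch = TRUE` (then the fit is an identity
#'   correction, provided for pipeline composition).
#' @param prior_mode `"parametric"` or `"nonparametric"`.
#' @param correction_mode `"both"`, `"additive"` or `"multiplicative"`.
#' @param reference_batch optional batch label to anchor to.
#' @param tol,max_iter parametric EB fixed-point controls.
#' @param allow_single_batch permit a one-batch identity fit.
#' @param feature_mask optional logical mask over original columns recorded in
#'   the model for downstream alignment.
#' @return list with `model` (a `combat_model`) and `X_star` (same shape as
#'   `X`).
#' @export
combat_fit_transform <- function(X, batches,
                                 prior_mode = c("parametric", "nonparametric"),
                                 correction_mode = c("both", "additive",
                                                     "multiplicative"),
                                 reference_batch = NULL,
                                 tol = 1e-4, max_iter = 500L,
                                 allow_single_batch = FALSE,
                                 feature_mask = NULL) {
  prior_mode <- match.arg(prior_mode)
  correction_mode <- match.arg(correction_mode)
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("combat_fit_transform: NaN in X")
  batches <- as.character(batches)
  lev <- unique(batches)
  if (length(lev) < 2L && !allow_single_batch)
    stop("combat_fit_transform: >= 2 batches required ",
         "(set allow_single_batch = TRUE for an identity fit)")
  if (!is.null(reference_batch) && !reference_batch %in% lev)
    stop("combat_fit_transform: unknown reference batch ", reference_batch)

  if (is.null(reference_batch)) {
    std <- standardize_features(X, batches)
  } else {
    ref_rows <- batches == reference_batch
    if (sum(ref_rows) < 2L)
      stop("combat_fit_transform: reference batch has < 2 samples")
    Xr <- X[ref_rows, , drop = FALSE]
    alpha_hat <- colMeans(Xr)
    sigma2 <- colvar_pop(Xr)
    if (any(sigma2 == 0))
      stop("combat_fit_transform: zero variance in reference batch")
    sigma_hat <- sqrt(sigma2)
    n_i <- vapply(lev, function(l) sum(batches == l), integer(1))
    if (any(n_i < 2L))
      stop("combat_fit_transform: batch with < 2 samples")
    std <- list(Z = sweep(sweep(X, 2L, alpha_hat), 2L, sigma_hat, `/`),
                alpha_hat = alpha_hat, sigma_hat = sigma_hat,
                batch_levels = lev, n_per_batch = n_i)
  }

  D <- ncol(X)
  B <- length(lev)
  gamma_hat <- matrix(NA_real_, B, D, dimnames = list(lev, NULL))
  delta2_hat <- matrix(NA_real_, B, D, dimnames = list(lev, NULL))
  for (l in lev) {
    Zb <- std$Z[batches == l, , drop = FALSE]
    gamma_hat[l, ] <- colMeans(Zb)
    # sample (n-1) denominator in the standard fit; population denominator in
    # the reference-anchored fit so that aligning a batch to itself is exactly
    # the identity (the reference standardization already uses N)
    delta2_hat[l, ] <- if (is.null(reference_batch)) colvar_sample(Zb)
                       else colvar_pop(Zb)
  }

  gamma_star <- gamma_hat
  delta_star2 <- delta2_hat
  hyper <- vector("list", B)
  names(hyper) <- lev
  converged <- stats::setNames(rep(TRUE, B), lev)
  for (l in lev) {
    if (!is.null(reference_batch) && l == reference_batch) {
      gamma_star[l, ] <- 0
      delta_star2[l, ] <- 1
      next
    }
    if (length(lev) == 1L && allow_single_batch) {
      # one batch: nothing to correct between batches, the fit is an identity
      gamma_star[l, ] <- 0
      delta_star2[l, ] <- 1
      next
    }
    if (prior_mode == "parametric") {
      hyper[[l]] <- moments_hyperpriors(gamma_hat[l, ], delta2_hat[l, ])
      sh <- eb_shrink_parametric(std$Z[batches == l, , drop = FALSE],
                                 gamma_hat[l, ], delta2_hat[l, ],
                                 hyper[[l]], tol = tol, max_iter = max_iter)
      converged[l] <- sh$converged
    } else {
      sh <- eb_shrink_nonparametric(std$Z[batches == l, , drop = FALSE],
                                    gamma_hat[l, ], delta2_hat[l, ])
    }
    gamma_star[l, ] <- sh$gamma_star
    delta_star2[l, ] <- sh$delta_star2
  }

  g_adj <- gamma_star
  d_adj <- delta_star2
  if (correction_mode == "additive") d_adj[] <- 1
  if (correction_mode == "multiplicative") g_adj[] <- 0

  Zs <- (std$Z - g_adj[batches, , drop = FALSE]) /
    sqrt(d_adj[batches, , drop = FALSE])
  X_star <- sweep(sweep(Zs, 2L, std$sigma_hat, `*`), 2L, std$alpha_hat, `+`)
  dimnames(X_star) <- dimnames(X)

  model <- structure(list(
    alpha_hat = std$alpha_hat, sigma_hat = std$sigma_hat,
    gamma_star = gamma_star, delta_star2 = delta_star2,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    hyper = hyper, batch_levels = lev, n_per_batch = std$n_per_batch,
    feature_mask = feature_mask %||% rep(TRUE, D),
    prior_mode = prior_mode, correction_mode = correction_mode,
    reference_batch = reference_batch, converged = converged),
    class = "combat_model")
  list(model = model, X_star = X_star)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf(
    "<combat_model> %d batches, D=%d, prior=%s, mode=%s%s\n",
    length(x$batch_levels), length(x$alpha_hat), x$prior_mode,
    x$correction_mode,
    if (is.null(x$reference_batch)) "" else
      paste0(", reference=", x$reference_batch)))
  invisible(x)
}

#' Align an external matrix to a harmonized reference space
#'
#' Runs a two-batch ComBat fit on `[X_reference; X_ext]` anchored at the
#' reference: standardization statistics come from the reference batch, the
#' reference rows are returned unchanged, and only the external batch is
#' adjusted. This is how a model trained on a harmonized cohort is deployed on
#' external data.
#'
#' @param X_reference the batch-corrected training matrix (defines the space).
#' @param X_ext external samples x D matrix, same retained features.
#' @param prior_mode,correction_mode,tol,max_iter passed to
#'   [combat_fit_transform()].
#' @return list `X_ext_star` (same shape as `X_ext`) and `model`.
#' @export
combat_apply_reference <- function(X_reference, X_ext,
                                   prior_mode = "parametric",
                                   correction_mode = "both",
                                   tol = 1e-4, max_iter = 500L) {
  X_reference <- as.matrix(X_reference)
  X_ext <- as.matrix(X_ext)
  if (ncol(X_reference) != ncol(X_ext))
    stop("combat_apply_reference: feature dimension mismatch")
  if (nrow(X_ext) < 2L)
    stop("combat_apply_reference: external batch needs >= 2 samples")
  Xall <- rbind(X_reference, X_ext)
  batches <- rep(c("__reference__", "__external__"),
                 c(nrow(X_reference), nrow(X_ext)))
  fit <- combat_fit_transform(Xall, batches, prior_mode = prior_mode,
                              correction_mode = correction_mode,
                              reference_batch = "__reference__",
                              tol = tol, max_iter = max_iter)
  list(X_ext_star = fit$X_star[batches == "__external__", , drop = FALSE],
       model = fit$model)
}

#' Harmonize a cohort with site as the batch variable
#'
#' Cohort-level front end to [combat_fit_transform()]: drops degenerate
#' features, pools all patches of all slides (samples = patches, batch = the
#' slide's site), fits ComBat once over the whole cohort, and re-bags the
#' corrected patches.
#'
#' @param cohort a [cohort()].
#' @param prior_mode,correction_mode,tol,max_iter see
#'   [combat_fit_transform()].
#' @return list `cohort` (corrected, masked to retained features), `model`,
#'   `feature_mask`.
#' @export
harmonize_cohort <- function(cohort, prior_mode = "parametric",
                             correction_mode = "both",
                             tol = 1e-4, max_iter = 500L) {
  dd <- drop_degenerate_features(cohort)
  pooled <- pool_patches(dd$cohort)
  fit <- combat_fit_transform(pooled$X, pooled$site, prior_mode = prior_mode,
                              correction_mode = correction_mode,
                              tol = tol, max_iter = max_iter,
                              allow_single_batch = length(unique(pooled$site)) == 1L,
                              feature_mask = dd$feature_mask)
  out <- repool_patches(dd$cohort, fit$X_star)
  out$provenance$combat <- list(prior_mode = prior_mode,
                                correction_mode = correction_mode)
  list(cohort = out, model = fit$model, feature_mask = dd$feature_mask)
}
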