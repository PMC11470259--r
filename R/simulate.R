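#' Specify a synthetic-attribute
#'
#' Describes one categorical slide-level attribute of a simulated cohort: how
#' many classes it has, which feature columns carry its signal and with what
#' per-class mean shift, and how strongly the class is confounded with the
#' site label.
#'
#' @param name attribute name.
#' @param n_classes number of classes (>= 2).
#' @param shift either an `n_classes x D` matrix of per-class mean-shift
#'   vectors, or a list of per-class numeric length-D vectors. Class 1 is
#'   conventionally the unshifted baseline but this is not enforced.
#' @param rho site-confounding strength in `[0, 1]`: 0 makes the class
#'   independent of site, 1 makes it a deterministic function of site via
#'   `site_map`.
#' @param site_map optional integer vector mapping site index -> class index;
#'   default `((site - 1) %% n_classes) + 1`.
#' @return an `attribute_spec` list.
#' @export
attribute_spec <- function(name, n_classes, shift, rho = 0, site_map = NULL) {
  stopifnot(n_classes >= 2, rho >= 0, rho <= 1)
  if (is.list(shift)) shift <- do.call(rbind, shift)
  shift <- as.matrix(shift)
  if (nrow(shift) != n_classes)
    stop("attribute_spec: shift needs one row per class")
  structure(list(name = name, n_classes = as.integer(n_classes),
                 shift = shift, rho = rho, site_map = site_map),
            class = "attribute_spec")
}

#' Configuration for the synthetic cohort generator
#'
#' Encodes the generative model under which patch embeddings are simulated:
#' for slide j of site i, feature g,
#' \deqn{Y_{ijg} = \alpha_g + s_g(\mathrm{class}(j)) + \gamma_{ig} +
#'       \delta_{ig}\,\varepsilon,\quad \varepsilon \sim N(0, \sigma_g^2),}
#' with additive site effects \eqn{\gamma_{ig} \sim N(\mu_i, \tau_i^2)} and
#' multiplicative site effects
#' \eqn{\delta_{ig}^2 \sim \mathrm{InvGamma}(\lambda_i, \Theta_i)} drawn once
#' per (site, feature). This is exactly the location-scale model that ComBat
#' assumes, plus an additive slide-level class signal on a feature subset.
#'
#' @param n_sites number of sites (batches), >= 2 when any attribute has
#'   `rho > 0`.
#' @param slides_per_site slides simulated per site.
#' @param patches_per_slide either a single integer or a length-2 range from
#'   which per-slide patch counts are drawn uniformly.
#' @param n_features embedding dimension D (>= 2).
#' @param grand_mean length-D vector `alpha_g` (or scalar, recycled).
#' @param noise_scale length-D positive vector `sigma_g` (or scalar).
#' @param additive_prior list with per-site numeric vectors `mu` (length
#'   n_sites) and `tau2` (>= 0).
#' @param multiplicative_prior list with per-site vectors `lambda` (> 2, so
#'   the prior variance of delta^2 is finite) and `theta` (> 0). Setting
#'   `lambda = Inf` degenerates the prior to `delta2 == 1`.
#' @param attributes list of [attribute_spec()] objects.
#' @param artifact_fraction fraction of slides receiving an artifact region
#'   (used by [inject_artifact_regions()]).
#' @param artifact_shift scalar or length-D offset added to artifact patches.
#' @param seed master seed; all randomness is derived from it through
#'   independent per-purpose streams.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(n_sites, slides_per_site, patches_per_slide,
                              n_features,
                              grand_mean = 0, noise_scale = 1,
                              additive_prior = list(mu = rep(0, n_sites),
                                                    tau2 = rep(1, n_sites)),
                              multiplicative_prior = list(
                                lambda = rep(Inf, n_sites),
                                theta = rep(1, n_sites)),
                              attributes = list(),
                              artifact_fraction = 0, artifact_shift = 0,
                              seed = 1L) {
  D <- as.integer(n_features)
  if (D < 2L) stop("simulation_config: n_features must be >= 2")
  grand_mean <- rep_len(as.numeric(grand_mean), D)
  noise_scale <- rep_len(as.numeric(noise_scale), D)
  if (!all(is.finite(grand_mean)) || !all(is.finite(noise_scale)))
    stop("simulation_config: non-finite grand_mean/noise_scale")
  if (any(noise_scale <= 0)) stop("simulation_config: noise_scale must be > 0")
  ap <- lapply(additive_prior, function(v) rep_len(as.numeric(v), n_sites))
  mp <- lapply(multiplicative_prior,
               function(v) rep_len(as.numeric(v), n_sites))
  if (any(!is.finite(ap$mu)) || any(!is.finite(ap$tau2)) || any(ap$tau2 < 0))
    stop("simulation_config: invalid additive prior")
  if (any(mp$lambda <= 2))
    stop("simulation_config: multiplicative prior needs lambda > 2")
  if (any(!is.finite(mp$theta)) || any(mp$theta <= 0))
    stop("simulation_config: multiplicative prior needs finite theta > 0")
  if (length(patches_per_slide) == 1L)
    patches_per_slide <- rep(patches_per_slide, 2L)
  if (any(patches_per_slide < 1L) ||
      patches_per_slide[2] < patches_per_slide[1])
    stop("simulation_config: invalid patches_per_slide range")
  for (a in attributes) {
    if (!inherits(a, "attribute_spec")) stop("attributes must be attribute_spec")
    if (ncol(a$shift) != D)
      stop("simulation_config: shift vectors must have length D for ", a$name)
    if (a$rho > 0 && n_sites < 2L)
      stop("simulation_config: rho > 0 requires n_sites >= 2")
  }
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop("simulation_config: artifact_fraction outside [0,1]")
  structure(list(n_sites = as.integer(n_sites),
                 slides_per_site = as.integer(slides_per_site),
                 patches_per_slide = as.integer(patches_per_slide),
                 n_features = D, grand_mean = grand_mean,
                 noise_scale = noise_scale,
                 additive_prior = ap, multiplicative_prior = mp,
                 attributes = attributes,
                 artifact_fraction = artifact_fraction,
                 artifact_shift = rep_len(as.numeric(artifact_shift), D),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# draw delta^2 ~ InvGamma(lambda, theta); lambda = Inf degenerates to 1
rinvgamma2 <- function(n, lambda, theta) {
  if (!is.finite(lambda)) return(rep(1, n))
  theta / stats::rgamma(n, shape = lambda, rate = 1)
}

#' Simulate a cohort of patch-embedding bags with known ground truth
#'
#' Draws site effects from their priors, assigns per-slide attribute classes
#' with site-conditional probabilities
#' \eqn{P(c \mid i) = \rho\,[c = \mathrm{map}(i)] + (1-\rho)/C}, and generates
#' patch embeddings under the location-scale model documented in
#' [simulation_config()]. Deterministic given `config$seed`. Artifact regions
#' are injected afterwards by [inject_artifact_regions()] when
#' `artifact_fraction > 0`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `cohort` (a [cohort()]) and `truth` (a list with
#'   `gamma_true`, `delta2_true` (sites x D), `slide_site`,
#'   `slide_attribute_labels`, `signal_features`, `artifact_mask`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  D <- config$n_features
  ns <- config$n_sites
  nsl <- config$slides_per_site
  seeds <- split_seed(config$seed, 4L)  # effects, labels, noise, artifacts

  # site effects, one draw per (site, feature)
  eff <- with_seed(seeds[1], {
    gamma <- matrix(NA_real_, ns, D)
    delta2 <- matrix(NA_real_, ns, D)
    for (i in seq_len(ns)) {
      gamma[i, ] <- stats::rnorm(D, config$additive_prior$mu[i],
                                 sqrt(config$additive_prior$tau2[i]))
      delta2[i, ] <- rinvgamma2(D, config$multiplicative_prior$lambda[i],
                                config$multiplicative_prior$theta[i])
    }
    list(gamma = gamma, delta2 = delta2)
  })

  site_of_slide <- rep(seq_len(ns), each = nsl)
  n_slides <- ns * nsl

  # attribute classes, site-conditional
  labels <- with_seed(seeds[2], {
    out <- list()
    for (a in config$attributes) {
      map <- a$site_map %||% (((seq_len(ns) - 1L) %% a$n_classes) + 1L)
      cls <- integer(n_slides)
      for (s in seq_len(n_slides)) {
        i <- site_of_slide[s]
        p <- rep((1 - a$rho) / a$n_classes, a$n_classes)
        p[map[i]] <- p[map[i]] + a$rho
        cls[s] <- sample.int(a$n_classes, 1L, prob = p)
      }
      out[[a$name]] <- cls
    }
    out
  })

  # patch counts and embeddings
  pps <- config$patches_per_slide
  bags <- vector("list", n_slides)
  slide_id <- sprintf("slide_%03d", seq_len(n_slides))
  with_seed(seeds[3], {
    counts <- if (pps[1] == pps[2]) rep(pps[1], n_slides)
              else sample(seq(pps[1], pps[2]), n_slides, replace = TRUE)
    for (s in seq_len(n_slides)) {
      i <- site_of_slide[s]
      P <- counts[s]
      mu_row <- config$grand_mean + eff$gamma[i, ]
      for (a in config$attributes) {
        mu_row <- mu_row + a$shift[labels[[a$name]][s], ]
      }
      sd_row <- sqrt(eff$delta2[i, ]) * config$noise_scale
      X <- matrix(stats::rnorm(P * D), P, D)
      X <- sweep(X, 2L, sd_row, `*`)
      X <- sweep(X, 2L, mu_row, `+`)
      ncols <- ceiling(sqrt(P))
      coords <- cbind((seq_len(P) - 1L) %/% ncols, (seq_len(P) - 1L) %% ncols)
      bags[[s]] <- patch_bag(slide_id[s], sprintf("site_%02d", i), X,
                             coords = coords)
    }
  })

  attr_df <- data.frame(slide_id = slide_id, stringsAsFactors = FALSE)
  signal_features <- list()
  for (a in config$attributes) {
    attr_df[[a$name]] <- paste0("class_", labels[[a$name]])
    signal_features[[a$name]] <- which(colSums(abs(a$shift)) > 0)
  }

  co <- cohort(bags, attr_df,
               provenance = list(config = config, seed = config$seed,
                                 package = "combatslide",
                                 version = as.character(
                                   utils::packageVersion("combatslide"))))
  truth <- list(gamma_true = eff$gamma, delta2_true = eff$delta2,
                slide_site = stats::setNames(sprintf("site_%02d",
                                                     site_of_slide), slide_id),
                slide_attribute_labels = labels,
                signal_features = signal_features,
                artifact_mask = lapply(stats::setNames(bags, slide_id),
                                       function(b) rep(FALSE,
                                                       nrow(b$features))))
  out <- list(cohort = co, truth = truth)
  if (config$artifact_fraction > 0) {
    out <- inject_artifact_regions(out$cohort, out$truth, config,
                                   .seed = seeds[4])
  }
  out
}

#' Inject localized artifact regions into simulated slides
#'
#' Emulates localized slide artifacts (pen markings, tissue folds, debris) as
#' a contiguous axis-aligned rectangular block of patches on the slide's grid
#' receiving an extra per-feature offset. A fixed fraction of slides is
#' selected at random; the artifact mask in the truth record is updated.
#'
#' @param cohort a [cohort()] whose bags carry grid coords.
#' @param truth matching truth record from [simulate_cohort()].
#' @param config the [simulation_config()] (uses `artifact_fraction`,
#'   `artifact_shift`, `seed`).
#' @param .seed internal override of the artifact stream seed.
#' @return list `(cohort, truth)` with shifted features and updated masks.
#' @export
inject_artifact_regions <- function(cohort, truth, config, .seed = NULL) {
  frac <- config$artifact_fraction
  if (frac < 0 || frac > 1)
    stop("inject_artifact_regions: artifact_fraction outside [0,1]")
  if (frac == 0) return(list(cohort = cohort, truth = truth))
  if (is.null(cohort$bags[[1]]$coords))
    stop("inject_artifact_regions: patch grid coordinates required")
  seed <- .seed %||% split_seed(config$seed, 4L)[4]
  n_slides <- length(cohort$bags)
  n_pick <- round(frac * n_slides)
  with_seed(seed, {
    picked <- sample.int(n_slides, n_pick)
    for (s in picked) {
      b <- cohort$bags[[s]]
      rows <- b$coords[, 1]; cols <- b$coords[, 2]
      # rectangle spanning roughly half the occupied grid in each dimension
      rr <- range(rows); cr <- range(cols)
      h <- max(1L, floor((rr[2] - rr[1] + 1L) / 2))
      w <- max(1L, floor((cr[2] - cr[1] + 1L) / 2))
      r0 <- if (rr[2] - h >= rr[1]) sample(rr[1]:(rr[2] - h + 1L), 1L) else rr[1]
      c0 <- if (cr[2] - w >= cr[1]) sample(cr[1]:(cr[2] - w + 1L), 1L) else cr[1]
      inblock <- rows >= r0 & rows < r0 + h & cols >= c0 & cols < c0 + w
      if (!any(inblock)) inblock[1] <- TRUE  # degenerate tiny grids
      b$features[inblock, ] <- sweep(b$features[inblock, , drop = FALSE], 2L,
                                     config$artifact_shift, `+`)
      cohort$bags[[s]] <- b
      truth$artifact_mask[[b$slide_id]] <- inblock
    }
  })
  list(cohort = cohort, truth = truth)
}
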