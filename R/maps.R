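#' Per-patch correction distances between raw and harmonized bags
#'
#' Euclidean distance between each patch's raw and corrected embedding; the
#' per-patch magnitude of the batch correction.
#'
#' @param raw_bag,corrected_bag [patch_bag()]s for the same slide with equal
#'   patch count/order and the same retained features.
#' @return non-negative length-P vector.
#' @export
patch_distances <- function(raw_bag, corrected_bag) {
  if (!identical(raw_bag$slide_id, corrected_bag$slide_id))
    stop("patch_distances: bags belong to different slides")
  A <- raw_bag$features; B <- corrected_bag$features
  if (!all(dim(A) == dim(B)))
    stop("patch_distances: shape mismatch (feature masks aligned?)")
  sqrt(rowSums((A - B)^2))
}

#' Build correction maps for every slide of a cohort pair
#'
#' @param raw_cohort cohort before harmonization, masked to the retained
#'   features (see `feature_mask` of [harmonize_cohort()]).
#' @param corrected_cohort harmonized cohort.
#' @return list of `correction_map` objects (slide_id, site, distances,
#'   normalized placeholder, coords).
#' @export
correction_maps <- function(raw_cohort, corrected_cohort) {
  stopifnot(identical(slide_ids(raw_cohort), slide_ids(corrected_cohort)))
  maps <- Map(function(rb, cb) {
    structure(list(slide_id = rb$slide_id, site = rb$site,
                   distance = patch_distances(rb, cb),
                   normalized = NULL, coords = rb$coords),
              class = "correction_map")
  }, raw_cohort$bags, corrected_cohort$bags)
  names(maps) <- slide_ids(raw_cohort)
  maps
}

#' Normalize correction distances within each site
#'
#' Min-max normalization to `[0, 1]` over the pooled distances of all patches
#' of all slides belonging to one site, so maps of slides from the same TSS
#' are on a common scale. A site whose distances are all equal maps to all
#' zeros by convention. `method = "zscore"` standardizes with the pooled site
#' mean/sd instead (not clipped to `[0, 1]`).
#'
#' @param maps list of `correction_map`s from [correction_maps()].
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return the maps with `normalized` filled in.
#' @export
normalize_within_site <- function(maps, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (length(maps) == 0L) stop("normalize_within_site: empty map list")
  sites <- vapply(maps, function(m) m$site, character(1))
  for (s in unique(sites)) {
    idx <- which(sites == s)
    pooled <- unlist(lapply(maps[idx], function(m) m$distance))
    if (method == "minmax") {
      rng <- range(pooled)
      den <- rng[2] - rng[1]
      for (i in idx) {
        maps[[i]]$normalized <- if (den == 0) rep(0, length(maps[[i]]$distance))
                                else (maps[[i]]$distance - rng[1]) / den
      }
    } else {
      mu <- mean(pooled); sd_ <- stats::sd(pooled)
      for (i in idx) {
        maps[[i]]$normalized <- if (sd_ == 0) rep(0, length(maps[[i]]$distance))
                                else (maps[[i]]$distance - mu) / sd_
      }
    }
  }
  maps
}

#' Render a correction map as a patch-grid intensity image
#'
#' Places each patch's normalized correction value at its (row, col) grid
#' cell; cells without a patch are `NA` (rendered transparent). Higher
#' intensity marks stronger correction. Optionally writes a PNG.
#'
#' @param map a `correction_map` with `normalized` filled in (falls back to
#'   raw distances if not normalized) and grid coords present.
#' @param file optional PNG path.
#' @return the 2-D intensity matrix, invisibly when writing a file.
#' @export
render_map <- function(map, file = NULL) {
  if (is.null(map$coords)) stop("render_map: grid coordinates required")
  vals <- map$normalized %||% map$distance
  rows <- map$coords[, 1]; cols <- map$coords[, 2]
  if (any(rows < 0) || any(cols < 0))
    stop("render_map: negative grid coordinates")
  grid <- matrix(NA_real_, max(rows) + 1L, max(cols) + 1L)
  grid[cbind(rows + 1L, cols + 1L)] <- vals
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    graphics::image(t(grid)[, nrow(grid):1, drop = FALSE],
                    col = grDevices::hcl.colors(64, "inferno"),
                    axes = FALSE, useRaster = TRUE,
                    main = sprintf("%s (site %s)", map$slide_id, map$site))
    return(invisible(grid))
  }
  grid
}
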