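#' Construct a patch bag
#'
#' A `patch_bag` is the atomic data unit: one whole-slide image represented by
#' the P x D matrix of patch embeddings produced by some feature extractor,
#' together with the slide's tissue-source-site (TSS) label and, optionally,
#' the (row, col) grid position of every patch.
#'
#' @param slide_id character scalar, unique within a cohort.
#' @param site character scalar; the TSS (batch) label.
#' @param features numeric P x D matrix of patch embeddings; finite.
#' @param coords optional P x 2 integer matrix of 0-based (row, col) grid
#'   positions, unique per slide.
#' @param extractor_tag free-text provenance tag for the feature extractor.
#' @return an object of class `patch_bag`.
#' @export
patch_bag <- function(slide_id, site, features, coords = NULL,
                      extractor_tag = "synthetic") {
  stopifnot(is.character(slide_id), length(slide_id) == 1L,
            length(site) == 1L)
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("patch_bag: bag must contain >= 1 patch")
  if (!all(is.finite(features)))
    stop("patch_bag: non-finite feature values in slide ", slide_id)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "integer"
    if (nrow(coords) != nrow(features) || ncol(coords) != 2L)
      stop("patch_bag: coords must be P x 2")
    if (anyDuplicated(paste(coords[, 1], coords[, 2])))
      stop("patch_bag: duplicate patch coordinates in slide ", slide_id)
  }
  structure(list(slide_id = slide_id, site = as.character(site),
                 features = features, coords = coords,
                 extractor_tag = extractor_tag),
            class = "patch_bag")
}

#' @export
print.patch_bag <- function(x, ...) {
  cat(sprintf("<patch_bag> %s  site=%s  %d patches x %d features%s\n",
              x$slide_id, x$site, nrow(x$features), ncol(x$features),
              if (is.null(x$coords)) "" else "  (grid coords)"))
  invisible(x)
}

#' Construct a cohort of patch bags
#'
#' A `cohort` bundles the per-slide bags with a slide-indexed table of
#' categorical attributes (clinical or genetic labels; missing values carried
#' as an explicit sentinel) and provenance information.
#'
#' @param bags list of [patch_bag()] objects with unique `slide_id`s.
#' @param attributes data.frame with a `slide_id` column and one column per
#'   categorical attribute; one row per bag. Missing values may be `NA` (they
#'   are stored with an explicit sentinel on disk).
#' @param provenance list carrying config, seed, package version.
#' @return an object of class `cohort`.
#' @export
cohort <- function(bags, attributes = NULL, provenance = list()) {
  stopifnot(is.list(bags), length(bags) >= 1L)
  ids <- vapply(bags, function(b) b$slide_id, character(1))
  if (anyDuplicated(ids)) stop("cohort: duplicate slide_ids")
  if (is.null(attributes))
    attributes <- data.frame(slide_id = ids, stringsAsFactors = FALSE)
  if (!"slide_id" %in% names(attributes))
    stop("cohort: attributes needs a slide_id column")
  if (!setequal(attributes$slide_id, ids))
    stop("cohort: attribute rows and bag slide_ids are not bijective")
  attributes <- attributes[match(ids, attributes$slide_id), , drop = FALSE]
  rownames(attributes) <- NULL
  structure(list(bags = bags, attributes = attributes,
                 provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  sites <- site_labels(x)
  cat(sprintf("<cohort> %d slides, %d sites, D=%d, attributes: %s\n",
              length(x$bags), length(unique(sites)),
              ncol(x$bags[[1]]$features),
              paste(setdiff(names(x$attributes), "slide_id"),
                    collapse = ", ")))
  invisible(x)
}

#' Slide ids of a cohort
#' @param x a `cohort`.
#' @return character vector.
#' @export
slide_ids <- function(x) vapply(x$bags, function(b) b$slide_id, character(1))

#' Site (TSS) label per slide
#' @param x a `cohort`.
#' @return character vector aligned with [slide_ids()].
#' @export
site_labels <- function(x) vapply(x$bags, function(b) b$site, character(1))

#' Pool all patches of a cohort into one matrix
#'
#' Stacks every bag's features row-wise and returns bookkeeping vectors used
#' by ComBat (site per patch) and by re-bagging (slide per patch).
#'
#' @param x a `cohort`.
#' @return list with `X` (sum(P) x D matrix), `site` and `slide` (per-row
#'   labels).
#' @export
pool_patches <- function(x) {
  X <- do.call(rbind, lapply(x$bags, function(b) b$features))
  np <- vapply(x$bags, function(b) nrow(b$features), integer(1))
  list(X = X,
       site = rep(site_labels(x), np),
       slide = rep(slide_ids(x), np))
}

#' Replace the pooled feature matrix of a cohort
#'
#' Inverse of [pool_patches()]: distributes the rows of `X` back into bags in
#' the original order, preserving coords and labels.
#'
#' @param x a `cohort`.
#' @param X matrix with as many rows as the cohort has patches.
#' @return a `cohort` with the same structure and new feature values.
#' @export
repool_patches <- function(x, X) {
  np <- vapply(x$bags, function(b) nrow(b$features), integer(1))
  stopifnot(nrow(X) == sum(np))
  off <- c(0L, cumsum(np))
  bags <- x$bags
  for (i in seq_along(bags)) {
    bags[[i]]$features <- X[(off[i] + 1L):off[i + 1L], , drop = FALSE]
  }
  cohort(bags, x$attributes, x$provenance)
}

#' Apply a feature mask to every bag of a cohort
#' @param x a `cohort`.
#' @param mask logical vector over the current feature columns.
#' @return masked `cohort`.
#' @export
mask_features <- function(x, mask) {
  stopifnot(is.logical(mask), length(mask) == ncol(x$bags[[1]]$features))
  if (!any(mask)) stop("mask_features: all features removed")
  bags <- lapply(x$bags, function(b) {
    b$features <- b$features[, mask, drop = FALSE]
    b
  })
  cohort(bags, x$attributes, x$provenance)
}
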