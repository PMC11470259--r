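# Cohort store: one directory per cohort holding
#   manifest.tsv     slide_id, site, patch_count, matrix_file, extractor_tag
#   attributes.tsv   slide_id + categorical columns (missing sentinel explicit)
#   provenance.json  config echo, seed, package version, feature mask
#   matrices/<slide_id>.tsv   P x D (and optional coords columns)
# Matrices use %.17g formatting so doubles round-trip exactly.

fmt17 <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(X, coords, path) {
  df <- as.data.frame(apply(X, 2L, fmt17))
  names(df) <- sprintf("f%04d", seq_len(ncol(X)))
  if (!is.null(coords)) {
    df$coord_row <- coords[, 1]
    df$coord_col <- coords[, 2]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  cc <- grepl("^coord_", names(df))
  X <- vapply(df[!cc], as.numeric, numeric(nrow(df)))
  X <- matrix(X, nrow = nrow(df))
  coords <- NULL
  if (any(cc))
    coords <- cbind(as.integer(df$coord_row), as.integer(df$coord_col))
  list(X = X, coords = coords)
}

#' Write a cohort to a directory store
#'
#' Layout: a TSV manifest (slide_id, site, patch_count, matrix file,
#' extractor tag), a TSV attribute table with an explicit missing-value
#' sentinel, a JSON provenance sidecar, and one TSV matrix per slide with
#' full-precision (`%.17g`) values so the round-trip is lossless.
#'
#' @param cohort a [cohort()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(file.path(path, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  ids <- slide_ids(cohort)
  manifest <- data.frame(
    slide_id = ids, site = site_labels(cohort),
    patch_count = vapply(cohort$bags, function(b) nrow(b$features),
                         integer(1)),
    matrix_file = file.path("matrices", paste0(ids, ".tsv")),
    extractor_tag = vapply(cohort$bags, function(b) b$extractor_tag,
                           character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  att <- cohort$attributes
  for (nm in setdiff(names(att), "slide_id")) {
    v <- as.character(att[[nm]])
    v[is.na(v)] <- MISSING_CODE
    att[[nm]] <- v
  }
  utils::write.table(att, file.path(path, "attributes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prov <- cohort$provenance
  prov$version <- prov$version %||%
    as.character(utils::packageVersion("combatslide"))
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  for (b in cohort$bags)
    write_matrix_tsv(b$features, b$coords,
                     file.path(path, "matrices", paste0(b$slide_id, ".tsv")))
  invisible(path)
}

#' Read a cohort from a directory store
#'
#' @param path directory written by [write_cohort()].
#' @return a [cohort()]; manifest/matrix inconsistencies raise errors naming
#'   the offending slide.
#' @export
read_cohort <- function(path) {
  manifest <- utils::read.table(file.path(path, "manifest.tsv"), sep = "\t",
                                header = TRUE, colClasses = "character")
  att <- utils::read.table(file.path(path, "attributes.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character")
  for (nm in setdiff(names(att), "slide_id"))
    att[[nm]][att[[nm]] == MISSING_CODE] <- NA
  prov <- tryCatch(
    jsonlite::read_json(file.path(path, "provenance.json"),
                        simplifyVector = TRUE),
    error = function(e) list())
  bags <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(path, manifest$matrix_file[i])
    if (!file.exists(f))
      stop("read_cohort: matrix file missing for slide ",
           manifest$slide_id[i])
    m <- read_matrix_tsv(f)
    if (nrow(m$X) != as.integer(manifest$patch_count[i]))
      stop("read_cohort: patch count mismatch for slide ",
           manifest$slide_id[i])
    bags[[i]] <- patch_bag(manifest$slide_id[i], manifest$site[i], m$X,
                           coords = m$coords,
                           extractor_tag = manifest$extractor_tag[i])
  }
  cohort(bags, att, as.list(prov))
}
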