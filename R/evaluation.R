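#' Drop slides from sites below a minimum size
#'
#' Sites contributing fewer than `min_n` slides are removed so that every
#' remaining site can appear in every cross-validation fold.
#'
#' @param cohort a [cohort()].
#' @param min_n minimum slides per site (default 5).
#' @return filtered `cohort`; errors if fewer than 2 sites remain.
#' @export
filter_sites_min_n <- function(cohort, min_n = 5L) {
  sites <- site_labels(cohort)
  keep_sites <- names(which(table(sites) >= min_n))
  if (length(keep_sites) < 2L)
    stop("filter_sites_min_n: fewer than 2 sites remain")
  keep <- sites %in% keep_sites
  co <- cohort(cohort$bags[keep],
               cohort$attributes[cohort$attributes$slide_id %in%
                                   slide_ids(cohort)[keep], , drop = FALSE],
               cohort$provenance)
  co
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA rejected).
#' @return q-values in the original order, capped at 1; monotone
#'   non-decreasing in the sorted order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("bh_adjust: NA p-values")
  if (any(pvals < 0 | pvals > 1)) stop("bh_adjust: p outside [0,1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
  q
}

#' Screen attributes for association with site
#'
#' Chi-squared test of each attribute against the site label (missing values
#' dropped pairwise), BH adjustment across the screened family, and the
#' minority-class support rule: an attribute is included when `q < fdr` AND
#' its minority class has at least `min_minority` non-missing slides.
#'
#' @param attribute_table data.frame of categorical attributes (no slide_id
#'   column needed; `NA` and the missing sentinel both count as missing).
#' @param site_labels per-row site labels.
#' @param min_minority minimum minority-class count (default 30).
#' @param fdr BH false-discovery threshold (default 0.05).
#' @return data.frame with one row per attribute: `attribute`, `chi2`, `p`,
#'   `q`, `minority_count`, `included`.
#' @export
screen_attributes <- function(attribute_table, site_labels,
                              min_minority = 30L, fdr = 0.05) {
  attrs <- setdiff(names(attribute_table), "slide_id")
  if (length(attrs) == 0L) stop("screen_attributes: empty attribute table")
  stopifnot(length(site_labels) == nrow(attribute_table))
  res <- lapply(attrs, function(a) {
    v <- attribute_table[[a]]
    v[v == MISSING_CODE] <- NA
    ok <- !is.na(v)
    tab <- table(v[ok], site_labels[ok])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      stop("screen_attributes: attribute ", a,
           " lacks two populated classes/sites")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(attribute = a, chi2 = unname(ct$statistic),
               p = unname(ct$p.value),
               minority_count = min(rowSums(tab)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$included <- out$q < fdr & out$minority_count >= min_minority
  out[, c("attribute", "chi2", "p", "q", "minority_count", "included")]
}

#' Stratified cross-validation folds
#'
#' Deals the members of each class round-robin into `k` folds after a seeded
#' shuffle, so every fold contains at least one member of every class.
#'
#' @param labels class labels (one per slide).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment in `1..k`, aligned with `labels`.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  cnt <- table(labels)
  if (any(cnt < k))
    stop("make_folds: class with fewer than k members: ",
         paste(names(cnt)[cnt < k], collapse = ", "))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(cnt)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Area under the ROC curve
#'
#' Binary AUROC via the midrank (Mann-Whitney) convention: the probability
#' that a random positive outscores a random negative, ties credited 1/2.
#' For multiclass input with `multiclass = "ovr_weighted"`, the one-vs-rest
#' AUROC of each class (scored by its probability column) is averaged with
#' weights proportional to the class support.
#'
#' @param scores for binary problems a numeric vector (score of the positive
#'   class, taken to be the last factor level unless `positive` is given);
#'   for multiclass a slides x C matrix with class-named columns.
#' @param labels true class labels.
#' @param multiclass `"none"` (binary) or `"ovr_weighted"`.
#' @param positive positive-class label for the binary case.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, multiclass = c("none", "ovr_weighted"),
                  positive = NULL) {
  multiclass <- match.arg(multiclass)
  labels <- as.character(labels)
  if (multiclass == "ovr_weighted") {
    scores <- as.matrix(scores)
    classes <- colnames(scores)
    if (is.null(classes)) stop("auroc: multiclass scores need class columns")
    present <- intersect(classes, unique(labels))
    if (length(present) < 2L) stop("auroc: need >= 2 classes present")
    n <- vapply(present, function(cl) sum(labels == cl), numeric(1))
    a <- vapply(present, function(cl)
      auroc(scores[, cl], ifelse(labels == cl, "pos", "neg"),
            positive = "pos"), numeric(1))
    return(sum(n / sum(n) * a))
  }
  u <- unique(labels)
  if (length(u) != 2L) stop("auroc: labels must have exactly 2 classes")
  positive <- positive %||% sort(u)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("auroc: one class absent")
  r <- rank(scores)                         # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-sample and paired t-tests on fold AUROCs
#'
#' With `b` a vector, performs the two-sided paired t-test on `a - b`; with
#' `b` a scalar null value (default 0.5), performs the one-sided (greater)
#' one-sample t-test of `a` against it. Zero-variance degenerate cases are
#' handled deterministically: t is `+/-Inf` (p 0 or 1 by sign) or `t = 0,
#' p = 1` (two-sided) / `p = 0.5` (one-sided) when the mean difference is also
#' zero, with `degenerate = TRUE`.
#'
#' @param a numeric vector of fold AUROCs.
#' @param b paired vector of equal length, or a scalar null value.
#' @param null_value null mean used when `b` is missing.
#' @return list `t`, `p`, `df`, `degenerate`, `type`.
#' @export
t_tests <- function(a, b = NULL, null_value = 0.5) {
  if (length(a) < 2L) stop("t_tests: need >= 2 folds")
  if (!is.null(b) && length(b) > 1L) {
    if (length(b) != length(a)) stop("t_tests: paired vectors differ in length")
    d <- a - b
    type <- "paired_two_sided"
    one_sided <- FALSE
  } else {
    d <- a - (if (is.null(b)) null_value else b)
    type <- "one_sample_greater"
    one_sided <- TRUE
  }
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0)
      return(list(t = 0, p = if (one_sided) 0.5 else 1, df = n - 1,
                  degenerate = TRUE, type = type))
    tt <- sign(m) * Inf
    p <- if (one_sided) (if (m > 0) 0 else 1) else 0
    return(list(t = tt, p = p, df = n - 1, degenerate = TRUE, type = type))
  }
  tt <- m / (s / sqrt(n))
  p <- if (one_sided) stats::pt(tt, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE)
  list(t = tt, p = p, df = n - 1, degenerate = FALSE, type = type)
}

#' Bootstrap confidence interval for an AUROC
#'
#' Resamples slides with replacement, recomputes the AUROC per replicate, and
#' reports the 2.5/97.5 percentile interval. Replicates with a single class
#' are redrawn (counted in `n_redrawn`).
#'
#' @param scores slide scores (vector, or matrix for `ovr_weighted`).
#' @param labels slide labels.
#' @param n_boot number of replicates (default 10).
#' @param seed RNG seed.
#' @param multiclass passed to [auroc()].
#' @return list `point`, `lower`, `upper`, `replicates`, `n_redrawn`.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 10L, seed = 1L,
                         multiclass = "none") {
  stopifnot(n_boot >= 2L)
  labels <- as.character(labels)
  n <- length(labels)
  smat <- if (is.matrix(scores)) scores else matrix(scores, ncol = 1)
  point <- auroc(if (multiclass == "none") smat[, 1] else smat, labels,
                 multiclass = multiclass)
  reps <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      for (try in seq_len(1000L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) >= 2L) break
        n_redrawn <- n_redrawn + 1L
        if (try == 1000L)
          stop("bootstrap_ci: cannot draw a two-class replicate")
      }
      reps[i] <- auroc(if (multiclass == "none") smat[idx, 1]
                       else smat[idx, , drop = FALSE],
                       labels[idx], multiclass = multiclass)
    }
  })
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  list(point = point, lower = qs[1], upper = qs[2], replicates = reps,
       n_redrawn = n_redrawn)
}

#' Cross-validated A-MIL experiment over paired conditions
#'
#' The core audit: for one prediction target, trains an A-MIL model per fold
#' and per condition (e.g. raw vs ComBat-harmonized features) using one shared
#' stratified fold assignment (the pairing requirement of the paired t-test),
#' evaluates the held-out fold with the (OvR-weighted) AUROC, and reports
#' per-condition fold AUROCs, one-sided t-tests against 0.5, and two-sided
#' paired t-tests of every condition against the first.
#'
#' The held-out fold doubles as the early-stopping validation set (no inner
#' split), which mirrors the apparent design of site-audit studies but is
#' optimistic; pass `inner_val = TRUE` to carve a stratified 80/20 inner
#' split from the training folds instead.
#'
#' @param cohorts named list of condition -> [cohort()], all sharing slide
#'   ids and attributes; the first condition is the baseline for paired
#'   comparisons.
#' @param target attribute name to predict (use `"site"` to predict the TSS).
#' @param k number of folds (5, or 3 for small targets).
#' @param config_fn function(input_dim, n_classes) -> [amil_config()], so the
#'   caller controls the training budget.
#' @param seed seed for the fold assignment (training seeds derive from it).
#' @param inner_val use an inner 80/20 validation split instead of the test
#'   fold.
#' @return an `experiment_result`: data.frame `summary` (one row per
#'   condition: mean AUROC, range, t and p vs 0.5, paired t/p/q vs baseline),
#'   list `fold_aurocs`, the fold assignment, and per-slide out-of-fold score
#'   matrices.
#' @export
run_experiment <- function(cohorts, target, k = 5L, config_fn = NULL,
                           seed = 1L, inner_val = FALSE) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L,
            !is.null(names(cohorts)))
  base <- cohorts[[1]]
  ids <- slide_ids(base)
  lab <- if (identical(target, "site")) site_labels(base)
         else base$attributes[[target]]
  if (is.null(lab)) stop("run_experiment: unknown target ", target)
  lab <- as.character(lab)
  keep <- !is.na(lab) & lab != MISSING_CODE
  ids <- ids[keep]; lab <- lab[keep]
  classes <- sort(unique(lab))
  fold <- make_folds(lab, k, seed = seed)
  names(fold) <- ids
  # one training seed per fold, shared across conditions: identical inputs
  # then yield identical results, keeping the paired comparison exact
  seeds <- split_seed(seed, k)

  if (is.null(config_fn))
    config_fn <- function(input_dim, n_classes)
      amil_config(input_dim, n_classes)

  fold_aurocs <- list()
  scores <- list()
  for (cond in names(cohorts)) {
    co <- cohorts[[cond]]
    stopifnot(setequal(slide_ids(co), slide_ids(base)))
    D <- ncol(co$bags[[1]]$features)
    att <- co$attributes
    if (identical(target, "site")) att$site <- site_labels(co)
    co_l <- cohort(co$bags, att, co$provenance)
    aucs <- numeric(k)
    smat <- matrix(NA_real_, length(ids), length(classes),
                   dimnames = list(ids, classes))
    for (f in seq_len(k)) {
      test_ids <- ids[fold == f]
      train_ids <- ids[fold != f]
      if (inner_val) {
        iv <- make_folds(lab[fold != f], 5L, seed = seeds[f])
        val_ids <- train_ids[iv == 1L]
        train_ids <- train_ids[iv != 1L]
      } else val_ids <- test_ids
      cfg <- config_fn(D, length(classes))
      cfg$seed <- seeds[f]
      mod <- amil_train(co_l, if (identical(target, "site")) "site" else
                          target, train_ids, val_ids, cfg)
      sub <- cohort(co_l$bags[match(test_ids, slide_ids(co_l))],
                    co_l$attributes[match(test_ids,
                                          co_l$attributes$slide_id), ,
                                    drop = FALSE])
      P <- amil_predict_proba(mod, sub)
      smat[test_ids, colnames(P)] <- P
      y_test <- lab[match(test_ids, ids)]
      if (length(unique(y_test)) < 2L)
        stop("run_experiment: fold ", f, " has a single class at evaluation")
      aucs[f] <- if (length(classes) == 2L)
        auroc(P[, classes[2]], y_test, positive = classes[2])
      else auroc(P, y_test, multiclass = "ovr_weighted")
    }
    fold_aurocs[[cond]] <- aucs
    scores[[cond]] <- smat
  }

  summ <- data.frame(target = target, condition = names(cohorts),
                     mean_auroc = NA_real_, min_auroc = NA_real_,
                     max_auroc = NA_real_, t_vs_chance = NA_real_,
                     p_vs_chance = NA_real_, t_vs_baseline = NA_real_,
                     p_vs_baseline = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(cohorts)) {
    a <- fold_aurocs[[i]]
    summ$mean_auroc[i] <- mean(a)
    summ$min_auroc[i] <- min(a)
    summ$max_auroc[i] <- max(a)
    ts <- t_tests(a, null_value = 0.5)
    summ$t_vs_chance[i] <- ts$t
    summ$p_vs_chance[i] <- ts$p
    if (i > 1L) {
      tp <- t_tests(a, fold_aurocs[[1]])
      summ$t_vs_baseline[i] <- tp$t
      summ$p_vs_baseline[i] <- tp$p
    }
  }
  if (length(cohorts) > 1L)
    summ$q_vs_baseline <- c(NA, bh_adjust(summ$p_vs_baseline[-1]))
  structure(list(summary = summ, fold_aurocs = fold_aurocs, fold = fold,
                 scores = scores, target = target, k = k, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> target=%s, %d-fold\n", x$target, x$k))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Table-1-style cohort summary
#'
#' Per categorical attribute: the percentage of slides with a missing value
#' (denominator = all slides), and per class the count plus percentage under
#' both denominators (non-missing, the default display convention, and
#' total).
#'
#' @param attribute_table data.frame of categorical attributes (a `slide_id`
#'   column is ignored); `NA` or the missing sentinel mark missing values.
#' @param digits rounding used for the display columns (unrounded values are
#'   kept alongside).
#' @return data.frame with columns `attribute`, `class` (`NA` on the
#'   attribute-level missingness row), `n`, `pct_nonmissing`, `pct_total`,
#'   `pct_missing`, plus unrounded `*_raw` columns.
#' @export
summarize_cohort <- function(attribute_table, digits = 2L) {
  attrs <- setdiff(names(attribute_table), "slide_id")
  if (length(attrs) == 0L || nrow(attribute_table) == 0L)
    stop("summarize_cohort: empty attribute table")
  N <- nrow(attribute_table)
  rows <- list()
  for (a in attrs) {
    v <- as.character(attribute_table[[a]])
    v[v == MISSING_CODE] <- NA
    n_miss <- sum(is.na(v))
    pm <- 100 * n_miss / N
    rows[[length(rows) + 1L]] <- data.frame(
      attribute = a, class = NA_character_, n = n_miss,
      pct_nonmissing = NA_real_, pct_total = NA_real_,
      pct_missing = round(pm, digits), pct_missing_raw = pm,
      pct_nonmissing_raw = NA_real_, pct_total_raw = NA_real_,
      stringsAsFactors = FALSE)
    nn <- N - n_miss
    if (nn > 0L) {
      tab <- table(v)
      for (cl in names(tab)) {
        p1 <- 100 * tab[[cl]] / nn
        p2 <- 100 * tab[[cl]] / N
        rows[[length(rows) + 1L]] <- data.frame(
          attribute = a, class = cl, n = tab[[cl]],
          pct_nonmissing = round(p1, digits), pct_total = round(p2, digits),
          pct_missing = NA_real_, pct_missing_raw = NA_real_,
          pct_nonmissing_raw = p1, pct_total_raw = p2,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
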