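#' MAX_DIFF: maximum ratio between consecutive clone abundances
#'
#' Clones are ordered by decreasing abundance and the ratio of each clone to
#' the next, \code{pct[N] / pct[N + 1]}, is computed; MAX_DIFF is the
#' maximum of these ratios and its position the candidate clonal/subclonal
#' cut-off. Scale-invariant: percentages, fractions or raw read counts give
#' the same value. With a single clone there is no consecutive pair and
#' MAX_DIFF is \code{Inf}; with no clones it is \code{NA}.
#'
#' @param pcts numeric clone abundances (any scale, any order).
#' @return \code{maxDiff}: the maximum consecutive ratio.
#' @examples
#' maxDiff(c(60, 5, 4, 1))          # 12
#' maxDiffPosition(c(40, 30, 2))    # 2
#' @export
maxDiff <- function(pcts) {
  pcts <- sort(pcts[pcts > 0], decreasing = TRUE)
  if (length(pcts) == 0L) return(NA_real_)
  if (length(pcts) == 1L) return(Inf)
  max(pcts[-length(pcts)] / pcts[-1])
}

#' @rdname maxDiff
#' @return \code{maxDiffPosition}: 1-based index N of the first maximal
#'   ratio (ties resolve to the most abundant position, the conservative N).
#' @export
maxDiffPosition <- function(pcts) {
  pcts <- sort(pcts[pcts > 0], decreasing = TRUE)
  if (length(pcts) <= 1L) return(if (length(pcts)) 1L else NA_integer_)
  r <- pcts[-length(pcts)] / pcts[-1]
  which.max(r)  # first maximum on ties
}

#' Compute a repertoire abundance profile
#'
#' Drops clones below \code{minPct} percent (noise floor 0.1 by default),
#' re-sorts the remainder by decreasing percentage and computes the
#' consecutive ratios and MAX_DIFF. An all-filtered profile is returned
#' empty and flagged unclassifiable by [classifySample()].
#'
#' @param x a [RearrangementSet-class] (uses \code{clonal_pct} and ids) or a
#'   numeric vector of clone percentages.
#' @param minPct minimum clone percentage retained (default 0.1).
#' @param sampleId sample name (taken from the set when given one).
#' @return a [RepertoireProfile-class].
#' @examples
#' computeProfile(c(50, 25, 12.5))
#' @export
computeProfile <- function(x, minPct = 0.1, sampleId = "sample") {
  if (is(x, "RearrangementSet")) {
    pcts <- x@table$clonal_pct
    ids <- x@table$id
    sampleId <- x@sampleId
  } else {
    pcts <- as.numeric(x)
    ids <- names(x) %||% paste0("clone", seq_along(pcts))
  }
  keep <- !is.na(pcts) & pcts >= minPct
  pcts <- pcts[keep]; ids <- ids[keep]
  ord <- order(-pcts, ids)
  pcts <- pcts[ord]; ids <- ids[ord]
  n <- length(pcts)
  ratios <- if (n >= 2) pcts[-n] / pcts[-1] else numeric(0)
  new("RepertoireProfile", sampleId = sampleId, clonePcts = pcts,
      cloneIds = ids, ratios = ratios,
      maxDiff = maxDiff(pcts),
      maxDiffPosition = maxDiffPosition(pcts) %||% NA_integer_)
}

#' @export
setMethod("show", "RepertoireProfile", function(object) {
  cat("RepertoireProfile", object@sampleId, "-", length(object@clonePcts),
      "clone(s); MAX_DIFF =", format(object@maxDiff, digits = 4),
      "at position", object@maxDiffPosition, "\n")
})

#' Feature vector of a profile for classification
#'
#' The default features are \code{log10(MAX_DIFF)} and the top-clone
#' percentage. An infinite MAX_DIFF (single-clone profile) is capped at the
#' value \code{capRatio} before the log so the feature stays finite.
#'
#' @param profile a [RepertoireProfile-class].
#' @param capRatio finite stand-in for an infinite ratio (default 1000,
#'   just above the largest ratio seen in practice).
#' @return named numeric: \code{log10_max_diff}, \code{top_clone_pct}.
#' @export
profileFeatures <- function(profile, capRatio = 1000) {
  md <- profile@maxDiff
  if (is.na(md)) return(c(log10_max_diff = NA_real_,
                          top_clone_pct = NA_real_))
  md <- min(md, capRatio)
  c(log10_max_diff = log10(md),
    top_clone_pct = if (length(profile@clonePcts))
      profile@clonePcts[1] else NA_real_)
}

.f1Scores <- function(truth, pred) {
  lv <- levels(truth)
  perClass <- vapply(lv, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  tp <- sum(pred == truth)
  c(f1_micro = tp / length(truth),  # micro-F1 equals accuracy here
    f1_macro = mean(perClass, na.rm = TRUE))
}

#' Train the KNN repertoire classifier
#'
#' Fits a k-nearest-neighbour model (Euclidean distance on standardized
#' features) separating clonal from polyclonal repertoires, reporting
#' accuracy on a stratified train/test split and stratified 10-fold
#' cross-validated micro/macro F1.
#'
#' @param features numeric matrix (samples x features), e.g. rows of
#'   [profileFeatures()].
#' @param labels factor/character of per-sample labels (two or more classes).
#' @param k number of neighbours (odd; default 3).
#' @param testFraction fraction held out for the test accuracy (default 0.3,
#'   stratified).
#' @param nFolds folds for cross-validation (default 10).
#' @param seed optional integer seed for the split and folds.
#' @return a [KnnClassifier-class]; its \code{accuracy} slot holds
#'   \code{train_accuracy}, \code{test_accuracy}, \code{cv_f1_micro_mean},
#'   \code{cv_f1_micro_sd}, \code{cv_f1_macro_mean}, \code{cv_f1_macro_sd}.
#' @export
trainKnn <- function(features, labels, k = 3L, testFraction = 0.3,
                     nFolds = 10L, seed = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training requires at least two classes")
  if (k >= nrow(features)) stop("k must be smaller than the number of samples")
  if (anyNA(features)) stop("features contain NA")
  .withSeed(seed, {
    # stratified split
    testIdx <- unlist(lapply(levels(labels), function(cl) {
      ix <- which(labels == cl)
      sample(ix, max(1L, round(testFraction * length(ix))))
    }))
    trainIdx <- setdiff(seq_len(nrow(features)), testIdx)
    ctr <- colMeans(features[trainIdx, , drop = FALSE])
    scl <- apply(features[trainIdx, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
    trX <- std(features[trainIdx, , drop = FALSE])
    teX <- std(features[testIdx, , drop = FALSE])
    predTr <- class::knn(trX, trX, labels[trainIdx], k = k)
    predTe <- class::knn(trX, teX, labels[trainIdx], k = k)
    # stratified nFolds-fold CV on the full data
    folds <- integer(nrow(features))
    for (cl in levels(labels)) {
      ix <- sample(which(labels == cl))
      folds[ix] <- rep_len(seq_len(nFolds), length(ix))
    }
    cv <- vapply(seq_len(nFolds), function(f) {
      tr <- folds != f; te <- folds == f
      if (!any(te) || length(unique(labels[tr])) < 2)
        return(c(f1_micro = NA_real_, f1_macro = NA_real_))
      c0 <- colMeans(features[tr, , drop = FALSE])
      s0 <- apply(features[tr, , drop = FALSE], 2, stats::sd)
      s0[s0 == 0] <- 1
      sf <- function(m) sweep(sweep(m, 2, c0), 2, s0, "/")
      p <- class::knn(sf(features[tr, , drop = FALSE]),
                      sf(features[te, , drop = FALSE]),
                      labels[tr], k = min(k, sum(tr) - 1L))
      .f1Scores(labels[te], p)
    }, numeric(2))
    acc <- c(train_accuracy = mean(predTr == labels[trainIdx]),
             test_accuracy = mean(predTe == labels[testIdx]),
             cv_f1_micro_mean = mean(cv["f1_micro", ], na.rm = TRUE),
             cv_f1_micro_sd = stats::sd(cv["f1_micro", ], na.rm = TRUE),
             cv_f1_macro_mean = mean(cv["f1_macro", ], na.rm = TRUE),
             cv_f1_macro_sd = stats::sd(cv["f1_macro", ], na.rm = TRUE))
    new("KnnClassifier", train = trX, labels = factor(labels[trainIdx]),
        center = ctr, scale = scl, k = as.integer(k), accuracy = acc)
  })
}

#' @export
setMethod("show", "KnnClassifier", function(object) {
  cat("KnnClassifier (k =", object@k, ") on", nrow(object@train),
      "training samples\n")
  print(round(object@accuracy, 4))
})

#' Classify a sample's repertoire structure
#'
#' Applies the KNN classifier to the profile's features. A clonal verdict is
#' labelled \code{"<N>CLONE"} with N the MAX_DIFF position: clones ranked
#' 1..N are clonal, the rest subclonal. A single-rearrangement profile
#' (infinite MAX_DIFF) is 1CLONE. An empty profile yields an
#' \code{"unclassifiable"} verdict rather than an error. MAX_DIFF values in
#' the overlap zone between the clonal groups and the polyclonal maximum
#' (4-8.19) are flagged near-threshold.
#'
#' @param profile a [RepertoireProfile-class].
#' @param classifier a fitted [KnnClassifier-class].
#' @return a [ClonalityCall-class].
#' @export
classifySample <- function(profile, classifier) {
  if (length(profile@clonePcts) == 0L || is.na(profile@maxDiff))
    return(new("ClonalityCall", sampleId = profile@sampleId,
               label = "unclassifiable", nClones = 0L,
               clonalIds = character(0), subclonalIds = character(0),
               maxDiff = NA_real_, features = numeric(0),
               k = classifier@k, nearThreshold = FALSE))
  feat <- profileFeatures(profile)
  x <- (feat - classifier@center) / classifier@scale
  lab <- as.character(class::knn(classifier@train, rbind(x),
                                 classifier@labels, k = classifier@k))
  md <- profile@maxDiff
  near <- is.finite(md) && md > 4 && md < 8.19
  if (lab == "polyclonal")
    return(new("ClonalityCall", sampleId = profile@sampleId,
               label = "polyclonal", nClones = 0L,
               clonalIds = character(0),
               subclonalIds = profile@cloneIds, maxDiff = md,
               features = feat, k = classifier@k, nearThreshold = near))
  n <- if (is.finite(md)) profile@maxDiffPosition else 1L
  new("ClonalityCall", sampleId = profile@sampleId,
      label = paste0(n, "CLONE"), nClones = as.integer(n),
      clonalIds = profile@cloneIds[seq_len(n)],
      subclonalIds = profile@cloneIds[-seq_len(n)],
      maxDiff = md, features = feat, k = classifier@k,
      nearThreshold = near)
}

#' @export
setMethod("show", "ClonalityCall", function(object) {
  cat("ClonalityCall", object@sampleId, ":", object@label,
      if (object@nearThreshold) "(near-threshold)" else "", "\n")
  if (object@nClones > 0)
    cat("  clonal:", paste(object@clonalIds, collapse = ", "), "\n")
})

#' Group statistics for MAX_DIFF
#'
#' Per-group average/maximum/minimum MAX_DIFF, pairwise two-sided
#' Mann-Whitney U tests with Bonferroni correction over the number of
#' pairwise comparisons, and the fold-difference of each pair's group
#' averages. Groups with fewer than 3 samples are excluded with a warning.
#' The U test uses exact enumeration up to 20 samples per group (no ties)
#' and the tie-corrected normal approximation otherwise, via
#' \code{stats::wilcox.test}.
#'
#' @param groups named list of numeric MAX_DIFF vectors, one per group.
#' @return list with \code{summary} (data.frame: group, n, average, maximum,
#'   minimum) and \code{tests} (data.frame: group1, group2, U, p_value,
#'   p_bonferroni, fold_difference).
#' @export
groupStats <- function(groups) {
  n <- vapply(groups, length, 0L)
  if (any(n < 3)) {
    warning("excluding group(s) with < 3 samples: ",
            paste(names(groups)[n < 3], collapse = ", "))
    groups <- groups[n >= 3]
  }
  if (length(groups) < 2) stop("need at least two groups with >= 3 samples")
  summary <- data.frame(group = names(groups),
                        n = vapply(groups, length, 0L),
                        average = vapply(groups, mean, 0),
                        maximum = vapply(groups, max, 0),
                        minimum = vapply(groups, min, 0),
                        stringsAsFactors = FALSE)
  pairs <- utils::combn(names(groups), 2)
  tests <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- groups[[g1]]; y <- groups[[g2]]
    exact <- length(x) <= 20 && length(y) <= 20 &&
      !any(duplicated(c(x, y)))
    wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                             exact = exact, correct = !exact)
    data.frame(group1 = g1, group2 = g2, U = unname(wt$statistic),
               p_value = wt$p.value,
               fold_difference = mean(x) / mean(y),
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  tests$p_bonferroni <- pmin(1, tests$p_value * nrow(tests))
  rownames(summary) <- rownames(tests) <- NULL
  list(summary = summary,
       tests = tests[, c("group1", "group2", "U", "p_value",
                         "p_bonferroni", "fold_difference")])
}

#' Sensitivity and specificity of rearrangement detection
#'
#' Exact-arithmetic confusion metrics, rounded to 2 decimals for reporting:
#' specificity = 100 TN / (TN + FP), sensitivity = 100 TP / (TP + FN). A
#' zero denominator yields \code{NA} (undefined), not an error.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return list with \code{sensitivity}, \code{specificity} (exact values)
#'   and \code{sensitivity_rounded}, \code{specificity_rounded}.
#' @examples
#' confusionMetrics(tp = 344, fp = 8, tn = 306, fn = 0)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       sensitivity_rounded = round(sens, 2),
       specificity_rounded = round(spec, 2))
}

#' Concordance percentage, report-style
#'
#' Percentage agreement \code{100 k / n} rounded to 2 decimals, the rounding
#' rule used throughout the reports.
#'
#' @param k concordant count.
#' @param n total count.
#' @param digits decimal places in the report (default 2).
#' @return numeric percentage rounded to \code{digits} decimals.
#' @examples
#' concordancePct(329, 344)
#' @export
concordancePct <- function(k, n, digits = 2) {
  if (n == 0) return(NA_real_)
  round(100 * k / n, digits)
}
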