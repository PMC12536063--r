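test_that("profiles order clones, filter noise and locate MAX_DIFF", {
  p <- computeProfile(c(50, 25, 12.5))
  expect_equal(p@ratios, c(2, 2))
  expect_equal(p@maxDiff, 2)
  expect_equal(p@maxDiffPosition, 1L)  # first maximal ratio on ties

  p <- computeProfile(c(60, 5, 4, 1))
  expect_equal(p@ratios, c(12, 1.25, 4))
  expect_equal(p@maxDiff, 12)
  expect_equal(p@maxDiffPosition, 1L)

  p <- computeProfile(c(40, 30, 2))
  expect_equal(p@maxDiff, 15)
  expect_equal(p@maxDiffPosition, 2L)

  # clones under the noise floor are dropped before anything else
  p <- computeProfile(c(60, 30, 0.05, 0.01))
  expect_length(p@clonePcts, 2)
  # unsorted input is re-sorted descending
  expect_equal(computeProfile(c(5, 60, 4, 1))@maxDiff, 12)
  # single clone: sentinel-infinite; empty: NA
  expect_equal(computeProfile(100)@maxDiff, Inf)
  expect_true(is.na(computeProfile(c(0.01, 0.02))@maxDiff))
})

test_that("MAX_DIFF is scale-invariant with a geometric closed form", {
  counts <- c(8000, 500, 400, 100)
  expect_equal(maxDiff(counts), maxDiff(counts * 17))
  expect_equal(maxDiff(counts), maxDiff(100 * counts / sum(counts)))
  for (r in c(1.5, 2, 3.7, 8)) {
    geo <- 100 * r^-(0:5)
    expect_equal(maxDiff(geo), r, tolerance = 1e-12)
  }
})

test_that("the KNN classifier separates simulated clonal from polyclonal", {
  profs <- c(lapply(1:20, function(i)
               simulateProfile("one_clone", seed = 1000 + i)),
             lapply(1:10, function(i)
               simulateProfile("two_clone", seed = 2000 + i)),
             lapply(1:15, function(i)
               simulateProfile("polyclonal", seed = 3000 + i)))
  labels <- c(rep("clonal", 30), rep("polyclonal", 15))
  feats <- t(vapply(profs, function(p)
    profileFeatures(computeProfile(100 * p)), numeric(2)))
  model <- trainKnn(feats, labels, k = 3, seed = 7)
  expect_equal(unname(model@accuracy["test_accuracy"]), 1)
  expect_gte(model@accuracy["cv_f1_macro_mean"], 0.95)

  # verdicts carry N from the MAX_DIFF position
  c1 <- classifySample(computeProfile(100 * profs[[1]], sampleId = "a"),
                       model)
  expect_equal(c1@label, "1CLONE")
  expect_equal(c1@nClones, 1L)
  c2 <- classifySample(computeProfile(100 * profs[[25]], sampleId = "b"),
                       model)
  expect_equal(c2@label, "2CLONE")
  expect_length(c2@clonalIds, 2)
  c0 <- classifySample(computeProfile(100 * profs[[40]], sampleId = "c"),
                       model)
  expect_equal(c0@label, "polyclonal")
  expect_length(c0@clonalIds, 0)
  # single-rearrangement sample (infinite MAX_DIFF) is 1CLONE
  cInf <- classifySample(computeProfile(100, sampleId = "d"), model)
  expect_equal(cInf@label, "1CLONE")
  # empty profile: unclassifiable verdict, not an exception
  cEmpty <- classifySample(computeProfile(c(0.01), sampleId = "e"), model)
  expect_equal(cEmpty@label, "unclassifiable")
})

test_that("KNN training rejects degenerate inputs and sanity-checks chance", {
  feats <- matrix(rnorm(20), ncol = 2)
  expect_error(trainKnn(feats, rep("x", 10)), "two classes")
  expect_error(trainKnn(feats, rep(c("x", "y"), 5), k = 11), "smaller")
  # permuted labels: cross-validated accuracy falls to about the class prior
  set.seed(31)
  n <- 60
  f2 <- cbind(c(rnorm(n / 2, 3), rnorm(n / 2, -3)), rnorm(n))
  permLabels <- sample(rep(c("clonal", "polyclonal"), n / 2))
  mPerm <- trainKnn(f2, permLabels, k = 3, seed = 8)
  expect_lt(mPerm@accuracy["cv_f1_micro_mean"], 0.75)
})

test_that("group statistics agree with an exact permutation oracle", {
  g <- list(a = c(8, 9, 10), b = c(1, 2, 2))
  gs <- groupStats(c(g, list(c = c(3, 4, 5, 6))))
  expect_equal(gs$summary$average[gs$summary$group == "a"], 9)
  ab <- gs$tests[gs$tests$group1 == "a" & gs$tests$group2 == "b", ]
  expect_equal(ab$U, 9)  # all a > all b
  # ties force the normal approximation; agreement with the exact
  # permutation oracle is approximate
  expect_lt(abs(ab$p_value - exactMannWhitneyP(g$a, g$b)), 0.05)
  expect_equal(ab$fold_difference, 9 / mean(c(1, 2, 2)))
  expect_equal(gs$tests$p_bonferroni,
               pmin(1, gs$tests$p_value * 3))

  # tie-free groups match the exact oracle exactly
  x <- c(11, 14, 17, 20); y <- c(1, 3, 5, 7, 9)
  gs2 <- groupStats(list(x = x, y = y, z = c(2, 4, 6)))
  xy <- gs2$tests[gs2$tests$group1 == "x" & gs2$tests$group2 == "y", ]
  expect_equal(xy$p_value, exactMannWhitneyP(x, y))

  # identical groups: corrected p = 1
  same <- list(a = c(5, 6, 7, 8), b = c(5, 6, 7, 8))
  gs3 <- groupStats(same)
  expect_equal(gs3$tests$p_bonferroni, 1)
  expect_warning(groupStats(list(a = 1:5, b = 1:2, c = 2:6)), "excluding")
  expect_error(suppressWarnings(groupStats(list(a = 1:5, b = 1:2))))
})

test_that("confusion and concordance arithmetic is exact", {
  cm <- confusionMetrics(tp = 344, fp = 8, tn = 306, fn = 0)
  expect_equal(cm$specificity_rounded, 97.45)
  expect_equal(cm$sensitivity_rounded, 100)
  und <- confusionMetrics(tp = 0, fp = 0, tn = 0, fn = 0)
  expect_true(is.na(und$sensitivity) && is.na(und$specificity))
  expect_equal(concordancePct(329, 344), 95.64)
  expect_equal(concordancePct(293, 333), 87.99)
  expect_equal(concordancePct(341, 344, digits = 1), 99.1)
  expect_true(is.na(concordancePct(0, 0)))
})
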