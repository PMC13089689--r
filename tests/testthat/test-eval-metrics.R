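test_that("feature extraction is a deterministic row-wise map", {
  set.seed(61)
  v <- array(runif(16 * 16 * 3 * 8), c(16, 16, 3, 8))
  batch <- ImageBatch(v, "unit")
  ex <- toyFeatureExtractor(dim = 16, seed = 7)
  f1 <- extractFeatures(batch, ex)
  f2 <- extractFeatures(batch, ex)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(8L, 16L))
  expect_true(all(is.finite(f1)))
  # permuting images permutes rows identically
  perm <- c(3, 1, 2, 8, 4, 6, 5, 7)
  fp <- extractFeatures(ImageBatch(v[, , , perm], "unit"), ex)
  expect_equal(fp, f1[perm, ], ignore_attr = TRUE)
  expect_error(extractFeatures(ImageBatch(v[, , , 1, drop = FALSE], "unit"), ex),
               "at least 2")
})

test_that("the Frechet distance matches closed forms and is symmetric and zero on itself", {
  a <- gaussFeatures(40, 5, seed = 62)
  expect_lt(fidScore(computeFid(a, a)), 1e-6)
  b <- gaussFeatures(40, 5, mu = 0.5, seed = 63)
  expect_equal(fidScore(computeFid(a, b)), fidScore(computeFid(b, a)),
               tolerance = 1e-8)
  # 1-d two-Gaussian closed form with exact sample moments:
  # a has mean 0, var 1; b has mean 1, var 1 -> (0-1)^2 + (1+1-2) = 1
  a1 <- matrix(c(-1, 0, 1), 3, 1); b1 <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(fidScore(computeFid(a1, b1)), 1.0, tolerance = 1e-12)
  # 2-d diagonal-covariance case against the commuting closed form
  a2 <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  b2 <- rbind(c(2, 1), c(0, 1), c(1, 3), c(1, -1)) # a2/ shifted by (1,1), var (2/3, 8/3)
  va <- apply(a2, 2, var); vb <- apply(b2, 2, var)
  closed <- sum((colMeans(a2) - colMeans(b2))^2) +
    sum(va + vb - 2 * sqrt(va * vb))
  expect_equal(fidScore(computeFid(a2, b2)), closed, tolerance = 1e-8)
  # guards
  bad <- gaussFeatures(10, 5, seed = 64, id = "other")
  expect_error(computeFid(a, bad), "different extractors")
  expect_error(computeFid(a, gaussFeatures(10, 4, seed = 65)), "dimensionality")
})

test_that("FID grows monotonically with additive image noise", {
  set.seed(66)
  base <- array(runif(16 * 16 * 3 * 24), c(16, 16, 3, 24))
  ex <- toyFeatureExtractor(dim = 16, seed = 8)
  fa <- extractFeatures(ImageBatch(base, "unit"), ex)
  fids <- vapply(c(0.05, 0.15, 0.4), function(sig) {
    set.seed(67)
    noisy <- pmin(pmax(base + array(rnorm(length(base), 0, sig), dim(base)), 0), 1)
    fidScore(computeFid(fa, extractFeatures(ImageBatch(noisy, "unit"), ex)))
  }, numeric(1))
  expect_true(all(diff(fids) > 0))
})

test_that("macro-F1 matches hand computations and is permutation invariant", {
  expect_equal(macroF1(c(0, 1, 2, 3), c(0, 1, 2, 3), 4), 1.0)
  expect_equal(macroF1(c(0, 0, 1, 1), c(0, 1, 0, 1), 2), 0.5)
  # degenerate one-class predictor over 7 balanced classes:
  # predicted class: F1 = 2*2/(2*2 + 12 + 0); others 0
  yt <- rep(0:6, each = 2)
  yp <- rep(0L, 14)
  expect_equal(macroF1(yt, yp, 7), (2 * 2 / (2 * 2 + 12 + 0)) / 7,
               tolerance = 1e-12)
  # joint label permutation leaves the score unchanged
  set.seed(68)
  yt2 <- sample(0:3, 40, replace = TRUE)
  yp2 <- sample(0:3, 40, replace = TRUE)
  perm <- c(2L, 3L, 0L, 1L)
  expect_equal(macroF1(perm[yt2 + 1L], perm[yp2 + 1L], 4), macroF1(yt2, yp2, 4),
               tolerance = 1e-12)
  expect_error(macroF1(c(0, 1), c(0), 2), "length")
  expect_error(macroF1(c(0, 5), c(0, 1), 2), "range")
})

test_that("the two-arm baseline experiment is controlled and beats chance on separable fixtures", {
  # untinted fixtures: the class signal (lesion radius/darkness) is the
  # quantity under test, so the tone nuisance is held fixed
  real <- simulateDataset(fixtureConfig(resolution = 16,
                                        counts = c(df = 12L, mel = 12L,
                                                   nv = 12L), seed = 71))
  synth <- simulateDataset(fixtureConfig(resolution = 16,
                                         counts = c(df = 6L, mel = 6L,
                                                    nv = 6L), seed = 72))
  rep <- runBaselineExperiment(real, synth, epochs = 15, batchSize = 4, seed = 3)
  expect_s4_class(rep, "ComparisonReport")
  metrics <- c(rep@realOnly, rep@realPlusSynth)
  expect_true(all(is.finite(metrics) & metrics >= 0 & metrics <= 1))
  # classes are separable by lesion size/darkness: both arms beat 1/3 chance
  expect_gt(rep@realOnly["accuracy"], 1 / 3)
  expect_gt(rep@realPlusSynth["accuracy"], 1 / 3)
  # a zero-synthetic arm is exactly the real-only arm (identical settings)
  rep0 <- runBaselineExperiment(real, NULL, epochs = 2, batchSize = 4, seed = 3)
  expect_identical(rep0@realOnly, rep0@realPlusSynth)
  # synthetic classes outside the real set are refused
  alien <- simulateDataset(fixtureConfig(resolution = 16,
                                         counts = c(vasc = 4L), seed = 73))
  expect_error(runBaselineExperiment(real, alien, epochs = 1), "subset")
})
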