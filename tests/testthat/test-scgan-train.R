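# desk-scale training smokes: tiny nets at 16x16 keep these fast; the fuller
# 32x32 five-epoch run lives with the acceptance checks

smokeSet <- function(seed, n = 4L) {
  tintedFixtureSet(seed = seed, resolution = 16,
                   counts = c(mel = n, nv = n))
}

smokeCfg <- generatorConfig(resolution = 16, noise_channels = 2,
                            base_width = 2, n_res_blocks = 1)

test_that("a short training run completes with finite logged losses and a checkpoint", {
  ds <- smokeSet(81)
  set.seed(1)
  gen <- scganGenerator(smokeCfg)
  disc <- scganDiscriminator(smokeCfg)
  ck <- withr::local_tempfile(fileext = ".rds")
  fit <- scganTrain(gen, disc, ds,
                    trainConfig(epochs = 2, batch_size = 4, seed = 2),
                    checkpointPath = ck)
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(is.finite(as.matrix(fit$history))))
  expect_true(all(as.matrix(fit$history)[, -1] >= 0))
  expect_true(file.exists(ck))
  # weights actually moved
  expect_false(identical(fit$generator@layers[[1]]$params$W,
                         gen@layers[[1]]$params$W))
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- smokeSet(82)
  run <- function() {
    set.seed(9)
    scganTrain(scganGenerator(smokeCfg), scganDiscriminator(smokeCfg), ds,
               trainConfig(epochs = 2, batch_size = 4, seed = 7))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$generator@layers[[1]]$params$W,
                   b$generator@layers[[1]]$params$W)
})

test_that("training requires normalized input and a non-empty dataset", {
  ds <- smokeSet(83)
  unitDs <- LabeledImageSet(toUnitRange(images(ds)), lesionLabels(ds),
                            classNames = classNames(ds),
                            tones = as.character(tones(ds)))
  set.seed(1)
  expect_error(scganTrain(scganGenerator(smokeCfg),
                          scganDiscriminator(smokeCfg), unitDs,
                          trainConfig(epochs = 1)), "signed_unit")
})

test_that("trainConfig validates the optimisation hyperparameters", {
  expect_error(trainConfig(learning_rate = 0))
  expect_error(trainConfig(beta1 = 1))
  expect_error(trainConfig(epochs = 0))
  expect_error(trainConfig(lambda_rec = -1))
  cfg <- trainConfig()
  expect_equal(cfg$learning_rate, 2e-4)
  expect_equal(c(cfg$beta1, cfg$beta2), c(0.5, 0.999))
  expect_identical(cfg$epochs, 100L)
})
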