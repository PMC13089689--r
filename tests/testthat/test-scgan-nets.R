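test_that("tone one-hot encoding and spatial broadcast follow the medium=[1,0], dark=[0,1] convention", {
  expect_equal(toneOneHot(c("medium", "dark")),
               cbind(medium = c(1, 0), dark = c(0, 1)), ignore_attr = TRUE)
  expect_error(toneOneHot("light"), "unknown tone")
  m <- broadcastTone("medium", 4, 4)
  expect_true(all(m[, , 1] == 1) && all(m[, , 2] == 0))
  d <- broadcastTone("dark", 1, 1)
  expect_equal(as.vector(d), c(0, 1))
  # one-hot property: channels sum to one everywhere
  expect_true(all(m[, , 1] + m[, , 2] == 1))
})

test_that("the generator is fully convolutional, Tanh-bounded and deterministic", {
  cfg <- generatorConfig(resolution = 32, noise_channels = 4, base_width = 4,
                         n_res_blocks = 2)
  set.seed(21)
  gen <- scganGenerator(cfg)
  z <- sampleNoise(2, cfg)
  out <- scganGenerate(gen, z, c("medium", "dark"))
  expect_identical(dim(imageValues(out)), c(32L, 32L, 3L, 2L))
  expect_identical(rangeTag(out), "signed_unit")
  expect_true(all(abs(imageValues(out)) <= 1))
  # determinism with fixed weights and noise
  out2 <- scganGenerate(gen, z, c("medium", "dark"))
  expect_identical(imageValues(out), imageValues(out2))
  # a different tone on identical noise changes the output (input concat)
  out3 <- scganGenerate(gen, z, c("dark", "dark"))
  expect_false(identical(imageValues(out)[, , , 1], imageValues(out3)[, , , 1]))
  # any resolution divisible by 4 works without code change
  cfg20 <- generatorConfig(resolution = 20, noise_channels = 4, base_width = 4,
                           n_res_blocks = 1)
  set.seed(22)
  g20 <- scganGenerator(cfg20)
  expect_identical(dim(imageValues(scganGenerate(g20, sampleNoise(1, cfg20),
                                                 "medium"))),
                   c(20L, 20L, 3L, 1L))
  expect_error(generatorConfig(resolution = 30), "divisible by 4")
  expect_error(scganGenerate(gen, z, "medium"), "tone batch length")
})

test_that("channel bookkeeping: generator sees noise+2, discriminator sees 3+2", {
  cfg <- generatorConfig(resolution = 16, noise_channels = 6, base_width = 4,
                         n_res_blocks = 1)
  set.seed(23)
  gen <- scganGenerator(cfg)
  expect_identical(dim(gen@layers[[1]]$params$W)[3], 6L + 2L)
  disc <- scganDiscriminator(cfg)
  expect_identical(dim(disc@layers[[1]]$params$W)[3], 5L)
})

test_that("the discriminator yields a patch map (res/16) and 2-column tone logits", {
  cfg <- generatorConfig(resolution = 128, noise_channels = 2, base_width = 2,
                         n_res_blocks = 0)
  set.seed(24)
  disc <- scganDiscriminator(cfg)
  x <- ImageBatch(array(tanh(rnorm(128 * 128 * 3 * 3)), c(128, 128, 3, 3)),
                  "signed_unit")
  out <- scganDiscriminate(disc, x, c("medium", "dark", "medium"))
  expect_identical(dim(out$advMap), c(8L, 8L, 1L, 3L))   # four stride-2 halvings
  expect_identical(dim(out$toneLogits), c(3L, 2L))
  expect_true(all(is.finite(out$advMap)), all(is.finite(out$toneLogits)))
  small <- ImageBatch(array(0, c(32, 32, 3, 1)), "signed_unit")
  expect_error(scganDiscriminate(disc, small, "medium"), "shape")
})

test_that("checkpoints reproduce generation across sessions", {
  cfg <- generatorConfig(resolution = 16, noise_channels = 2, base_width = 2,
                         n_res_blocks = 1)
  set.seed(25)
  gen <- scganGenerator(cfg)
  z <- sampleNoise(1, cfg)
  ref <- imageValues(scganGenerate(gen, z, "dark"))
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(f, gen)
  back <- loadCheckpoint(f)$generator
  expect_identical(imageValues(scganGenerate(back, z, "dark")), ref)
  expect_error(loadCheckpoint(file.path(tempdir(), "missing.rds")), "not found")
})
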