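test_that("tint defaults carry the published triples and blend fractions", {
  m <- tintSpec("medium"); d <- tintSpec("dark")
  expect_equal(m@rgb, c(0.682, 0.439, 0.227))
  expect_equal(m@alpha, 0.40)
  expect_equal(d@rgb, c(0.384, 0.227, 0.094))
  expect_equal(d@alpha, 0.80)
})

test_that("blending is the stated affine map with identity, fixed-point and hand-computed cases", {
  set.seed(51)
  v <- array(runif(6 * 6 * 3 * 3), c(6, 6, 3, 3))
  batch <- ImageBatch(v, "unit")
  # alpha = 0 is the identity
  none <- blendTone(batch, tintSpec("medium", alpha = 0))
  expect_identical(imageValues(none), v)
  # the tint colour is a fixed point for any alpha
  tintImg <- ImageBatch(array(rep(tintSpec("dark")@rgb, each = 16),
                              c(4, 4, 3, 1)), "unit")
  expect_equal(imageValues(blendTone(tintImg, tintSpec("dark"))),
               imageValues(tintImg), tolerance = 1e-12)
  # white blended dark, black blended medium (hand computations)
  white <- ImageBatch(array(1, c(2, 2, 3, 1)), "unit")
  expect_equal(imageValues(blendTone(white, tintSpec("dark")))[1, 1, , 1],
               c(0.5072, 0.3816, 0.2752), tolerance = 1e-12)
  black <- ImageBatch(array(0, c(2, 2, 3, 1)), "unit")
  expect_equal(imageValues(blendTone(black, tintSpec("medium")))[1, 1, , 1],
               c(0.2728, 0.1756, 0.0908), tolerance = 1e-12)
  expect_error(blendTone(ImageBatch(v * 2 - 1, "signed_unit"),
                         tintSpec("dark")), "unit space")
})

test_that("blending contracts toward the tint and preserves per-pixel order", {
  set.seed(52)
  v <- array(runif(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  tint <- tintSpec("dark")
  out <- imageValues(blendTone(ImageBatch(v, "unit"), tint))
  for (c in 1:3) {
    lhs <- abs(out[, , c, ] - tint@rgb[c])
    rhs <- (1 - tint@alpha) * abs(v[, , c, ] - tint@rgb[c])
    expect_equal(lhs, rhs, tolerance = 1e-12)
    # monotone: ordering of two images is preserved within the channel
    expect_identical(out[, , c, 1] <= out[, , c, 2], v[, , c, 1] <= v[, , c, 2])
  }
  # dark-blended batches sit closer to the dark tint than medium-blended ones
  dk <- imageValues(blendTone(ImageBatch(v, "unit"), tintSpec("dark")))
  md <- imageValues(blendTone(ImageBatch(v, "unit"), tintSpec("medium")))
  target <- tintSpec("dark")@rgb
  distTo <- function(x) sqrt(sum((apply(x, 3, mean) - target)^2))
  expect_lt(distTo(dk), distTo(md))
})

test_that("PNG-tree blending writes a parallel tinted tree", {
  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  dir.create(file.path(src, "nv"))
  png::writePNG(array(1, c(4, 4, 3)), file.path(src, "nv", "a.png"))
  n <- blendPngTree(src, dst, "dark")
  expect_identical(n, 1L)
  back <- png::readPNG(file.path(dst, "nv", "a.png"))
  expect_equal(back[1, 1, ], round(c(0.5072, 0.3816, 0.2752) * 255) / 255,
               tolerance = 1e-12)
  expect_error(blendPngTree(withr::local_tempdir(), dst, "dark"), "no PNG")
})
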