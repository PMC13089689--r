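test_that("folder-per-class loading counts files, orders classes lexicographically and resizes", {
  root <- withr::local_tempdir()
  cfg <- fixtureConfig(resolution = 24, counts = c(nv = 3L, bcc = 3L), seed = 2)
  writeFixtureTree(root, cfg)
  # a non-square JPEG must land at the requested square resolution
  jp <- file.path(root, "bcc", "wide.jpg")
  EBImage::writeImage(EBImage::Image(array(runif(60 * 45 * 3), c(60, 45, 3)),
                                     colormode = "Color"), jp, quality = 90)
  ds <- loadLabeledImages(root, resolution = 16)
  expect_s4_class(ds, "LabeledImageSet")
  expect_identical(nImages(ds), 7L)
  expect_identical(classNames(ds), c("bcc", "nv"))   # lexicographic
  expect_identical(imageResolution(ds), c(16L, 16L))
  expect_identical(rangeTag(images(ds)), "raw_u8")
  expect_identical(as.integer(table(lesionLabels(ds))), c(4L, 3L))
  # deterministic ordering
  ds2 <- loadLabeledImages(root, resolution = 16)
  expect_identical(as.character(lesionLabels(ds)), as.character(lesionLabels(ds2)))
  expect_identical(imageValues(images(ds)), imageValues(images(ds2)))
})

test_that("loading errors on missing roots and empty trees", {
  expect_error(loadLabeledImages(file.path(tempdir(), "no-such-dir-xyz")),
               "not found")
  empty <- withr::local_tempdir()
  dir.create(file.path(empty, "mel"))
  expect_error(loadLabeledImages(empty), "no readable")
})

test_that("normalization maps 0..255 onto [-1,1] and toUnitRange inverts it", {
  v <- array(rep(0:255, length.out = 4 * 4 * 3 * 6), c(4, 4, 3, 6))
  nb <- normalizeImage(ImageBatch(v, "raw_u8"))
  expect_identical(rangeTag(nb), "signed_unit")
  expect_equal(range(imageValues(nb)), c(-1, 1))
  expect_equal(imageValues(nb)[1, 1, 1, 1], -1)
  # 128 -> (128/255 - 0.5)/0.5
  expect_equal(imageValues(normalizeImage(
    ImageBatch(array(128, c(1, 1, 3, 1)), "raw_u8")))[1, 1, 1, 1],
    (128 / 255 - 0.5) / 0.5, tolerance = 1e-12)
  # exhaustive round trip over all 256 levels within 1/255
  ub <- toUnitRange(nb)
  expect_identical(rangeTag(ub), "unit")
  expect_lt(max(abs(imageValues(ub) * 255 - v)), 1 / 255 + 1e-9)
  # wrong-range errors
  expect_error(normalizeImage(ub), "raw_u8")
  expect_error(toUnitRange(ub), "signed_unit")
})

test_that("PNG dataset writing round-trips pixels and manifests every image", {
  set.seed(4)
  v <- array(runif(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  out <- withr::local_tempdir()
  man <- writePngDataset(ImageBatch(v, "unit"),
                         labels = c("nv", "nv", "mel", "mel"),
                         tones = c("medium", "dark", "medium", "dark"), out)
  expect_identical(nrow(man), 4L)
  expect_identical(sort(unique(man$tone)), c("dark", "medium"))
  expect_true(all(file.exists(file.path(out, man$filename))))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  for (i in 1:4) {
    back <- png::readPNG(file.path(out, man$filename[i]))
    expect_equal(back, round(v[, , , i] * 255) / 255, tolerance = 1e-12)
  }
  # zero images: empty manifest, no tone/class subdirectories
  out2 <- withr::local_tempdir()
  man0 <- writePngDataset(ImageBatch(array(0, c(4, 4, 3, 0)), "unit"),
                          character(0), character(0), out2)
  expect_identical(nrow(man0), 0L)
  expect_identical(list.dirs(out2, recursive = TRUE, full.names = FALSE), "")
})
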