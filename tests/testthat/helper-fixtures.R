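# shared fixture builders (all data generated in code at test time)

# small tinted, normalised fixture set: tones are separable by mean colour
# because each image is blended with its own tone's tint
tintedFixtureSet <- function(seed = 1L, resolution = 32L,
                             counts = c(akiec = 3L, bcc = 5L, bkl = 11L,
                                        df = 1L, mel = 11L, nv = 67L,
                                        vasc = 1L)) {
  ds <- blendDatasetByTone(simulateDataset(
    fixtureConfig(resolution = resolution, counts = counts, seed = seed)))
  raw <- ImageBatch(round(imageValues(images(ds)) * 255), "raw_u8")
  LabeledImageSet(normalizeImage(raw), lesionLabels(ds),
                  classNames = classNames(ds),
                  tones = as.character(tones(ds)))
}

# deterministic non-image feature matrix for FID tests
gaussFeatures <- function(n, d, mu = 0, sd = 1, seed = 1L, id = "user") {
  set.seed(seed)
  m <- matrix(rnorm(n * d, mu, sd), n, d)
  attr(m, "extractor_id") <- id
  m
}

meanChannel <- function(dir) {
  fs <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                   full.names = TRUE)
  m <- vapply(fs, function(f) apply(png::readPNG(f), 3, mean), numeric(3))
  rowMeans(m)
}
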