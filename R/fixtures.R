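# Dermoscopy-like fixture images: a skin-coloured background plus one
# anti-aliased elliptical lesion with class-dependent morphology. The seven
# classes differ in lesion radius, interior darkness and eccentricity, so
# they are separable by simple image statistics; the two tones differ in
# background colour. Fixtures exist to exercise the pipeline and its
# statistics, not to look clinically real.

#' Configuration of the fixture simulator
#'
#' @param resolution square image size in pixels (>= 16).
#' @param counts named non-negative integer vector, images per lesion class.
#'   Defaults to the seven-class HAM10000 metadata counts divided by 100
#'   (N = 99), a desk-scale stand-in with the same class imbalance.
#' @param backgroundRgb list with elements `medium` and `dark`, each an RGB
#'   triple in \[0, 1\], the skin background per tone.
#' @param seed integer seed; each image derives its own stream from it by
#'   counter, so the dataset is reproducible independent of iteration order.
#' @return A list of class `"FixtureConfig"`.
#' @export
#' @examples
#' cfg <- fixtureConfig(resolution = 24, counts = c(mel = 2, nv = 3), seed = 7)
#' ds <- simulateDataset(cfg)
#' table(lesionLabels(ds))
fixtureConfig <- function(resolution = 32L,
                          counts = c(akiec = 3L, bcc = 5L, bkl = 11L, df = 1L,
                                     mel = 11L, nv = 67L, vasc = 1L),
                          backgroundRgb = list(medium = c(0.85, 0.66, 0.52),
                                               dark = c(0.55, 0.38, 0.26)),
                          seed = 1L) {
  resolution <- as.integer(resolution)
  if (resolution < 16L) stop("resolution must be >= 16")
  if (is.null(names(counts)) || any(counts < 0))
    stop("counts must be a named non-negative vector")
  structure(list(resolution = resolution, counts = counts,
                 backgroundRgb = backgroundRgb, seed = as.integer(seed)),
            class = "FixtureConfig")
}

# per-class morphology: radius fraction of half-width, interior darkness
# (fraction by which the lesion is darker than the background), eccentricity
# and border jitter amplitude. Ordered as lesionClasses().
.fixture_morphology <- function(class_name) {
  m <- list(
    akiec = list(radius = 0.16, darkness = 0.30, ecc = 0.30, jitter = 0.10),
    bcc   = list(radius = 0.22, darkness = 0.40, ecc = 0.15, jitter = 0.12),
    bkl   = list(radius = 0.28, darkness = 0.35, ecc = 0.40, jitter = 0.18),
    df    = list(radius = 0.14, darkness = 0.55, ecc = 0.10, jitter = 0.06),
    mel   = list(radius = 0.38, darkness = 0.65, ecc = 0.35, jitter = 0.25),
    nv    = list(radius = 0.30, darkness = 0.50, ecc = 0.20, jitter = 0.10),
    vasc  = list(radius = 0.20, darkness = 0.45, ecc = 0.50, jitter = 0.08))
  out <- m[[class_name]]
  if (is.null(out)) stop("unknown lesion class: ", class_name)
  out
}

.fixture_image_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

# low-frequency noise field in [-1, 1]: a coarse random grid bilinearly
# upsampled to the target resolution
.lowfreq_noise <- function(res, cells = 5L) {
  g <- matrix(stats::runif(cells * cells, -1, 1), cells, cells)
  as.matrix(EBImage::resize(EBImage::Image(g), w = res, h = res))
}

#' Simulate a single dermoscopy-like fixture image
#'
#' Renders a skin-coloured background with one darker elliptical lesion whose
#' border is perturbed by smooth radial jitter. Deterministic given
#' `(classId, tone, config, counter)`.
#'
#' @param classId lesion class name (one of `names(config$counts)` or any of
#'   \code{\link{lesionClasses}()}).
#' @param tone `"medium"` or `"dark"`.
#' @param config a \code{\link{fixtureConfig}}.
#' @param counter integer image index used to derive the per-image RNG
#'   stream from `config$seed`.
#' @return `H x W x 3` numeric array in \[0, 1\].
#' @export
simulateLesionImage <- function(classId, tone = c("medium", "dark"),
                                config = fixtureConfig(), counter = 1L) {
  tone <- match.arg(tone)
  morph <- .fixture_morphology(classId)
  res <- config$resolution
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.fixture_image_seed(config$seed, counter))

  bg <- config$backgroundRgb[[tone]]
  # pixel grid centred on a jittered lesion centre
  cx <- res / 2 + stats::runif(1, -0.08, 0.08) * res
  cy <- res / 2 + stats::runif(1, -0.08, 0.08) * res
  theta0 <- stats::runif(1, 0, pi)
  r0 <- morph$radius * (res / 2) * stats::runif(1, 0.85, 1.15)
  ecc <- morph$ecc * stats::runif(1, 0.7, 1.3)
  ax <- r0 * (1 + ecc); ay <- r0 / (1 + ecc)

  xs <- matrix(rep(seq_len(res), each = res), res, res)   # column index
  ys <- matrix(rep(seq_len(res), times = res), res, res)  # row index
  dx <- xs - cx; dy <- ys - cy
  xr <- dx * cos(theta0) + dy * sin(theta0)
  yr <- -dx * sin(theta0) + dy * cos(theta0)
  rho <- sqrt((xr / ax)^2 + (yr / ay)^2)                  # 1 on the ellipse
  ang <- atan2(yr, xr)
  # smooth radial border jitter from low-order harmonics
  amp <- morph$jitter
  jit <- 0
  for (h in 2:4)
    jit <- jit + stats::rnorm(1, 0, amp / 2) * cos(h * ang + stats::runif(1, 0, 2 * pi))
  edge <- 1 + jit
  # soft (anti-aliased) mask: 1 inside, 0 outside, ~1.5 px transition
  softness <- 1.5 / r0
  mask <- 1 / (1 + exp((rho - edge) / softness))

  tex <- .lowfreq_noise(res)
  lesion_rgb <- bg * (1 - morph$darkness)
  img <- array(0, c(res, res, 3L))
  for (c in 1:3) {
    base <- bg[c] * (1 + 0.03 * tex)
    les <- lesion_rgb[c] * (1 + 0.10 * tex)
    img[, , c] <- base * (1 - mask) + les * mask
  }
  pmin(pmax(img, 0), 1)
}

#' Simulate a labelled fixture dataset
#'
#' Generates `sum(config$counts)` images, with exactly the requested number
#' per class. Tones are assigned by alternating medium/dark within each class
#' so both tones appear in (near-)equal numbers.
#'
#' @param config a \code{\link{fixtureConfig}} with `sum(counts) >= 1`.
#' @return A \linkS4class{LabeledImageSet} (unit range) with tone labels.
#' @export
simulateDataset <- function(config = fixtureConfig()) {
  counts <- config$counts[order(names(config$counts))]
  if (sum(counts) < 1) stop("all-zero counts: nothing to simulate")
  res <- config$resolution
  n <- sum(counts)
  vals <- array(0, c(res, res, 3L, n))
  labs <- character(n); tns <- character(n)
  i <- 0L
  for (cl in names(counts)) {
    for (j in seq_len(counts[[cl]])) {
      i <- i + 1L
      tone <- toneLevels()[(j - 1L) %% 2L + 1L]
      vals[, , , i] <- simulateLesionImage(cl, tone, config, counter = i)
      labs[i] <- cl; tns[i] <- tone
    }
  }
  LabeledImageSet(ImageBatch(vals, "unit"), labs,
                  classNames = names(counts), tones = tns)
}

#' Write a fixture tree compatible with loadLabeledImages
#'
#' Simulates a dataset and writes it as a `root/<class>/*.png` hierarchy
#' (tones recorded in each filename, since the loader's layout is
#' folder-per-class only).
#'
#' @param rootPath output directory.
#' @param config a \code{\link{fixtureConfig}}.
#' @return Invisibly, the character vector of files written.
#' @export
writeFixtureTree <- function(rootPath, config = fixtureConfig()) {
  ds <- simulateDataset(config)
  dir.create(rootPath, recursive = TRUE, showWarnings = FALSE)
  labs <- as.character(lesionLabels(ds)); tns <- as.character(tones(ds))
  v <- imageValues(images(ds))
  out <- character(nImages(ds))
  for (i in seq_len(nImages(ds))) {
    d <- file.path(rootPath, labs[i])
    dir.create(d, showWarnings = FALSE)
    out[i] <- file.path(d, sprintf("fix_%05d_%s.png", i, tns[i]))
    png::writePNG(v[, , , i], out[i])
  }
  invisible(out)
}
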