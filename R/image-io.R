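#' Load a folder-per-class image dataset
#'
#' Reads a directory tree with one subdirectory per lesion class, each
#' containing PNG/JPEG images, resizes every image to
#' `resolution x resolution` (bilinear) and returns a
#' \linkS4class{LabeledImageSet} in the raw 8-bit range. Class order is the
#' lexicographic order of the subdirectory names and files are read in sorted
#' path order, so two loads of the same tree are identical.
#'
#' Greyscale images are replicated to three channels; an alpha channel, if
#' present, is dropped.
#'
#' @param rootPath dataset root directory.
#' @param resolution target square resolution in pixels (default 128, the
#'   training resolution of the synthesis protocol).
#' @return A \linkS4class{LabeledImageSet} with `rangeTag == "raw_u8"`.
#' @export
#' @examples
#' root <- file.path(tempdir(), "toy-imgfolder")
#' writeFixtureTree(root, fixtureConfig(resolution = 24,
#'   counts = c(mel = 2, nv = 2), seed = 1))
#' ds <- loadLabeledImages(root, resolution = 24)
#' ds
loadLabeledImages <- function(rootPath, resolution = 128L) {
  if (!dir.exists(rootPath)) stop("dataset root not found: ", rootPath)
  resolution <- as.integer(resolution)
  stopifnot(resolution >= 1L)
  classes <- sort(list.dirs(rootPath, recursive = FALSE, full.names = FALSE))
  files <- character(0); labs <- character(0)
  for (cl in classes) {
    f <- sort(list.files(file.path(rootPath, cl),
                         pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                         full.names = TRUE))
    files <- c(files, f); labs <- c(labs, rep(cl, length(f)))
  }
  if (length(files) == 0L)
    stop("no readable PNG/JPEG images under ", rootPath)
  n <- length(files)
  vals <- array(0, c(resolution, resolution, 3L, n))
  for (i in seq_len(n)) {
    img <- tryCatch(EBImage::readImage(files[i]),
                    error = function(e) stop("unreadable image file: ", files[i],
                                             " (", conditionMessage(e), ")", call. = FALSE))
    img <- EBImage::resize(img, w = resolution, h = resolution)
    a <- as.array(img)                      # EBImage: x (width), y (height)[, c]
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
    vals[, , , i] <- aperm(a, c(2L, 1L, 3L))  # to H x W x C
  }
  vals <- pmin(pmax(round(vals * 255), 0), 255)
  LabeledImageSet(ImageBatch(vals, "raw_u8"), labs, classNames = classes)
}

#' Normalize raw 8-bit images to the signed unit range
#'
#' Applies the network input convention `v -> (v/255 - 0.5) / 0.5`, mapping
#' 0..255 onto 256 evenly spaced points of \[-1, 1\].
#'
#' @param batch an \linkS4class{ImageBatch} with `rangeTag == "raw_u8"`.
#' @return An \linkS4class{ImageBatch} with `rangeTag == "signed_unit"`.
#' @export
normalizeImage <- function(batch) {
  stopifnot(is(batch, "ImageBatch"))
  if (rangeTag(batch) != "raw_u8")
    stop("normalizeImage expects a raw_u8 batch, got '", rangeTag(batch), "'")
  ImageBatch((batch@values / 255 - 0.5) / 0.5, "signed_unit")
}

#' Map signed-unit images to the unit range
#'
#' `v -> (v + 1) / 2`, clipped to \[0, 1\]; the inverse of
#' \code{\link{normalizeImage}} up to the 1/255 quantisation. Blending and
#' PNG export are defined in unit space.
#'
#' @param batch an \linkS4class{ImageBatch} with `rangeTag == "signed_unit"`.
#' @return An \linkS4class{ImageBatch} with `rangeTag == "unit"`.
#' @export
toUnitRange <- function(batch) {
  stopifnot(is(batch, "ImageBatch"))
  if (rangeTag(batch) != "signed_unit")
    stop("toUnitRange expects a signed_unit batch, got '", rangeTag(batch), "'")
  ImageBatch(pmin(pmax((batch@values + 1) / 2, 0), 1), "unit")
}

#' Write a tone/class PNG tree with a manifest
#'
#' Writes each image as an 8-bit PNG under `outDir/<tone>/<class>/` and
#' returns (and writes as `manifest.csv`) a manifest with one row per image:
#' `filename` (relative to `outDir`), `class`, `tone`. Re-reading a written
#' file reproduces the 8-bit-quantised pixel values exactly.
#'
#' @param images \linkS4class{ImageBatch} in unit range.
#' @param labels character or factor lesion class per image.
#' @param tones character or factor tone per image.
#' @param outDir output directory (created if needed).
#' @param prefix filename prefix (default `"img"`).
#' @return The manifest `data.frame`, invisibly written to
#'   `file.path(outDir, "manifest.csv")`.
#' @export
writePngDataset <- function(images, labels, tones, outDir, prefix = "img") {
  stopifnot(is(images, "ImageBatch"))
  if (rangeTag(images) != "unit")
    stop("writePngDataset expects a unit-range batch")
  n <- nImages(images)
  labels <- as.character(labels); tones <- as.character(tones)
  if (length(labels) != n || length(tones) != n)
    stop("labels and tones must each have one entry per image")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fn <- character(n)
  for (i in seq_len(n)) {
    d <- file.path(outDir, tones[i], labels[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    fn[i] <- file.path(tones[i], labels[i], sprintf("%s_%05d.png", prefix, i))
    png::writePNG(images@values[, , , i], file.path(outDir, fn[i]))
  }
  manifest <- data.frame(filename = fn, class = labels, tone = tones,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
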