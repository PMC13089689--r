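#' Blend images with a fixed skin-tone tint
#'
#' The post-generation colour step that simulates medium and dark
#' pigmentation: per channel `c`, `out_c = (1 - alpha) * in_c + alpha *
#' rgb_c`. The blend is affine and contracts every pixel toward the tint
#' colour by the factor `1 - alpha`, so the tint itself is a fixed point and
#' per-pixel orderings are preserved. Blending is defined in unit space
#' (the tint triples live in \[0, 1\]), after mapping generator output from
#' \[-1, 1\] with \code{\link{toUnitRange}} and before 8-bit quantisation.
#'
#' @param images \linkS4class{ImageBatch} with `rangeTag == "unit"`.
#' @param tint a \linkS4class{TintSpec} (see \code{\link{tintSpec}}).
#' @return A blended \linkS4class{ImageBatch} in unit range.
#' @export
#' @examples
#' white <- ImageBatch(array(1, c(2, 2, 3, 1)), "unit")
#' imageValues(blendTone(white, tintSpec("dark")))[1, 1, , 1]
#' # 0.2 * 1 + 0.8 * (0.384, 0.227, 0.094)
blendTone <- function(images, tint) {
  stopifnot(is(images, "ImageBatch"), is(tint, "TintSpec"))
  if (rangeTag(images) != "unit")
    stop("blendTone is defined in unit space; got '", rangeTag(images),
         "' (use toUnitRange first)")
  v <- images@values
  a <- tint@alpha
  for (c in 1:3) v[, , c, ] <- (1 - a) * v[, , c, ] + a * tint@rgb[c]
  ImageBatch(v, "unit")
}

#' Blend an existing PNG tree into a tone-tinted parallel tree
#'
#' Reads every PNG under `inDir` (recursively), applies
#' \code{\link{blendTone}} with the given tone's tint, and writes the result
#' to the same relative path under `outDir`.
#'
#' @param inDir input directory of PNGs.
#' @param outDir output directory.
#' @param tone `"medium"` or `"dark"`.
#' @param tint optional \linkS4class{TintSpec} overriding the default for
#'   `tone`.
#' @return Invisibly, the number of files written.
#' @export
blendPngTree <- function(inDir, outDir, tone = c("medium", "dark"),
                         tint = NULL) {
  tone <- match.arg(tone)
  if (is.null(tint)) tint <- tintSpec(tone)
  files <- list.files(inDir, pattern = "\\.png$", recursive = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) stop("no PNG files under ", inDir)
  for (f in files) {
    img <- png::readPNG(file.path(inDir, f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img <- img[, , 1:3, drop = FALSE]
    b <- blendTone(ImageBatch(array(img, c(dim(img), 1L)), "unit"), tint)
    out <- file.path(outDir, f)
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(b@values[, , , 1], out)
  }
  invisible(length(files))
}

#' Tint-blend a labelled dataset according to its tone labels
#'
#' Convenience used when turning fixture data into tone-separable training
#' data: each image is blended with the tint of its own tone label.
#'
#' @param dataset \linkS4class{LabeledImageSet} (unit range) with tone
#'   labels.
#' @return The blended \linkS4class{LabeledImageSet}.
#' @export
blendDatasetByTone <- function(dataset) {
  stopifnot(is(dataset, "LabeledImageSet"), length(tones(dataset)) > 0L)
  v <- imageValues(images(dataset))
  tn <- as.character(tones(dataset))
  for (tone in toneLevels()) {
    sel <- which(tn == tone)
    if (!length(sel)) next
    sub <- ImageBatch(v[, , , sel, drop = FALSE], "unit")
    v[, , , sel] <- imageValues(blendTone(sub, tintSpec(tone)))
  }
  LabeledImageSet(ImageBatch(v, "unit"), lesionLabels(dataset),
                  classNames = classNames(dataset), tones = tn)
}
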