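#' Accessors for ToneGAN data classes
#'
#' `images()`, `lesionLabels()`, `classNames()` and `tones()` extract the
#' components of a \linkS4class{LabeledImageSet}; `imageValues()` and
#' `rangeTag()` those of an \linkS4class{ImageBatch}; `nImages()` and
#' `imageResolution()` work on both; `fidScore()` extracts the scalar from a
#' \linkS4class{FidResult}; `allocationDF()` turns an
#' \linkS4class{AllocationTable} into a data frame shaped like the published
#' per-class allocation table (Class, Medium, Dark).
#'
#' @param x the object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname accessors
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("tones", function(x) standardGeneric("tones"))
#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setGeneric("rangeTag", function(x) standardGeneric("rangeTag"))
#' @rdname accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
#' @rdname accessors
#' @export
setGeneric("imageResolution", function(x) standardGeneric("imageResolution"))
#' @rdname accessors
#' @export
setGeneric("fidScore", function(x) standardGeneric("fidScore"))
#' @rdname accessors
#' @export
setGeneric("allocationDF", function(x) standardGeneric("allocationDF"))

#' @rdname accessors
setMethod("imageValues", "ImageBatch", function(x) x@values)
#' @rdname accessors
setMethod("rangeTag", "ImageBatch", function(x) x@rangeTag)
#' @rdname accessors
setMethod("nImages", "ImageBatch", function(x) dim(x@values)[4])
#' @rdname accessors
setMethod("imageResolution", "ImageBatch", function(x) dim(x@values)[1:2])

#' @rdname accessors
setMethod("images", "LabeledImageSet", function(x) x@images)
#' @rdname accessors
setMethod("lesionLabels", "LabeledImageSet", function(x) x@labels)
#' @rdname accessors
setMethod("classNames", "LabeledImageSet", function(x) x@classNames)
#' @rdname accessors
setMethod("tones", "LabeledImageSet", function(x) x@tones)
#' @rdname accessors
setMethod("nImages", "LabeledImageSet", function(x) nImages(x@images))
#' @rdname accessors
setMethod("imageResolution", "LabeledImageSet", function(x) imageResolution(x@images))

#' @rdname accessors
setMethod("fidScore", "FidResult", function(x) x@fid)

#' @rdname accessors
setMethod("allocationDF", "AllocationTable", function(x)
  data.frame(Class = x@classNames, Medium = x@medium, Dark = x@dark,
             stringsAsFactors = FALSE))

setMethod("show", "ImageBatch", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageBatch: %d image(s), %dx%d, range '%s'\n",
              d[4], d[1], d[2], object@rangeTag))
})

setMethod("show", "LabeledImageSet", function(object) {
  d <- dim(object@images@values)
  cat(sprintf("LabeledImageSet: %d image(s), %dx%d, %d classes\n",
              d[4], d[1], d[2], length(object@classNames)))
  print(table(object@labels))
  if (length(object@tones)) print(table(object@tones))
})

setMethod("show", "TintSpec", function(object) {
  cat(sprintf("TintSpec '%s': rgb = (%.3f, %.3f, %.3f), alpha = %.2f\n",
              object@tone, object@rgb[1], object@rgb[2], object@rgb[3],
              object@alpha))
})

setMethod("show", "AllocationTable", function(object) {
  cat(sprintf("AllocationTable: %d per tone, %d total\n",
              sum(object@medium), sum(object@medium) + sum(object@dark)))
  print(allocationDF(object))
})

setMethod("show", "FidResult", function(object) {
  cat(sprintf("FID = %.4f  (n = %d vs %d, extractor '%s')\n",
              object@fid, object@nA, object@nB, object@extractorId))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("Baseline classification comparison (", object@splitDescription, ")\n",
      sep = "")
  cat(sprintf("  real only       : accuracy %.4f, macro-F1 %.4f\n",
              object@realOnly["accuracy"], object@realOnly["macroF1"]))
  cat(sprintf("  real + synthetic: accuracy %.4f, macro-F1 %.4f\n",
              object@realPlusSynth["accuracy"], object@realPlusSynth["macroF1"]))
})

setMethod("show", "ScganGenerator", function(object) {
  cat(sprintf(
    "ScganGenerator: %dx%d, base width %d, %d residual blocks, %d noise channels\n",
    object@config$resolution, object@config$resolution,
    object@config$base_width, object@config$n_res_blocks,
    object@config$noise_channels))
})

setMethod("show", "ScganDiscriminator", function(object) {
  cat(sprintf("ScganDiscriminator: %dx%d input, base width %d, dual head (patch + tone)\n",
              object@config$resolution, object@config$resolution,
              object@config$base_width))
})
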