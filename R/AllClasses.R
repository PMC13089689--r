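#' @import methods
NULL

#' Ordered lesion-class names of the seven-class dermoscopy taxonomy
#'
#' The seven diagnostic categories of HAM10000-style datasets, in the
#' lexicographic order used throughout the package: actinic keratosis,
#' basal cell carcinoma, benign keratosis-like lesions, dermatofibroma,
#' melanoma, melanocytic nevi and vascular lesions.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' lesionClasses()
lesionClasses <- function() c("akiec", "bcc", "bkl", "df", "mel", "nv", "vasc")

#' Skin-tone levels
#'
#' The two conditioning tones. `medium` is encoded as the one-hot vector
#' `[1, 0]` and `dark` as `[0, 1]`.
#'
#' @return Character vector `c("medium", "dark")`.
#' @export
toneLevels <- function() c("medium", "dark")

#' ImageBatch: a stack of RGB images with a declared value range
#'
#' An `ImageBatch` holds `N` RGB images of one resolution as a numeric
#' `H x W x 3 x N` array together with a `rangeTag` declaring the value
#' convention: `"raw_u8"` (integers in 0..255), `"signed_unit"` (values in
#' \[-1, 1\], the network convention) or `"unit"` (values in \[0, 1\], the
#' blending and PNG convention).
#'
#' @slot values numeric 4-d array, `H x W x 3 x N`.
#' @slot rangeTag character scalar, one of `"raw_u8"`, `"signed_unit"`,
#'   `"unit"`.
#' @export
setClass("ImageBatch", representation(values = "array", rangeTag = "character"))

setValidity("ImageBatch", function(object) {
  v <- object@values
  if (length(dim(v)) != 4L) return("values must be a 4-d array (H x W x C x N)")
  if (dim(v)[3] != 3L) return("images must have 3 colour channels")
  if (!object@rangeTag %in% c("raw_u8", "signed_unit", "unit"))
    return("rangeTag must be raw_u8, signed_unit or unit")
  if (length(v) && anyNA(v)) return("values contain NA")
  if (length(v)) {
    rng <- range(v)
    ok <- switch(object@rangeTag,
      raw_u8      = rng[1] >= 0 && rng[2] <= 255 && all(v == round(v)),
      signed_unit = rng[1] >= -1 - 1e-9 && rng[2] <= 1 + 1e-9,
      unit        = rng[1] >= -1e-9 && rng[2] <= 1 + 1e-9)
    if (!ok) return(sprintf("values outside the declared '%s' range", object@rangeTag))
  }
  TRUE
})

#' Construct an ImageBatch
#'
#' @param values numeric `H x W x 3 x N` array (a single `H x W x 3` image is
#'   promoted to `N = 1`).
#' @param rangeTag declared value range, see \linkS4class{ImageBatch}.
#' @return An \linkS4class{ImageBatch}.
#' @export
ImageBatch <- function(values, rangeTag = c("unit", "signed_unit", "raw_u8")) {
  rangeTag <- match.arg(rangeTag)
  if (length(dim(values)) == 3L) dim(values) <- c(dim(values), 1L)
  new("ImageBatch", values = values, rangeTag = rangeTag)
}

#' LabeledImageSet: images with lesion-class (and optionally tone) labels
#'
#' Couples an \linkS4class{ImageBatch} with a lesion-class factor over a
#' fixed, ordered set of class names, and an optional per-image tone factor
#' over \code{\link{toneLevels}()}.
#'
#' @slot images an \linkS4class{ImageBatch}.
#' @slot labels factor of length `N`, levels equal to `classNames`.
#' @slot classNames ordered character vector of class names.
#' @slot tones factor of length `N` over `c("medium", "dark")`, or length 0
#'   when tones are unknown.
#' @export
setClass("LabeledImageSet", representation(
  images = "ImageBatch", labels = "factor",
  classNames = "character", tones = "factor"))

setValidity("LabeledImageSet", function(object) {
  n <- dim(object@images@values)[4]
  if (length(object@labels) != n) return("one label per image is required")
  if (!identical(levels(object@labels), object@classNames))
    return("label levels must equal classNames (in order)")
  if (anyNA(object@labels)) return("labels contain NA")
  if (length(object@tones)) {
    if (length(object@tones) != n) return("tones must be empty or length N")
    if (!identical(levels(object@tones), toneLevels()))
      return("tone levels must be c('medium', 'dark')")
  }
  TRUE
})

#' Construct a LabeledImageSet
#'
#' @param images an \linkS4class{ImageBatch}.
#' @param labels character or factor of lesion classes, one per image.
#' @param classNames ordered class names; defaults to the sorted unique
#'   labels.
#' @param tones optional character or factor of tones per image.
#' @return A \linkS4class{LabeledImageSet}.
#' @export
LabeledImageSet <- function(images, labels, classNames = NULL, tones = NULL) {
  if (is.null(classNames))
    classNames <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- factor(as.character(labels), levels = classNames)
  tones <- if (is.null(tones)) factor(character(0), levels = toneLevels())
           else factor(as.character(tones), levels = toneLevels())
  new("LabeledImageSet", images = images, labels = labels,
      classNames = classNames, tones = tones)
}

#' TintSpec: a fixed RGB tint with a blend fraction
#'
#' Describes the post-generation colour blend for one tone: the output is
#' `(1 - alpha) * image + alpha * rgb`, applied per channel in unit space.
#'
#' @slot tone `"medium"` or `"dark"`.
#' @slot rgb numeric RGB triple in \[0, 1\].
#' @slot alpha blend fraction in \[0, 1\].
#' @export
setClass("TintSpec", representation(tone = "character", rgb = "numeric",
                                    alpha = "numeric"))

setValidity("TintSpec", function(object) {
  if (!object@tone %in% toneLevels()) return("tone must be 'medium' or 'dark'")
  if (length(object@rgb) != 3L || any(object@rgb < 0 | object@rgb > 1))
    return("rgb must be a triple in [0, 1]")
  if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
    return("alpha must be a scalar in [0, 1]")
  TRUE
})

#' Default or custom tint specification per tone
#'
#' Defaults are the fixed earthy tints of the synthesis protocol: medium tone
#' blends 40\% of RGB (0.682, 0.439, 0.227); dark tone blends 80\% of
#' RGB (0.384, 0.227, 0.094).
#'
#' @param tone `"medium"` or `"dark"`.
#' @param rgb optional RGB triple overriding the default tint.
#' @param alpha optional blend fraction overriding the default.
#' @return A \linkS4class{TintSpec}.
#' @export
#' @examples
#' tintSpec("dark")
tintSpec <- function(tone = c("medium", "dark"), rgb = NULL, alpha = NULL) {
  tone <- match.arg(tone)
  if (is.null(rgb))
    rgb <- if (tone == "medium") c(0.682, 0.439, 0.227) else c(0.384, 0.227, 0.094)
  if (is.null(alpha)) alpha <- if (tone == "medium") 0.40 else 0.80
  new("TintSpec", tone = tone, rgb = rgb, alpha = alpha)
}

#' AllocationTable: per-class synthetic image counts for each tone
#'
#' Holds the number of synthetic images to label with each lesion class, for
#' the medium and the dark tone. By design both tones receive identical
#' per-class counts and each tone sums to `totalPerTone`.
#'
#' @slot classNames ordered class names.
#' @slot medium integer counts per class.
#' @slot dark integer counts per class.
#' @export
setClass("AllocationTable", representation(
  classNames = "character", medium = "integer", dark = "integer"))

setValidity("AllocationTable", function(object) {
  k <- length(object@classNames)
  if (length(object@medium) != k || length(object@dark) != k)
    return("medium and dark must have one count per class")
  if (any(object@medium < 0) || any(object@dark < 0))
    return("counts must be non-negative")
  if (!identical(object@medium, object@dark))
    return("equal tone design: medium and dark counts must match per class")
  TRUE
})

#' FidResult: a Frechet distance between two image-feature distributions
#'
#' @slot fid non-negative scalar distance.
#' @slot nA,nB sizes of the two image sets.
#' @slot extractorId identifier of the feature extractor; FID values are only
#'   comparable within one extractor.
#' @export
setClass("FidResult", representation(fid = "numeric", nA = "integer",
                                     nB = "integer", extractorId = "character"))

setValidity("FidResult", function(object) {
  if (length(object@fid) != 1L || !is.finite(object@fid) || object@fid < -1e-6)
    return("fid must be a finite non-negative scalar")
  TRUE
})

#' ComparisonReport: two-arm baseline classification results
#'
#' Accuracy and macro-averaged F1 on one shared real test split, for a
#' classifier trained on real data only versus real plus synthetic data.
#'
#' @slot realOnly named numeric, `accuracy` and `macroF1`.
#' @slot realPlusSynth named numeric, `accuracy` and `macroF1`.
#' @slot splitDescription how the test split was drawn.
#' @slot seed integer seed of the experiment.
#' @export
setClass("ComparisonReport", representation(
  realOnly = "numeric", realPlusSynth = "numeric",
  splitDescription = "character", seed = "integer"))

setValidity("ComparisonReport", function(object) {
  for (arm in list(object@realOnly, object@realPlusSynth)) {
    if (!all(c("accuracy", "macroF1") %in% names(arm)))
      return("each arm needs named 'accuracy' and 'macroF1'")
    if (any(arm < 0 | arm > 1)) return("metrics must lie in [0, 1]")
  }
  TRUE
})

#' ScganGenerator / ScganDiscriminator: tone-conditioned network wrappers
#'
#' Thin S4 wrappers around the internal layer lists, carrying the
#' configuration needed to rebuild and reuse the network.
#'
#' @slot layers internal layer list.
#' @slot config configuration list (resolution, widths, ...).
#' @rdname ScganModel
#' @export
setClass("ScganGenerator", representation(layers = "list", config = "list"))

#' @rdname ScganModel
#' @slot toneHead global-average-pool linear head parameters (discriminator).
#' @export
setClass("ScganDiscriminator", representation(layers = "list",
                                              toneHead = "list",
                                              advHead = "list",
                                              config = "list"))
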