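# Evaluation layer: feature extraction + Frechet distance between Gaussian
# fits, macro-averaged F1, and the two-arm baseline classification
# experiment. At desk scale the feature extractor is a fixed-seed random
# convolutional embedder; FID values are only comparable within one
# extractor id.

#' Fixed-seed convolutional feature extractor
#'
#' A small untrained convolutional embedder (three stride-2 ReLU blocks and
#' global average pooling) whose weights are drawn once from a fixed seed.
#' Random convolutional features preserve distributional differences well
#' enough for the Frechet statistic's qualitative properties; the
#' `extractorId` records the configuration so that FID values are never
#' compared across extractors.
#'
#' @param dim embedding dimensionality (channels of the last block).
#' @param seed weight seed.
#' @return A list of class `"FeatureExtractor"`.
#' @export
toyFeatureExtractor <- function(dim = 32L, seed = 1234L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  layers <- list(
    .layer_conv(3L, 3L, 8L, 2L, 1L, init_sd = 0.3), .layer_relu(),
    .layer_conv(3L, 8L, 16L, 2L, 1L, init_sd = 0.3), .layer_relu(),
    .layer_conv(3L, 16L, as.integer(dim), 2L, 1L, init_sd = 0.3), .layer_relu())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(layers = layers, dim = as.integer(dim),
                 id = sprintf("toyconv-d%d-seed%d", dim, seed)),
            class = "FeatureExtractor")
}

#' Extract image features
#'
#' Deterministically embeds each image; rows follow image order. Input may be
#' in any declared range (converted to unit internally).
#'
#' @param batch an \linkS4class{ImageBatch} with at least 2 images (a
#'   covariance is fitted downstream).
#' @param extractor a \code{\link{toyFeatureExtractor}}.
#' @return `N x dim` matrix with attribute `extractor_id`.
#' @export
extractFeatures <- function(batch, extractor = toyFeatureExtractor()) {
  stopifnot(is(batch, "ImageBatch"), inherits(extractor, "FeatureExtractor"))
  n <- nImages(batch)
  if (n < 2L) stop("need at least 2 images to characterise a distribution")
  v <- switch(rangeTag(batch),
              unit = batch@values,
              signed_unit = (batch@values + 1) / 2,
              raw_u8 = batch@values / 255)
  out <- matrix(NA_real_, n, extractor$dim)
  step <- 32L
  for (s in seq(1L, n, by = step)) {
    ii <- s:min(s + step - 1L, n)
    f <- .seq_fwd(extractor$layers, v[, , , ii, drop = FALSE])$y
    out[ii, ] <- .gap_fwd(f)$y
  }
  attr(out, "extractor_id") <- extractor$id
  out
}

# principal matrix square root of a symmetric PSD matrix, negative
# eigenvalue dust clipped at zero
.sqrtm_psd <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Frechet distance between two feature distributions
#'
#' Fits a Gaussian (mean, covariance) to each feature matrix and returns
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`. The matrix square
#' root is computed by eigendecomposition of the symmetrised product
#' `S_a^{1/2} S_b S_a^{1/2}` with negative eigenvalues clipped at zero,
#' which is robust on the near-singular covariances of small samples. The
#' statistic is symmetric and zero for identical inputs.
#'
#' @param a,b feature matrices from \code{\link{extractFeatures}}, or plain
#'   matrices with matching column count (then `extractor_id` defaults to
#'   `"user"`).
#' @return A \linkS4class{FidResult}.
#' @export
computeFid <- function(a, b) {
  ida <- attr(a, "extractor_id"); idb <- attr(b, "extractor_id")
  if (is.null(ida)) ida <- "user"
  if (is.null(idb)) idb <- "user"
  if (!identical(ida, idb))
    stop("feature sets come from different extractors: ", ida, " vs ", idb)
  if (ncol(a) != ncol(b)) stop("feature dimensionality mismatch")
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 feature rows per set")
  mua <- colMeans(a); mub <- colMeans(b)
  Sa <- stats::cov(a); Sb <- stats::cov(b)
  Ra <- .sqrtm_psd(Sa)
  M <- Ra %*% Sb %*% Ra
  e <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)
  trsqrt <- sum(sqrt(pmax(e$values, 0)))
  fid <- sum((mua - mub)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * trsqrt
  new("FidResult", fid = max(fid, 0), nA = nrow(a), nB = nrow(b),
      extractorId = ida)
}

#' FID between two PNG directories
#'
#' Loads every PNG under each directory (recursively), embeds both sets with
#' one extractor and returns their Frechet distance.
#'
#' @param dirA,dirB image directories.
#' @param resolution square resolution the images are resized to.
#' @param extractor a \code{\link{toyFeatureExtractor}}.
#' @return A \linkS4class{FidResult}.
#' @export
fidBetweenDirs <- function(dirA, dirB, resolution = 32L,
                           extractor = toyFeatureExtractor()) {
  loadDir <- function(d) {
    files <- sort(list.files(d, pattern = "\\.(png|jpe?g)$", recursive = TRUE,
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) stop("need >= 2 images under ", d)
    vals <- array(0, c(resolution, resolution, 3L, length(files)))
    for (i in seq_along(files)) {
      img <- EBImage::resize(EBImage::readImage(files[i]), w = resolution,
                             h = resolution)
      a <- as.array(img)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
      vals[, , , i] <- aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
    }
    ImageBatch(pmin(pmax(vals, 0), 1), "unit")
  }
  computeFid(extractFeatures(loadDir(dirA), extractor),
             extractFeatures(loadDir(dirB), extractor))
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over all `nClasses` classes. A class with
#' no true and no predicted instances (or any zero-division) contributes
#' F1 = 0, the convention that penalises degenerate predictors.
#'
#' @param yTrue,yPred integer class labels in `0:(nClasses-1)` (or factors
#'   over the same levels), equal length.
#' @param nClasses number of classes.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' macroF1(c(0, 0, 1, 1), c(0, 1, 0, 1), 2)  # symmetric confusion: 0.5
macroF1 <- function(yTrue, yPred, nClasses) {
  if (is.factor(yTrue)) yTrue <- as.integer(yTrue) - 1L
  if (is.factor(yPred)) yPred <- as.integer(yPred) - 1L
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (any(c(yTrue, yPred) < 0) || any(c(yTrue, yPred) >= nClasses))
    stop("labels out of range 0:(nClasses-1)")
  f1 <- numeric(nClasses)
  for (k in seq_len(nClasses) - 1L) {
    tp <- sum(yTrue == k & yPred == k)
    fp <- sum(yTrue != k & yPred == k)
    fn <- sum(yTrue == k & yPred != k)
    f1[k + 1L] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  mean(f1)
}

# ---- small CNN classifier for the baseline experiment ----------------------

.clf_build <- function(nClasses, width = 8L) {
  # He-scaled init: unlike the GAN nets this stack has no normalisation
  # layers, so GAN-style N(0, 0.02) would collapse activations to ~0
  he <- function(cin) sqrt(2 / (9 * cin))
  list(layers = list(
         .layer_conv(3L, 3L, width, 2L, 1L, init_sd = he(3L)), .layer_relu(),
         .layer_conv(3L, width, 2L * width, 2L, 1L, init_sd = he(width)),
         .layer_relu(),
         .layer_conv(3L, 2L * width, 4L * width, 2L, 1L,
                     init_sd = he(2L * width)), .layer_relu()),
       W = matrix(stats::rnorm(4L * width * nClasses, 0, 0.05), 4L * width,
                  nClasses),
       b = numeric(nClasses))
}

.clf_logits <- function(clf, x) {
  f <- .seq_fwd(clf$layers, x)
  g <- .gap_fwd(f$y)
  lin <- .linear_fwd(g$y, clf$W, clf$b)
  list(logits = lin$y, f = f, g = g, lin = lin)
}

.softmaxK <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# trains with mean softmax cross-entropy + Adam; labels are 0-based
.clf_train <- function(clf, x, y01, epochs, batch_size, lr = 1e-3) {
  st <- .adam_init(clf$layers)
  stW <- list(m = clf$W * 0, v = clf$W * 0)
  stB <- list(m = clf$b * 0, v = clf$b * 0)
  n <- dim(x)[4]; t <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in seq_len(ceiling(n / batch_size))) {
      ii <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      xb <- x[, , , ii, drop = FALSE]
      fw <- .clf_logits(clf, xb)
      p <- .softmaxK(fw$logits)
      yb <- y01[ii]
      Y <- matrix(0, length(ii), ncol(p))
      Y[cbind(seq_along(ii), yb + 1L)] <- 1
      dlog <- (p - Y) / length(ii)
      lb <- .linear_bwd(dlog, fw$lin$cache, clf$W)
      dgap <- .gap_bwd(lb$dx, fw$g$cache)
      bb <- .seq_bwd(clf$layers, fw$f$caches, dgap, need_dx = FALSE)
      t <- t + 1L
      r <- .adam_step(clf$layers, bb$grads, st, lr, 0.9, 0.999, t)
      clf$layers <- r$layers; st <- r$state
      for (nm in c("W", "b")) {
        sv <- if (nm == "W") stW else stB
        g <- lb$grads[[nm]]
        sv$m <- 0.9 * sv$m + 0.1 * g
        sv$v <- 0.999 * sv$v + 0.001 * g * g
        clf[[nm]] <- clf[[nm]] - lr * (sv$m / (1 - 0.9^t)) /
          (sqrt(sv$v / (1 - 0.999^t)) + 1e-8)
        if (nm == "W") stW <- sv else stB <- sv
      }
    }
  }
  clf
}

.clf_predict <- function(clf, x) {
  max.col(.clf_logits(clf, x)$logits, ties.method = "first") - 1L
}

#' Two-arm baseline classification experiment
#'
#' Trains two identical small CNN classifiers under identical settings (same
#' seed, initial weights, optimiser, epochs), one on the real training split
#' alone and one on the real training split plus the synthetic images, and
#' evaluates both on the same held-out real test split (stratified by class;
#' synthetic images never enter the test set). Reports accuracy and
#' macro-averaged F1 per arm.
#'
#' @param real \linkS4class{LabeledImageSet}, the real (or fixture-real)
#'   data; any declared range.
#' @param synth \linkS4class{LabeledImageSet} of synthetic images whose
#'   classes are a subset of the real classes, or `NULL` for a pure
#'   real-only comparison (the two arms are then identical).
#' @param epochs,batchSize,testFraction,seed experiment settings.
#' @return A \linkS4class{ComparisonReport}.
#' @export
runBaselineExperiment <- function(real, synth = NULL, epochs = 10L,
                                  batchSize = 8L, testFraction = 0.2,
                                  seed = 1L) {
  stopifnot(is(real, "LabeledImageSet"))
  toUnit <- function(ds) {
    v <- imageValues(images(ds))
    switch(rangeTag(images(ds)), unit = v, signed_unit = (v + 1) / 2,
           raw_u8 = v / 255)
  }
  xr <- toUnit(real)
  yr <- as.integer(lesionLabels(real)) - 1L
  k <- length(classNames(real))
  if (!is.null(synth)) {
    stopifnot(is(synth, "LabeledImageSet"))
    if (!all(unique(as.character(lesionLabels(synth))) %in% classNames(real)))
      stop("synthetic classes must be a subset of the real classes")
    xs <- toUnit(synth)
    ys <- as.integer(factor(as.character(lesionLabels(synth)),
                            levels = classNames(real))) - 1L
  }

  set.seed(seed)
  test <- integer(0)                          # stratified hold-out
  for (cl in seq_len(k) - 1L) {
    ii <- which(yr == cl)
    ntest <- max(1L, round(length(ii) * testFraction))
    if (length(ii) > 1L) test <- c(test, sample(ii, min(ntest, length(ii) - 1L)))
  }
  train <- setdiff(seq_along(yr), test)

  runArm <- function(x, y) {
    set.seed(seed)                            # identical init + batching
    clf <- .clf_build(k)
    clf <- .clf_train(clf, x, y, epochs, batchSize)
    pred <- .clf_predict(clf, xr[, , , test, drop = FALSE])
    c(accuracy = mean(pred == yr[test]),
      macroF1 = macroF1(yr[test], pred, k))
  }

  armA <- runArm(xr[, , , train, drop = FALSE], yr[train])
  if (is.null(synth) || nImages(synth) == 0L) {
    armB <- armA
  } else {
    xb <- array(0, c(dim(xr)[1:3], length(train) + length(ys)))
    xb[, , , seq_along(train)] <- xr[, , , train, drop = FALSE]
    xb[, , , length(train) + seq_along(ys)] <- xs
    armB <- runArm(xb, c(yr[train], ys))
  }

  new("ComparisonReport", realOnly = armA, realPlusSynth = armB,
      splitDescription = sprintf("stratified %d/%d real train/test split",
                                 length(train), length(test)),
      seed = as.integer(seed))
}
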