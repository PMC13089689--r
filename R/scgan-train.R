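#' Least-squares adversarial loss
#'
#' Mean squared difference between a PatchGAN prediction map and the constant
#' target map (1 for real, 0 for fake).
#'
#' @param predMap numeric array/vector of patch predictions (non-empty).
#' @param target 0 or 1.
#' @return Scalar loss.
#' @export
#' @examples
#' adversarialLoss(array(0.5, c(2, 2, 1, 1)), target = 1)  # (1 - 0.5)^2
adversarialLoss <- function(predMap, target) {
  if (length(predMap) == 0L) stop("empty prediction map")
  if (!target %in% c(0, 1)) stop("target must be 0 (fake) or 1 (real)")
  mean((predMap - target)^2)
}

#' Tone classification loss (softmax cross-entropy)
#'
#' Mean cross-entropy of the 2-class tone logits against integer labels.
#'
#' @param toneLogits `N x 2` numeric matrix.
#' @param toneLabels integer labels in `{0, 1}` (0 = medium, 1 = dark), or a
#'   character/factor vector of tone names.
#' @return Scalar loss.
#' @export
#' @examples
#' toneClassLoss(matrix(0, 1, 2), 0)  # log(2)
toneClassLoss <- function(toneLogits, toneLabels) {
  toneLogits <- as.matrix(toneLogits)
  if (ncol(toneLogits) != 2L) stop("tone logits must have exactly 2 columns")
  if (is.character(toneLabels) || is.factor(toneLabels))
    toneLabels <- as.integer(factor(as.character(toneLabels),
                                    levels = toneLevels())) - 1L
  if (length(toneLabels) != nrow(toneLogits))
    stop("one label per logit row is required")
  if (anyNA(toneLabels) || any(!toneLabels %in% c(0L, 1L)))
    stop("tone labels must be 0/1 (or 'medium'/'dark')")
  m <- apply(toneLogits, 1L, max)
  lse <- m + log(rowSums(exp(toneLogits - m)))
  mean(lse - toneLogits[cbind(seq_along(toneLabels), toneLabels + 1L)])
}

# softmax probabilities and CE gradient wrt logits (mean reduction)
.softmax2 <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

.ce_grad <- function(logits, labels01) {
  p <- .softmax2(logits)
  y <- cbind(labels01 == 0L, labels01 == 1L) + 0
  (p - y) / nrow(logits)
}

#' L1 reconstruction loss
#'
#' Mean absolute difference between two equal-shaped image batches.
#'
#' @param fake,realRef numeric arrays (or \linkS4class{ImageBatch}es) of
#'   identical shape.
#' @return Scalar loss.
#' @export
reconstructionLoss <- function(fake, realRef) {
  if (is(fake, "ImageBatch")) fake <- fake@values
  if (is(realRef, "ImageBatch")) realRef <- realRef@values
  if (!identical(dim(fake), dim(realRef)))
    stop("shape mismatch between fake and reference batches")
  mean(abs(fake - realRef))
}

#' Random tone assignment
#'
#' Draws i.i.d. uniform tones over `{medium, dark}` from the current RNG
#' state; used both for generator conditioning during training and for real
#' images whose datasets carry no tone labels.
#'
#' @param n number of tones to draw (>= 1).
#' @return Character vector of tones.
#' @export
assignRandomTones <- function(n) {
  stopifnot(n >= 1L)
  sample(toneLevels(), n, replace = TRUE)
}

#' Training configuration
#'
#' Defaults follow the published optimisation strategy: Adam with learning
#' rate 2e-4, beta1 = 0.5, beta2 = 0.999, 100 epochs; the loss weights
#' (adversarial 1, tone cross-entropy 1, L1 reconstruction 10) follow the
#' established convention for reconstruction-regularised GANs.
#'
#' @param learning_rate Adam step size (> 0).
#' @param beta1,beta2 Adam moment decays in \[0, 1).
#' @param epochs number of passes over the data (>= 1).
#' @param batch_size minibatch size.
#' @param lambda_adv,lambda_cls,lambda_rec non-negative loss weights.
#' @param seed integer RNG seed for the full run.
#' @return A validated configuration list.
#' @export
trainConfig <- function(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                        epochs = 100L, batch_size = 16L,
                        lambda_adv = 1, lambda_cls = 1, lambda_rec = 10,
                        seed = 1L) {
  stopifnot(learning_rate > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            epochs >= 1L, batch_size >= 1L,
            lambda_adv >= 0, lambda_cls >= 0, lambda_rec >= 0)
  list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
       epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lambda_adv = lambda_adv, lambda_cls = lambda_cls,
       lambda_rec = lambda_rec, seed = as.integer(seed))
}

#' Train the tone-conditioned GAN
#'
#' Alternates one discriminator and one generator update per minibatch. The
#' discriminator minimises least-squares adversarial loss (real -> 1,
#' detached fake -> 0) plus `lambda_cls` times the tone cross-entropy on real
#' images; the generator minimises adversarial loss (fake -> 1) plus
#' `lambda_cls` times the tone cross-entropy of its fakes against the
#' conditioning tone plus `lambda_rec` times the L1 distance between each
#' fake and the real image at the same batch index. Tone conditions for fakes
#' are drawn uniformly at random per batch; real images use their own tone
#' labels when the dataset carries them, otherwise randomly assigned ones.
#'
#' @param generator \linkS4class{ScganGenerator}.
#' @param discriminator \linkS4class{ScganDiscriminator} (same config).
#' @param dataset \linkS4class{LabeledImageSet} whose images are in
#'   signed-unit range.
#' @param config a \code{\link{trainConfig}}.
#' @param checkpointPath optional path; when given, a checkpoint is saved at
#'   the end of training.
#' @param verbose log per-epoch losses to stderr.
#' @return List with `generator`, `discriminator` (trained) and `history`, a
#'   per-epoch data frame of the loss terms `d_adv`, `d_tone`, `g_adv`,
#'   `g_tone`, `g_rec`, `d_total`, `g_total`.
#' @export
scganTrain <- function(generator, discriminator, dataset,
                       config = trainConfig(), checkpointPath = NULL,
                       verbose = FALSE) {
  stopifnot(is(generator, "ScganGenerator"),
            is(discriminator, "ScganDiscriminator"),
            is(dataset, "LabeledImageSet"))
  if (rangeTag(images(dataset)) != "signed_unit")
    stop("training expects signed_unit images (see normalizeImage)")
  n <- nImages(dataset)
  if (n < 1L) stop("empty dataset")
  xall <- imageValues(images(dataset))
  toneLab <- if (length(tones(dataset))) as.character(tones(dataset)) else NULL
  cfg <- config
  set.seed(cfg$seed)

  gl <- generator@layers
  dl <- discriminator@layers
  advH <- discriminator@advHead
  toneH <- discriminator@toneHead
  gstate <- .adam_init(gl)
  dstate <- .adam_init(dl)
  advM <- lapply(advH$conv$params, function(p) list(m = p * 0, v = p * 0))
  toneM <- lapply(toneH, function(p) list(m = p * 0, v = p * 0))

  hist <- data.frame(epoch = seq_len(cfg$epochs), d_adv = NA_real_,
                     d_tone = NA_real_, g_adv = NA_real_, g_tone = NA_real_,
                     g_rec = NA_real_, d_total = NA_real_, g_total = NA_real_)
  tstep <- 0L

  adam_upd <- function(p, g, st, t) {
    st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
    st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g * g
    p <- p - cfg$learning_rate * (st$m / (1 - cfg$beta1^t)) /
      (sqrt(st$v / (1 - cfg$beta2^t)) + 1e-8)
    list(p = p, st = st)
  }

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    acc <- c(d_adv = 0, d_tone = 0, g_adv = 0, g_tone = 0, g_rec = 0)
    for (b in seq_len(nb)) {
      ii <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      xr <- xall[, , , ii, drop = FALSE]
      m <- length(ii)
      tReal <- if (is.null(toneLab)) assignRandomTones(m) else toneLab[ii]
      tFake <- assignRandomTones(m)
      z <- sampleNoise(m, generator@config)

      genT <- new("ScganGenerator", layers = gl, config = generator@config)
      discT <- new("ScganDiscriminator", layers = dl, advHead = advH,
                   toneHead = toneH, config = discriminator@config)

      ## ---- discriminator step (fake detached) ----
      fake <- .gen_forward(genT, z, tFake)$y
      fwR <- .disc_forward(discT, xr, tReal)
      fwF <- .disc_forward(discT, fake, tFake)
      treal01 <- as.integer(factor(tReal, levels = toneLevels())) - 1L
      lossDadv <- adversarialLoss(fwR$adv, 1) + adversarialLoss(fwF$adv, 0)
      lossDtone <- toneClassLoss(fwR$logits, treal01)
      dadvR <- cfg$lambda_adv * 2 * (fwR$adv - 1) / length(fwR$adv)
      dadvF <- cfg$lambda_adv * 2 * fwF$adv / length(fwF$adv)
      dlogR <- cfg$lambda_cls * .ce_grad(fwR$logits, treal01)
      bR <- .disc_backward(discT, fwR, dadvR, dlogR)
      bF <- .disc_backward(discT, fwF, dadvF, matrix(0, m, 2L))
      tstep <- tstep + 1L
      gsum <- .grads_add(bR$backbone, bF$backbone)
      r <- .adam_step(dl, gsum, dstate, cfg$learning_rate, cfg$beta1,
                      cfg$beta2, tstep)
      dl <- r$layers; dstate <- r$state
      for (nm in names(advH$conv$params)) {
        u <- adam_upd(advH$conv$params[[nm]],
                      bR$adv[[nm]] + bF$adv[[nm]], advM[[nm]], tstep)
        advH$conv$params[[nm]] <- u$p; advM[[nm]] <- u$st
      }
      for (nm in names(toneH)) {
        u <- adam_upd(toneH[[nm]], bR$tone[[nm]] + bF$tone[[nm]],
                      toneM[[nm]], tstep)
        toneH[[nm]] <- u$p; toneM[[nm]] <- u$st
      }

      ## ---- generator step ----
      discT <- new("ScganDiscriminator", layers = dl, advHead = advH,
                   toneHead = toneH, config = discriminator@config)
      gfw <- .gen_forward(genT, z, tFake)
      fake <- gfw$y
      fwG <- .disc_forward(discT, fake, tFake)
      tfake01 <- as.integer(factor(tFake, levels = toneLevels())) - 1L
      lossGadv <- adversarialLoss(fwG$adv, 1)
      lossGtone <- toneClassLoss(fwG$logits, tfake01)
      lossGrec <- reconstructionLoss(fake, xr)
      dadvG <- cfg$lambda_adv * 2 * (fwG$adv - 1) / length(fwG$adv)
      dlogG <- cfg$lambda_cls * .ce_grad(fwG$logits, tfake01)
      bG <- .disc_backward(discT, fwG, dadvG, dlogG, need_dx = TRUE)
      dfake <- bG$dimg + cfg$lambda_rec * sign(fake - xr) / length(fake)
      gb <- .seq_bwd(gl, gfw$caches, dfake, need_dx = FALSE)
      r <- .adam_step(gl, gb$grads, gstate, cfg$learning_rate, cfg$beta1,
                      cfg$beta2, tstep)
      gl <- r$layers; gstate <- r$state

      losses <- c(lossDadv, lossDtone, lossGadv, lossGtone, lossGrec)
      if (any(!is.finite(losses)))
        stop(sprintf("non-finite loss at epoch %d, batch %d (d_adv=%.3g, d_tone=%.3g, g_adv=%.3g, g_tone=%.3g, g_rec=%.3g)",
                     ep, b, lossDadv, lossDtone, lossGadv, lossGtone, lossGrec))
      acc <- acc + losses
    }
    acc <- acc / nb
    hist[ep, 2:8] <- c(acc, acc["d_adv"] + cfg$lambda_cls * acc["d_tone"],
                       acc["g_adv"] + cfg$lambda_cls * acc["g_tone"] +
                         cfg$lambda_rec * acc["g_rec"])
    if (verbose)
      message(sprintf("epoch %3d | D adv %.4f tone %.4f | G adv %.4f tone %.4f rec %.4f",
                      ep, acc["d_adv"], acc["d_tone"], acc["g_adv"],
                      acc["g_tone"], acc["g_rec"]))
  }

  genOut <- new("ScganGenerator", layers = gl, config = generator@config)
  discOut <- new("ScganDiscriminator", layers = dl, advHead = advH,
                 toneHead = toneH, config = discriminator@config)
  if (!is.null(checkpointPath))
    saveCheckpoint(checkpointPath, genOut, discOut, hist)
  list(generator = genOut, discriminator = discOut, history = hist)
}

#' Tone-head accuracy of a trained discriminator
#'
#' Fraction of images whose tone the discriminator's classification head
#' predicts correctly, evaluated exactly as in training (image concatenated
#' with its own tone condition map).
#'
#' @param discriminator \linkS4class{ScganDiscriminator}.
#' @param dataset \linkS4class{LabeledImageSet} with tone labels, images in
#'   signed-unit range.
#' @return Accuracy in \[0, 1\].
#' @export
toneHeadAccuracy <- function(discriminator, dataset) {
  stopifnot(is(dataset, "LabeledImageSet"), length(tones(dataset)) > 0L)
  tn <- as.character(tones(dataset))
  out <- scganDiscriminate(discriminator, images(dataset), tn)
  pred <- toneLevels()[max.col(out$toneLogits, ties.method = "first")]
  mean(pred == tn)
}
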