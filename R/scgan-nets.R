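#' One-hot encoding of skin tones
#'
#' `medium` maps to `[1, 0]` and `dark` to `[0, 1]`.
#'
#' @param tone character or factor vector of tones.
#' @return `length(tone) x 2` numeric matrix of one-hot rows.
#' @export
#' @examples
#' toneOneHot(c("medium", "dark"))
toneOneHot <- function(tone) {
  tone <- as.character(tone)
  bad <- !tone %in% toneLevels()
  if (any(bad)) stop("unknown tone(s): ", paste(unique(tone[bad]), collapse = ", "))
  cbind(medium = as.numeric(tone == "medium"),
        dark = as.numeric(tone == "dark"))
}

#' Broadcast a tone one-hot vector over spatial dimensions
#'
#' Produces the 2-channel condition map that is concatenated channel-wise
#' with the generator's noise tensor and with the discriminator's input
#' image: channel `c` is constant at the `c`-th one-hot component.
#'
#' @param tone a single tone (`"medium"` or `"dark"`).
#' @param height,width spatial size of the map (>= 1).
#' @return `height x width x 2` numeric array.
#' @export
#' @examples
#' broadcastTone("dark", 2, 2)[1, 1, ]
broadcastTone <- function(tone, height, width) {
  oh <- toneOneHot(tone)
  stopifnot(nrow(oh) == 1L, height >= 1L, width >= 1L)
  array(rep(oh[1, ], each = height * width), c(height, width, 2L))
}

# batch version: (H, W, 2, N) condition stack for a tone vector
.tone_maps <- function(tone, height, width) {
  oh <- toneOneHot(tone)
  out <- array(0, c(height, width, 2L, nrow(oh)))
  for (i in seq_len(nrow(oh)))
    out[, , , i] <- array(rep(oh[i, ], each = height * width), c(height, width, 2L))
  out
}

#' Generator configuration
#'
#' The generator is fully convolutional: an initial 7x7 block, two stride-2
#' downsampling blocks that double the width, `n_res_blocks` residual blocks
#' at the bottleneck, two transposed-convolution upsampling blocks, and a
#' final 7x7 convolution with Tanh. Instance normalisation is used everywhere
#' except the first and last block.
#'
#' @param resolution output resolution in pixels, divisible by 4 (default
#'   128, the protocol's training resolution).
#' @param noise_channels channels of the spatial noise tensor (default 8).
#' @param base_width channel count of the first convolution (default 64).
#' @param n_res_blocks number of residual blocks (default 6).
#' @return A validated configuration list.
#' @export
generatorConfig <- function(resolution = 128L, noise_channels = 8L,
                            base_width = 64L, n_res_blocks = 6L) {
  resolution <- as.integer(resolution)
  if (resolution %% 4L != 0L)
    stop("resolution must be divisible by 4 (two stride-2 halvings)")
  stopifnot(noise_channels >= 1L, base_width >= 1L, n_res_blocks >= 0L)
  list(resolution = resolution, noise_channels = as.integer(noise_channels),
       base_width = as.integer(base_width), n_res_blocks = as.integer(n_res_blocks))
}

#' Build a tone-conditioned generator
#'
#' Input is an `N x noise_channels x H x W` standard-normal noise tensor
#' concatenated channel-wise with the broadcast 2-channel tone condition, so
#' the first convolution sees `noise_channels + 2` channels.
#'
#' @param config a \code{\link{generatorConfig}}; weights are initialised
#'   from N(0, 0.02) using the current RNG state.
#' @return An \linkS4class{ScganGenerator}.
#' @export
scganGenerator <- function(config = generatorConfig()) {
  w <- config$base_width
  nin <- config$noise_channels + 2L
  layers <- c(
    list(.layer_conv(7L, nin, w, 1L, 3L), .layer_relu(),
         .layer_conv(3L, w, 2L * w, 2L, 1L), .layer_inorm(), .layer_relu(),
         .layer_conv(3L, 2L * w, 4L * w, 2L, 1L), .layer_inorm(), .layer_relu()),
    lapply(seq_len(config$n_res_blocks), function(i) .layer_res(4L * w)),
    list(.layer_upzero(), .layer_conv(3L, 4L * w, 2L * w, 1L, 0L),
         .layer_inorm(), .layer_relu(),
         .layer_upzero(), .layer_conv(3L, 2L * w, w, 1L, 0L),
         .layer_inorm(), .layer_relu(),
         .layer_conv(7L, w, 3L, 1L, 3L), .layer_tanh()))
  new("ScganGenerator", layers = layers, config = config)
}

#' Sample a spatial noise tensor
#'
#' I.i.d. standard-normal noise of shape `resolution x resolution x
#' noise_channels x n`, drawn from the current RNG state.
#'
#' @param n batch size.
#' @param config the matching \code{\link{generatorConfig}}.
#' @return 4-d numeric array.
#' @export
sampleNoise <- function(n, config = generatorConfig()) {
  r <- config$resolution
  array(stats::rnorm(r * r * config$noise_channels * n),
        c(r, r, config$noise_channels, n))
}

# internal forward with caches (training needs them)
.gen_forward <- function(gen, noise, tone) {
  d <- dim(noise)
  cfg <- gen@config
  if (d[1] != cfg$resolution || d[2] != cfg$resolution ||
      d[3] != cfg$noise_channels)
    stop("noise tensor shape does not match the generator configuration")
  if (length(tone) != d[4])
    stop("tone batch length (", length(tone), ") != noise batch length (", d[4], ")")
  x <- array(0, c(d[1], d[2], cfg$noise_channels + 2L, d[4]))
  x[, , seq_len(cfg$noise_channels), ] <- noise
  x[, , cfg$noise_channels + (1:2), ] <- .tone_maps(tone, d[1], d[2])
  .seq_fwd(gen@layers, x)
}

#' Generate images from noise and tones
#'
#' Deterministic given the generator weights and inputs. Output values lie in
#' \[-1, 1\] (final Tanh).
#'
#' @param gen an \linkS4class{ScganGenerator}.
#' @param noise a noise tensor from \code{\link{sampleNoise}}.
#' @param tone tone per sample (length = batch size).
#' @return An \linkS4class{ImageBatch} with `rangeTag == "signed_unit"`.
#' @export
scganGenerate <- function(gen, noise, tone) {
  stopifnot(is(gen, "ScganGenerator"))
  ImageBatch(.gen_forward(gen, noise, tone)$y, "signed_unit")
}

#' Build the dual-headed patch discriminator
#'
#' A shared backbone of four stride-2 convolution blocks (leaky-ReLU 0.2,
#' instance norm after the first block) over the 5-channel input (image plus
#' broadcast tone condition) feeds two heads: a 1-channel convolution
#' producing the PatchGAN real/fake map, and a global-average-pool plus
#' linear layer producing the 2-class tone logits.
#'
#' @param config a \code{\link{generatorConfig}} (shares resolution and
#'   base_width); resolution must be divisible by 16.
#' @return An \linkS4class{ScganDiscriminator}.
#' @export
scganDiscriminator <- function(config = generatorConfig()) {
  if (config$resolution %% 16L != 0L)
    stop("discriminator needs a resolution divisible by 16 (four halvings)")
  w <- config$base_width
  layers <- list(
    .layer_conv(4L, 5L, w, 2L, 1L), .layer_lrelu(),
    .layer_conv(4L, w, 2L * w, 2L, 1L), .layer_inorm(), .layer_lrelu(),
    .layer_conv(4L, 2L * w, 4L * w, 2L, 1L), .layer_inorm(), .layer_lrelu(),
    .layer_conv(4L, 4L * w, 8L * w, 2L, 1L), .layer_inorm(), .layer_lrelu())
  advHead <- list(conv = .layer_conv(3L, 8L * w, 1L, 1L, 1L))
  toneHead <- list(W = matrix(stats::rnorm(8L * w * 2L, 0, 0.02), 8L * w, 2L),
                   b = numeric(2L))
  new("ScganDiscriminator", layers = layers, advHead = advHead,
      toneHead = toneHead, config = config)
}

# forward with caches; input x is (H, W, 3, N) signed-unit values
.disc_forward <- function(disc, x, tone) {
  d <- dim(x)
  cfg <- disc@config
  if (d[1] != cfg$resolution || d[2] != cfg$resolution || d[3] != 3L)
    stop("image shape does not match the discriminator configuration")
  if (length(tone) != d[4])
    stop("tone batch length (", length(tone), ") != image batch length (", d[4], ")")
  xin <- array(0, c(d[1], d[2], 5L, d[4]))
  xin[, , 1:3, ] <- x
  xin[, , 4:5, ] <- .tone_maps(tone, d[1], d[2])
  bk <- .seq_fwd(disc@layers, xin)
  adv <- .conv_fwd(bk$y, disc@advHead$conv$params$W, disc@advHead$conv$params$b,
                   1L, 1L)
  gap <- .gap_fwd(bk$y)
  lin <- .linear_fwd(gap$y, disc@toneHead$W, disc@toneHead$b)
  list(adv = adv$y, logits = lin$y,
       caches = list(bk = bk$caches, adv = adv$cache, gap = gap$cache,
                     lin = lin$cache))
}

# backward: dadv is gradient at the patch map, dlogits at the tone logits.
# Returns grads for backbone layers, advHead, toneHead and (optionally) the
# gradient at the input image channels.
.disc_backward <- function(disc, fw, dadv, dlogits, need_dx = FALSE) {
  advb <- .conv_bwd(dadv, fw$caches$adv, disc@advHead$conv$params$W, TRUE)
  linb <- .linear_bwd(dlogits, fw$caches$lin, disc@toneHead$W)
  dgap <- .gap_bwd(linb$dx, fw$caches$gap)
  dfeat <- advb$dx + dgap
  bkb <- .seq_bwd(disc@layers, fw$caches$bk, dfeat, need_dx = need_dx)
  dimg <- NULL
  if (need_dx) dimg <- bkb$dx[, , 1:3, , drop = FALSE]
  list(backbone = bkb$grads, adv = advb$grads, tone = linb$grads, dimg = dimg)
}

#' Apply the discriminator
#'
#' @param disc an \linkS4class{ScganDiscriminator}.
#' @param image \linkS4class{ImageBatch} in signed-unit range at the
#'   configured resolution.
#' @param tone tone per sample.
#' @return List with `advMap` (`h x w x 1 x N` patch logits, `h = w =
#'   resolution/16`) and `toneLogits` (`N x 2`).
#' @export
scganDiscriminate <- function(disc, image, tone) {
  stopifnot(is(disc, "ScganDiscriminator"), is(image, "ImageBatch"))
  if (rangeTag(image) != "signed_unit")
    stop("discriminator expects signed_unit images")
  fw <- .disc_forward(disc, image@values, tone)
  list(advMap = fw$adv, toneLogits = fw$logits)
}

#' Save / load a model checkpoint
#'
#' Stores generator (and optionally discriminator) weights together with the
#' configuration, so generation is reproducible across sessions.
#'
#' @param path file path (`.rds`).
#' @param generator an \linkS4class{ScganGenerator}.
#' @param discriminator optional \linkS4class{ScganDiscriminator}.
#' @param history optional training loss record.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns a list with elements `generator`, `discriminator`, `history`.
#' @export
saveCheckpoint <- function(path, generator, discriminator = NULL,
                           history = NULL) {
  stopifnot(is(generator, "ScganGenerator"))
  saveRDS(list(config = generator@config, gen_layers = generator@layers,
               disc = if (!is.null(discriminator))
                 list(layers = discriminator@layers,
                      advHead = discriminator@advHead,
                      toneHead = discriminator@toneHead),
               history = history),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  gen <- new("ScganGenerator", layers = ck$gen_layers, config = ck$config)
  disc <- NULL
  if (!is.null(ck$disc))
    disc <- new("ScganDiscriminator", layers = ck$disc$layers,
                advHead = ck$disc$advHead, toneHead = ck$disc$toneHead,
                config = ck$config)
  list(generator = gen, discriminator = disc, history = ck$history)
}
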