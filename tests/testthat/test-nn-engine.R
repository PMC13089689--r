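# analytic backprop of every layer type is validated against central finite
# differences on tiny tensors

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

relErr <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))

ns <- asNamespace("ToneGAN")

test_that("convolution gradients match finite differences at stride 1 and 2", {
  set.seed(11)
  for (s in c(1L, 2L)) {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    L <- ns$.layer_conv(3L, 2L, 3L, s, 1L)
    loss <- function(v) {
      r <- ns$.conv_fwd(array(v, dim(x)), L$params$W, L$params$b, s, 1L)
      sum(r$y^2) / 2
    }
    fw <- ns$.conv_fwd(x, L$params$W, L$params$b, s, 1L)
    bw <- ns$.conv_bwd(fw$y, fw$cache, L$params$W)
    expect_lt(relErr(bw$dx, array(num_grad(loss, as.vector(x)), dim(x))), 1e-5)
    lossW <- function(v) {
      r <- ns$.conv_fwd(x, array(v, dim(L$params$W)), L$params$b, s, 1L)
      sum(r$y^2) / 2
    }
    expect_lt(relErr(bw$grads$W,
                     array(num_grad(lossW, as.vector(L$params$W)),
                           dim(L$params$W))), 1e-5)
  }
})

test_that("a deep mixed stack (conv, res, inorm, upzero, tanh) backpropagates correctly", {
  set.seed(12)
  layers <- list(ns$.layer_conv(3L, 2L, 4L, 2L, 1L), ns$.layer_lrelu(),
                 ns$.layer_res(4L), ns$.layer_inorm(), ns$.layer_relu(),
                 ns$.layer_upzero(), ns$.layer_conv(3L, 4L, 2L, 1L, 0L),
                 ns$.layer_tanh())
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  loss <- function(v) sum(ns$.seq_fwd(layers, array(v, dim(x)))$y^2) / 2
  fw <- ns$.seq_fwd(layers, x)
  bw <- ns$.seq_bwd(layers, fw$caches, fw$y)
  expect_lt(relErr(bw$dx, array(num_grad(loss, as.vector(x)), dim(x))), 1e-5)
  # weight gradient inside the residual block
  Wref <- layers[[3]]$layers[[1]]$params$W
  lossW <- function(v) {
    l2 <- layers
    l2[[3]]$layers[[1]]$params$W <- array(v, dim(Wref))
    sum(ns$.seq_fwd(l2, x)$y^2) / 2
  }
  expect_lt(relErr(bw$grads[[3]][[1]]$W,
                   array(num_grad(lossW, as.vector(Wref)), dim(Wref))), 1e-4)
})

test_that("transposed convolution doubles the spatial size", {
  set.seed(13)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  u <- ns$.upzero_fwd(x)
  L <- ns$.layer_conv(3L, 2L, 3L, 1L, 0L)
  y <- ns$.conv_fwd(u$y, L$params$W, L$params$b, 1L, 0L)$y
  expect_identical(dim(y)[1:2], c(10L, 10L))
})

test_that("gradient accumulation across two backward passes preserves layer alignment", {
  set.seed(14)
  layers <- list(ns$.layer_conv(3L, 2L, 3L, 2L, 1L), ns$.layer_lrelu(),
                 ns$.layer_conv(3L, 3L, 4L, 2L, 1L), ns$.layer_inorm(),
                 ns$.layer_lrelu())
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  fw <- ns$.seq_fwd(layers, x)
  b1 <- ns$.seq_bwd(layers, fw$caches, fw$y)
  b2 <- ns$.seq_bwd(layers, fw$caches, 2 * fw$y)
  s <- ns$.grads_add(b1$grads, b2$grads)
  expect_equal(s[[1]]$W, 3 * b1$grads[[1]]$W, tolerance = 1e-12)
  expect_equal(s[[3]]$b, 3 * b1$grads[[3]]$b, tolerance = 1e-12)
  expect_null(s[[2]])
})

test_that("Adam updates move parameters opposite to the gradient sign", {
  set.seed(15)
  layers <- list(ns$.layer_conv(3L, 1L, 1L, 1L, 1L))
  st <- ns$.adam_init(layers)
  g <- list(list(W = array(1, dim(layers[[1]]$params$W)), b = 1))
  r <- ns$.adam_step(layers, g, st, 0.01, 0.5, 0.999, 1L)
  expect_true(all(r$layers[[1]]$params$W < layers[[1]]$params$W))
  expect_lt(r$layers[[1]]$params$b, 0)
})
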