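# Compact CPU convolutional-network engine.
#
# Tensors are numeric arrays with dim c(H, W, C, N). Convolution is done by
# im2col + BLAS matrix multiplication; backward passes are analytic and are
# validated against finite differences in the test suite. Index maps for
# im2col depend only on the geometry, so they are memoised per layer shape.

.geom_cache <- new.env(parent = emptyenv())

# im2col geometry for input (H,W,C,N), square kernel k, stride s, padding p.
# idx maps one sample's padded array to the (k*k*C) x (Ho*Wo) patch matrix;
# bigidx extends it across the batch.
.conv_geom <- function(H, W, C, N, k, s, p) {
  key <- paste(H, W, C, N, k, s, p, sep = ",")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  stopifnot(Ho >= 1L, Wo >= 1L)
  roff <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
  roff <- as.vector(outer(roff, (0:(C - 1L)) * (Hp * Wp), "+"))
  base <- as.vector(outer((0:(Ho - 1L)) * s + 1L, ((0:(Wo - 1L)) * s) * Hp, "+"))
  idx <- outer(roff, base, "+")
  nidx <- length(idx)
  bigidx <- rep.int(as.vector(idx), N) +
    rep((0:(N - 1L)) * (Hp * Wp * C), each = nidx)
  # bigvec must stay a dimensionless vector: indexing a 4-d array with a
  # matrix that happens to have 4 columns would switch R to coordinate
  # indexing
  g <- list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
            nrow = k * k * C, bigvec = bigidx,
            bigmat = matrix(bigidx, nrow = k * k * C))
  .geom_cache[[key]] <- g
  g
}

.pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

.conv_fwd <- function(x, W, b, s, p) {
  d <- dim(x); k <- dim(W)[1]; Cin <- d[3]; Cout <- dim(W)[4]; N <- d[4]
  stopifnot(dim(W)[3] == Cin)
  g <- .conv_geom(d[1], d[2], Cin, N, k, s, p)
  xp <- .pad_hw(x, p)
  cols <- matrix(xp[g$bigvec], nrow = g$nrow)
  om <- crossprod(cols, matrix(W, nrow = g$nrow))     # (Ho*Wo*N) x Cout
  om <- om + matrix(b, nrow(om), Cout, byrow = TRUE)
  y <- aperm(array(om, c(g$Ho, g$Wo, N, Cout)), c(1L, 2L, 4L, 3L))
  list(y = y, cache = list(cols = cols, g = g, d = d, k = k, s = s, p = p))
}

.conv_bwd <- function(dy, cache, W, need_dx = TRUE) {
  d <- cache$d; g <- cache$g
  Cin <- d[3]; N <- d[4]; Cout <- dim(W)[4]
  G <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = Cout)
  dW <- array(cache$cols %*% G, dim(W))
  db <- colSums(G)
  dx <- NULL
  if (need_dx) {
    dcols <- tcrossprod(matrix(W, nrow = g$nrow), G)  # (kkCin) x (HoWoN)
    dxp <- numeric(g$Hp * g$Wp * Cin * N)
    bm <- g$bigmat
    for (r in seq_len(g$nrow)) {
      ii <- bm[r, ]
      dxp[ii] <- dxp[ii] + dcols[r, ]
    }
    dxp <- array(dxp, c(g$Hp, g$Wp, Cin, N))
    p <- cache$p
    dx <- if (p > 0L)
      dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , , drop = FALSE]
    else dxp
    dim(dx) <- d
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# Zero-insertion upsampling: places input pixels on the even grid of a
# (2H+2) x (2W+2) zero canvas. Followed by a valid 3x3 convolution this is a
# stride-2 transposed convolution that exactly doubles the resolution.
.upzero_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1] + 2L, 2L * d[2] + 2L, d[3], d[4]))
  y[2L * seq_len(d[1]), 2L * seq_len(d[2]), , ] <- x
  list(y = y, cache = d)
}

.upzero_bwd <- function(dy, d) {
  dx <- dy[2L * seq_len(d[1]), 2L * seq_len(d[2]), , , drop = FALSE]
  dim(dx) <- d
  dx
}

# Instance normalisation (no affine parameters): each (channel, sample) map
# is centred and scaled to unit variance over its H*W pixels.
.inorm_fwd <- function(x, eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2]
  xm <- matrix(x, nrow = m)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  yh <- xc * rep(inv, each = m)
  list(y = array(yh, d), cache = list(yh = yh, inv = inv, m = m, d = d))
}

.inorm_bwd <- function(dy, cache) {
  m <- cache$m
  dym <- matrix(dy, nrow = m)
  yh <- cache$yh
  t1 <- colMeans(dym)
  t2 <- colMeans(dym * yh)
  dx <- (dym - rep(t1, each = m) - yh * rep(t2, each = m)) * rep(cache$inv, each = m)
  array(dx, cache$d)
}

.linear_fwd <- function(x, W, b) {
  y <- x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE)
  list(y = y, cache = x)
}

.linear_bwd <- function(dy, x, W) {
  list(dx = tcrossprod(dy, W), grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

.gap_fwd <- function(x) {
  d <- dim(x); m <- d[1] * d[2]
  cm <- colMeans(matrix(x, nrow = m))          # length C*N, c fastest
  list(y = t(matrix(cm, d[3], d[4])), cache = d)   # N x C
}

.gap_bwd <- function(dy, d) {
  m <- d[1] * d[2]
  array(rep(as.vector(t(dy)) / m, each = m), d)
}

# ---- layer constructors -----------------------------------------------------

.init_w <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), 0, sd), dims)

.layer_conv <- function(k, cin, cout, stride = 1L, pad = 0L, init_sd = 0.02) {
  list(type = "conv", k = k, s = stride, p = pad,
       params = list(W = .init_w(c(k, k, cin, cout), init_sd), b = numeric(cout)))
}
.layer_upzero <- function() list(type = "upzero")
.layer_inorm  <- function() list(type = "inorm")
.layer_relu   <- function() list(type = "relu")
.layer_lrelu  <- function(slope = 0.2) list(type = "lrelu", slope = slope)
.layer_tanh   <- function() list(type = "tanh")
.layer_res <- function(ch, init_sd = 0.02) {
  list(type = "res", layers = list(
    .layer_conv(3L, ch, ch, 1L, 1L, init_sd), .layer_inorm(), .layer_relu(),
    .layer_conv(3L, ch, ch, 1L, 1L, init_sd), .layer_inorm()))
}

.layer_fwd <- function(L, x) {
  switch(L$type,
    conv   = .conv_fwd(x, L$params$W, L$params$b, L$s, L$p),
    upzero = .upzero_fwd(x),
    inorm  = .inorm_fwd(x),
    relu   = list(y = pmax(x, 0), cache = x > 0),
    lrelu  = {
      pos <- x > 0
      list(y = x * (pos + L$slope * !pos), cache = pos)
    },
    tanh   = {
      y <- tanh(x)
      list(y = y, cache = y)
    },
    res    = {
      sub <- .seq_fwd(L$layers, x)
      list(y = sub$y + x, cache = sub$caches)
    },
    stop("unknown layer type: ", L$type))
}

.layer_bwd <- function(L, cache, dy, need_dx = TRUE) {
  switch(L$type,
    conv   = .conv_bwd(dy, cache, L$params$W, need_dx),
    upzero = list(dx = .upzero_bwd(dy, cache)),
    inorm  = list(dx = .inorm_bwd(dy, cache)),
    relu   = list(dx = dy * cache),
    lrelu  = list(dx = dy * (cache + L$slope * !cache)),
    tanh   = list(dx = dy * (1 - cache * cache)),
    res    = {
      sub <- .seq_bwd(L$layers, cache, dy, need_dx = TRUE)
      list(dx = sub$dx + dy, grads = sub$grads)
    },
    stop("unknown layer type: ", L$type))
}

.seq_fwd <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- .layer_fwd(layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

.seq_bwd <- function(layers, caches, dy, need_dx = TRUE) {
  n <- length(layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    r <- .layer_bwd(layers[[i]], caches[[i]], dy,
                    need_dx = need_dx || i > 1L)
    if (!is.null(r$grads)) grads[[i]] <- r$grads
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

# ---- Adam optimiser over a layer list --------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(L) {
    st <- list()
    if (!is.null(L$params))
      st$params <- lapply(L$params, function(p) list(m = p * 0, v = p * 0))
    if (!is.null(L$layers)) st$layers <- .adam_init(L$layers)
    st
  })
}

# Applies one Adam update in place over the layer list; grads is the parallel
# structure returned by .seq_bwd (a layer's entry may itself be a grads list
# for residual sub-layers). Returns list(layers, state).
.adam_step <- function(layers, grads, state, lr, beta1, beta2, t, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    if (!is.null(layers[[i]]$params)) {
      for (nm in names(layers[[i]]$params)) {
        g <- gi[[nm]]
        st <- state[[i]]$params[[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g * g
        layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
          lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
        state[[i]]$params[[nm]] <- st
      }
    } else if (!is.null(layers[[i]]$layers)) {
      r <- .adam_step(layers[[i]]$layers, gi, state[[i]]$layers,
                      lr, beta1, beta2, t, eps)
      layers[[i]]$layers <- r$layers
      state[[i]]$layers <- r$state
    }
  }
  list(layers = layers, state = state)
}

# Residual layers carry grads nested one level down; .adam_step above handles
# both shapes because .seq_bwd stores a residual block's grads as a list
# parallel to its sub-layers.

# Elementwise addition of two grads structures (used to accumulate the real
# and fake discriminator passes).
.grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) { a[i] <- b[i]; next }   # [i] keeps NULL slots intact
    if (!is.null(a[[i]]$W) || !is.null(a[[i]]$b)) {
      for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
    } else {
      a[[i]] <- .grads_add(a[[i]], b[[i]])
    }
  }
  a
}
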