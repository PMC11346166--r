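# Low-level tensor operations for the synthesis networks.
#
# All activations are arrays of dim (H, W, N, C): with R's column-major
# storage this makes im2col, channel reshapes and the channel concatenation
# pure re-dims (no transposes), so convolution reduces to BLAS matrix
# products.  Every op has an exact reverse-mode backward used both for
# weight gradients (training) and input gradients (FGSM).  Gradient
# correctness is checked against finite differences in the tests.

pad_hw <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

conv_init <- function(k, cin, cout) {
  # He-normal fan-in initialization
  sd <- sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

# weight array (k, k, cin, cout) reshaped to (k*k*cin, cout); the im2col
# column order (kernel row fastest, then kernel col, then input channel)
# matches this flattening
conv_fwd <- function(x, W, b, stride = 1L, pad = (dim(W)[1] - 1L) %/% 2L) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; N <- d[3]; cin <- d[4]
  k <- dim(W)[1]; cout <- dim(W)[4]
  stopifnot(dim(W)[3] == cin)
  Wm <- W; dim(Wm) <- c(k * k * cin, cout)
  if (k == 1L && stride == 1L && pad == 0L) {
    xm <- x; dim(xm) <- c(H * Wd * N, cin)
    ym <- xm %*% Wm
    ym <- ym + rep(b, each = nrow(ym))
    dim(ym) <- c(H, Wd, N, cout)
    return(list(y = ym, cache = list(k = 1L, xm = xm, H = H, Wd = Wd,
                                     N = N, cin = cin, cout = cout)))
  }
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (Wd + 2L * pad - k) %/% stride + 1L
  xp <- pad_hw(x, pad)
  X <- array(0, c(Ho, Wo, N, k * k * cin))
  cidx <- seq_len(cin)
  for (dj in seq_len(k)) {
    cols <- seq.int(dj, by = stride, length.out = Wo)
    for (di in seq_len(k)) {
      rows <- seq.int(di, by = stride, length.out = Ho)
      X[, , , di + (dj - 1L) * k + (cidx - 1L) * k * k] <-
        xp[rows, cols, , , drop = FALSE]
    }
  }
  dim(X) <- c(Ho * Wo * N, k * k * cin)
  ym <- X %*% Wm
  ym <- ym + rep(b, each = nrow(ym))
  dim(ym) <- c(Ho, Wo, N, cout)
  list(y = ym,
       cache = list(k = k, Xm = X, stride = stride, pad = pad,
                    H = H, Wd = Wd, N = N, cin = cin, cout = cout,
                    Ho = Ho, Wo = Wo))
}

conv_bwd <- function(dy, W, cache) {
  k <- cache$k; cin <- cache$cin; N <- cache$N; cout <- cache$cout
  Wm <- W; dim(Wm) <- c(k * k * cin, cout)
  if (k == 1L) {
    dym <- dy; dim(dym) <- c(cache$H * cache$Wd * N, cout)
    dW <- array(crossprod(cache$xm, dym), c(1, 1, cin, cout))
    db <- colSums(dym)
    dx <- tcrossprod(dym, Wm)
    dim(dx) <- c(cache$H, cache$Wd, N, cin)
    return(list(dx = dx, dW = dW, db = db))
  }
  Ho <- cache$Ho; Wo <- cache$Wo; stride <- cache$stride; pad <- cache$pad
  dym <- dy; dim(dym) <- c(Ho * Wo * N, cout)
  dW <- array(crossprod(cache$Xm, dym), c(k, k, cin, cout))
  db <- colSums(dym)
  dX <- tcrossprod(dym, Wm)
  dim(dX) <- c(Ho, Wo, N, k * k * cin)
  Hp <- cache$H + 2L * pad; Wp <- cache$Wd + 2L * pad
  dxp <- array(0, c(Hp, Wp, N, cin))
  cidx <- seq_len(cin)
  for (dj in seq_len(k)) {
    cols <- seq.int(dj, by = stride, length.out = Wo)
    for (di in seq_len(k)) {
      rows <- seq.int(di, by = stride, length.out = Ho)
      slab <- dX[, , , di + (dj - 1L) * k + (cidx - 1L) * k * k, drop = FALSE]
      dim(slab) <- c(Ho, Wo, N, cin)
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + slab
    }
  }
  dx <- if (pad > 0L) {
    dxp[(pad + 1L):(pad + cache$H), (pad + 1L):(pad + cache$Wd), , ,
        drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

# 3x3 max pool, stride 1, same padding (used by branch A4)
maxpool3_fwd <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  xp <- pad_hw(x, 1L, fill = -Inf)
  y <- array(-Inf, d)
  amax <- array(1L, d)
  s <- 0L
  for (dj in 0:2) for (di in 0:2) {
    s <- s + 1L
    slab <- xp[(1L + di):(H + di), (1L + dj):(Wd + dj), , , drop = FALSE]
    upd <- slab > y
    y[upd] <- slab[upd]
    amax[upd] <- s
  }
  list(y = y, cache = amax)
}

maxpool3_bwd <- function(dy, cache) {
  d <- dim(dy); H <- d[1]; Wd <- d[2]
  dxp <- array(0, c(H + 2L, Wd + 2L, d[3], d[4]))
  s <- 0L
  for (dj in 0:2) for (di in 0:2) {
    s <- s + 1L
    sel <- cache == s
    if (!any(sel)) next
    contrib <- array(0, d)
    contrib[sel] <- dy[sel]
    dxp[(1L + di):(H + di), (1L + dj):(Wd + dj), , ] <-
      dxp[(1L + di):(H + di), (1L + dj):(Wd + dj), , , drop = FALSE] + contrib
  }
  dxp[2L:(H + 1L), 2L:(Wd + 1L), , , drop = FALSE]
}

# Nearest-neighbour 2x upsampling
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  dy[oi, oj, , , drop = FALSE] + dy[oi + 1L, oj, , , drop = FALSE] +
    dy[oi, oj + 1L, , , drop = FALSE] + dy[oi + 1L, oj + 1L, , , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

se_init <- function(cf, ratio) {
  h <- max(1L, cf %/% ratio)
  list(W1 = matrix(stats::rnorm(cf * h, sd = sqrt(2 / cf)), cf, h),
       b1 = numeric(h),
       W2 = matrix(stats::rnorm(h * cf, sd = sqrt(1 / h)), h, cf),
       b2 = numeric(cf))
}

#' Squeeze-and-excitation channel recalibration
#'
#' Standard SE gating: global average pool over space, a bottleneck
#' fully-connected pair (C -> max(1, C %/% ratio) -> C) with ReLU then
#' sigmoid, and a channel-wise multiplicative gate.  Output shape equals
#' input shape; the per-channel gain is constant over the spatial grid.
#'
#' @param x Array of dim (H, W, N, C): batch of N feature maps with C
#'   channels.
#' @param ratio Reduction ratio (>= 1); the bottleneck width is clamped to
#'   at least one unit.
#' @param params Optional list (W1, b1, W2, b2); freshly initialized when
#'   omitted.
#' @return Array of the same shape as `x`.
#' @export
se_recalibrate <- function(x, ratio, params = NULL) {
  if (is.null(params)) params <- se_init(dim(x)[4], ratio)
  se_fwd(x, params)$y
}

se_fwd <- function(x, p) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; cf <- d[4]
  xm <- x; dim(xm) <- c(H * Wd, N * cf)
  z <- matrix(colMeans(xm), N, cf)
  a1 <- z %*% p$W1 + rep(p$b1, each = N)
  h1 <- pmax(a1, 0)
  a2 <- h1 %*% p$W2 + rep(p$b2, each = N)
  g <- sigmoid(a2)                                           # (N, cf)
  y <- x * rep(as.vector(g), each = H * Wd)
  list(y = y, cache = list(x = x, z = z, a1 = a1, h1 = h1, g = g,
                           H = H, Wd = Wd, N = N, cf = cf))
}

se_bwd <- function(dy, p, cache) {
  H <- cache$H; Wd <- cache$Wd; N <- cache$N; cf <- cache$cf
  g <- cache$g
  dx <- dy * rep(as.vector(g), each = H * Wd)
  prod <- dy * cache$x
  dim(prod) <- c(H * Wd, N * cf)
  dg <- matrix(colSums(prod), N, cf)
  da2 <- dg * g * (1 - g)
  dW2 <- crossprod(cache$h1, da2)
  db2 <- colSums(da2)
  dh1 <- tcrossprod(da2, p$W2)
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- crossprod(cache$z, da1)
  db1 <- colSums(da1)
  dz <- tcrossprod(da1, p$W1)                                # (N, cf)
  dx <- dx + rep(as.vector(dz), each = H * Wd) / (H * Wd)
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# concatenate along the channel (4th) dimension
concat_c <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[4], integer(1))
  out <- array(0, c(d1[1], d1[2], d1[3], sum(cs)))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[4]
    out[, , , (at + 1L):(at + cc)] <- x
    at <- at + cc
  }
  out
}

split_c <- function(dy, widths) {
  at <- 0L
  out <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    out[[i]] <- dy[, , , (at + 1L):(at + widths[i]), drop = FALSE]
    at <- at + widths[i]
  }
  out
}
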