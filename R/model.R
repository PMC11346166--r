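# Instantiate a trainable encoder-decoder synthesis network from a genotype.
#
# Each configurable block runs: multi-branch module (branch A1 = 1x1 conv,
# A2 = 3x3 conv, A3 = 5x5 conv factorized as two 3x3, A4 = 3x3 max-pool +
# 1x1 conv; active branches per the connection pattern, outputs concatenated)
# -> point-wise 1x1 fusing convolution -> resolution stage (encoder: kernel-4
# stride-2 convolution; decoder: nearest x2 upsampling) -> 3x3 convolution ->
# optional squeeze-and-excitation gate.  ReLU follows every convolution;
# padding is "same" everywhere so only the explicit resolution stage changes
# spatial size.  Decoder j consumes the concatenation of the previous stage's
# output with the skip from its mirror encoder (encoder depth-j+1); decoder 1
# is the deepest, first-applied decoder.  A final linear 1x1 convolution maps
# to the output channels (a regression head in normalized CT units).

block_channels <- function(g, in_channels) {
  d <- g$depth
  enc_in <- integer(d); dec_in <- integer(d)
  enc_out <- vapply(g$encoders, function(b) b$filters, integer(1))
  dec_out <- vapply(g$decoders, function(b) b$filters, integer(1))
  for (i in seq_len(d)) enc_in[i] <- if (i == 1L) in_channels else enc_out[i - 1L]
  for (j in seq_len(d)) {
    prev <- if (j == 1L) enc_out[d] else dec_out[j - 1L]
    dec_in[j] <- prev + enc_out[d - j + 1L]
  }
  list(enc_in = enc_in, enc_out = enc_out, dec_in = dec_in, dec_out = dec_out)
}

init_block_params <- function(bc, cin, type) {
  f <- bc$filters
  p <- list()
  br <- pattern_branches(bc$pattern)
  if (1L %in% br) p$br1 <- conv_init(1L, cin, f)
  if (2L %in% br) p$br2 <- conv_init(3L, cin, f)
  if (3L %in% br) p$br3a <- conv_init(3L, cin, f)
  if (3L %in% br) p$br3b <- conv_init(3L, f, f)
  if (4L %in% br) p$br4 <- conv_init(1L, cin, f)
  p$fuse <- conv_init(1L, length(br) * f, f)
  if (type == "enc") p$down <- conv_init(4L, f, f)
  p$post <- conv_init(3L, f, f)
  if (bc$se) p$se <- se_init(f, bc$se_ratio)
  p
}

#' Build a synthesis network from a genotype
#'
#' Instantiates the generalized U-Net described by `g` with freshly
#' initialized weights (He-normal; uses R's RNG, so wrap in `set.seed()`
#' for reproducible initialization).  The network maps single-channel
#' slices to single-channel slices of the same size; the input height and
#' width must be divisible by `2^depth`.
#'
#' @param g A `unet_genotype`.
#' @param in_channels,out_channels Channel counts of input and output
#'   (default 1 each).
#' @return An object of class `unet_model` with elements `genotype`,
#'   `params` (named list of weight arrays) and `channels`.
#' @examples
#' set.seed(1)
#' g <- genotype(list(block_config(1, 8)), list(block_config(1, 8)))
#' m <- build_model(g)
#' x <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
#' dim(predict(m, x))
#' @export
build_model <- function(g, in_channels = 1L, out_channels = 1L) {
  validate_genotype(g)
  ch <- block_channels(g, in_channels)
  params <- list()
  for (i in seq_len(g$depth)) {
    params[[paste0("enc", i)]] <- init_block_params(g$encoders[[i]], ch$enc_in[i], "enc")
  }
  for (j in seq_len(g$depth)) {
    params[[paste0("dec", j)]] <- init_block_params(g$decoders[[j]], ch$dec_in[j], "dec")
  }
  params$head <- conv_init(1L, ch$dec_out[g$depth], out_channels)
  structure(list(genotype = g, params = params, channels = ch,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "unet_model")
}

#' Number of trainable parameters of a model
#' @param model A `unet_model`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("U-Net synthesis model: depth %d, %d parameters\n",
              x$genotype$depth, parameter_count(x)))
  print(x$genotype)
  invisible(x)
}

block_fwd <- function(p, bc, x, type) {
  cache <- list()
  br <- pattern_branches(bc$pattern)
  outs <- vector("list", length(br))
  k <- 0L
  for (b in br) {
    k <- k + 1L
    if (b == 1L) {
      cv <- conv_fwd(x, p$br1$W, p$br1$b); r <- relu_fwd(cv$y)
      cache$br1 <- list(conv = cv$cache, relu = r$cache)
      outs[[k]] <- r$y
    } else if (b == 2L) {
      cv <- conv_fwd(x, p$br2$W, p$br2$b); r <- relu_fwd(cv$y)
      cache$br2 <- list(conv = cv$cache, relu = r$cache)
      outs[[k]] <- r$y
    } else if (b == 3L) {
      cva <- conv_fwd(x, p$br3a$W, p$br3a$b); ra <- relu_fwd(cva$y)
      cvb <- conv_fwd(ra$y, p$br3b$W, p$br3b$b); rb <- relu_fwd(cvb$y)
      cache$br3 <- list(conva = cva$cache, relua = ra$cache,
                        convb = cvb$cache, relub = rb$cache)
      outs[[k]] <- rb$y
    } else {
      mp <- maxpool3_fwd(x)
      cv <- conv_fwd(mp$y, p$br4$W, p$br4$b); r <- relu_fwd(cv$y)
      cache$br4 <- list(pool = mp$cache, conv = cv$cache, relu = r$cache)
      outs[[k]] <- r$y
    }
  }
  h <- if (length(outs) == 1L) outs[[1]] else concat_c(outs)
  cache$branches <- br
  cache$branch_width <- bc$filters
  cv <- conv_fwd(h, p$fuse$W, p$fuse$b); r <- relu_fwd(cv$y)
  cache$fuse <- list(conv = cv$cache, relu = r$cache)
  h <- r$y
  if (type == "enc") {
    cv <- conv_fwd(h, p$down$W, p$down$b, stride = 2L, pad = 1L)
    r <- relu_fwd(cv$y)
    cache$down <- list(conv = cv$cache, relu = r$cache)
    h <- r$y
  } else {
    h <- upsample2_fwd(h)
  }
  cv <- conv_fwd(h, p$post$W, p$post$b); r <- relu_fwd(cv$y)
  cache$post <- list(conv = cv$cache, relu = r$cache)
  h <- r$y
  if (!is.null(p$se)) {
    se <- se_fwd(h, p$se)
    cache$se <- se$cache
    h <- se$y
  }
  list(y = h, cache = cache)
}

block_bwd <- function(p, bc, dy, cache, type) {
  g <- list()
  if (!is.null(p$se)) {
    se <- se_bwd(dy, p$se, cache$se)
    g$se <- list(W1 = se$dW1, b1 = se$db1, W2 = se$dW2, b2 = se$db2)
    dy <- se$dx
  }
  dy <- relu_bwd(dy, cache$post$relu)
  cb <- conv_bwd(dy, p$post$W, cache$post$conv)
  g$post <- list(W = cb$dW, b = cb$db)
  dy <- cb$dx
  if (type == "enc") {
    dy <- relu_bwd(dy, cache$down$relu)
    cb <- conv_bwd(dy, p$down$W, cache$down$conv)
    g$down <- list(W = cb$dW, b = cb$db)
    dy <- cb$dx
  } else {
    dy <- upsample2_bwd(dy)
  }
  dy <- relu_bwd(dy, cache$fuse$relu)
  cb <- conv_bwd(dy, p$fuse$W, cache$fuse$conv)
  g$fuse <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx
  br <- cache$branches
  parts <- if (length(br) == 1L) list(dh) else
    split_c(dh, rep(cache$branch_width, length(br)))
  dx <- NULL
  for (k in seq_along(br)) {
    b <- br[k]; dpart <- parts[[k]]
    if (b == 1L) {
      dpart <- relu_bwd(dpart, cache$br1$relu)
      cb <- conv_bwd(dpart, p$br1$W, cache$br1$conv)
      g$br1 <- list(W = cb$dW, b = cb$db)
      dxi <- cb$dx
    } else if (b == 2L) {
      dpart <- relu_bwd(dpart, cache$br2$relu)
      cb <- conv_bwd(dpart, p$br2$W, cache$br2$conv)
      g$br2 <- list(W = cb$dW, b = cb$db)
      dxi <- cb$dx
    } else if (b == 3L) {
      dpart <- relu_bwd(dpart, cache$br3$relub)
      cb <- conv_bwd(dpart, p$br3b$W, cache$br3$convb)
      g$br3b <- list(W = cb$dW, b = cb$db)
      dpart <- relu_bwd(cb$dx, cache$br3$relua)
      cb <- conv_bwd(dpart, p$br3a$W, cache$br3$conva)
      g$br3a <- list(W = cb$dW, b = cb$db)
      dxi <- cb$dx
    } else {
      dpart <- relu_bwd(dpart, cache$br4$relu)
      cb <- conv_bwd(dpart, p$br4$W, cache$br4$conv)
      g$br4 <- list(W = cb$dW, b = cb$db)
      dxi <- maxpool3_bwd(cb$dx, cache$br4$pool)
    }
    dx <- if (is.null(dx)) dxi else dx + dxi
  }
  list(dx = dx, grads = g)
}

check_input_size <- function(model, H, W) {
  div <- 2L^model$genotype$depth
  if (H %% div != 0L || W %% div != 0L)
    stop(sprintf(paste0("input size %dx%d is not divisible by 2^depth = %d; ",
                        "the encoder halves resolution %d times"),
                 H, W, div, model$genotype$depth))
}

model_forward <- function(model, x, want_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)   # (H, W, N) -> 1 channel
  d <- dim(x)
  check_input_size(model, d[1], d[2])
  g <- model$genotype
  p <- model$params
  caches <- if (want_cache) list() else NULL
  skips <- vector("list", g$depth)
  h <- x
  for (i in seq_len(g$depth)) {
    res <- block_fwd(p[[paste0("enc", i)]], g$encoders[[i]], h, "enc")
    skips[[i]] <- res$y
    h <- res$y
    if (want_cache) caches[[paste0("enc", i)]] <- res$cache
  }
  concat_prev_width <- integer(g$depth)
  for (j in seq_len(g$depth)) {
    skip <- skips[[g$depth - j + 1L]]
    concat_prev_width[j] <- dim(h)[4]
    inp <- concat_c(list(h, skip))
    res <- block_fwd(p[[paste0("dec", j)]], g$decoders[[j]], inp, "dec")
    h <- res$y
    if (want_cache) caches[[paste0("dec", j)]] <- res$cache
  }
  hd <- conv_fwd(h, p$head$W, p$head$b)
  if (want_cache) {
    caches$head <- hd$cache
    caches$concat_prev_width <- concat_prev_width
  }
  list(y = hd$y, caches = caches)
}

model_backward <- function(model, caches, dy) {
  g <- model$genotype
  p <- model$params
  grads <- list()
  cb <- conv_bwd(dy, p$head$W, caches$head)
  grads$head <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx
  denc_out <- vector("list", g$depth)           # grads flowing into skips
  add_to <- function(cur, inc) if (is.null(cur)) inc else cur + inc
  for (j in rev(seq_len(g$depth))) {
    bb <- block_bwd(p[[paste0("dec", j)]], g$decoders[[j]], dh,
                    caches[[paste0("dec", j)]], "dec")
    grads[[paste0("dec", j)]] <- bb$grads
    mirror <- g$depth - j + 1L
    widths <- c(caches$concat_prev_width[j],
                dim(bb$dx)[4] - caches$concat_prev_width[j])
    parts <- split_c(bb$dx, widths)
    denc_out[[mirror]] <- add_to(denc_out[[mirror]], parts[[2]])
    if (j > 1L) {
      dh <- parts[[1]]
    } else {
      denc_out[[g$depth]] <- add_to(denc_out[[g$depth]], parts[[1]])
    }
  }
  dprev <- NULL
  for (i in rev(seq_len(g$depth))) {
    dout <- if (is.null(dprev)) denc_out[[i]] else denc_out[[i]] + dprev
    bb <- block_bwd(p[[paste0("enc", i)]], g$encoders[[i]], dout,
                    caches[[paste0("enc", i)]], "enc")
    grads[[paste0("enc", i)]] <- bb$grads
    dprev <- bb$dx
  }
  list(dx = dprev, grads = grads)
}

# Mean-squared-error loss plus gradients with respect to weights and,
# optionally, the input.  Inputs of dim (H, W, N) are treated as
# single-channel batches.
model_loss <- function(model, S, T, want_weight_grads = TRUE,
                       want_input_grad = FALSE) {
  if (length(dim(S)) == 3L) dim(S) <- c(dim(S), 1L)
  if (length(dim(T)) == 3L) dim(T) <- c(dim(T), 1L)
  fw <- model_forward(model, S, want_cache = want_weight_grads || want_input_grad)
  resid <- fw$y - T
  loss <- mean(resid^2)
  out <- list(loss = loss, pred = fw$y)
  if (want_weight_grads || want_input_grad) {
    dpred <- 2 * resid / length(resid)
    bw <- model_backward(model, fw$caches, dpred)
    if (want_weight_grads) out$grads <- bw$grads
    if (want_input_grad) out$dinput <- bw$dx
  }
  out
}

#' Gradient of the training loss with respect to the input
#'
#' Generic needed by the fast gradient sign method.  For `unet_model` this
#' is full reverse-mode backpropagation of the mean-squared-error loss
#' through the network to the input pixels; weights are left untouched.
#'
#' @param model A model object.
#' @param S Input slices, array (H, W, N) or (H, W, 1, N).
#' @param T Target slices, same shape.
#' @return Array of the same shape as `S`.
#' @export
input_gradient <- function(model, S, T) UseMethod("input_gradient")

#' @export
input_gradient.unet_model <- function(model, S, T) {
  dims <- dim(S)
  res <- model_loss(model, S, T, want_weight_grads = FALSE,
                    want_input_grad = TRUE)
  if (any(!is.finite(res$dinput))) {
    n <- dim(res$dinput)[3]
    bad <- which(vapply(seq_len(n), function(i) {
      any(!is.finite(res$dinput[, , i, ]))
    }, logical(1)))
    stop("non-finite input gradient in batch index ",
         paste(bad, collapse = ", "))
  }
  g <- res$dinput
  dim(g) <- dims
  g
}

#' Predict synthesized slices
#'
#' Runs the network over a stack of input slices in batches and returns
#' predictions in the model's output units (normalized CT units for the
#' synthesis task; use [denormalize_ct()] for Hounsfield units).
#'
#' @param object A `unet_model`.
#' @param x Array (H, W) or (H, W, N) of input slices.
#' @param batch_size Slices per forward pass.
#' @param ... Unused.
#' @return Array of the same shape as `x`.
#' @export
predict.unet_model <- function(object, x, batch_size = 16L, ...) {
  dims <- dim(x)
  if (length(dims) == 2L) dim(x) <- c(dims, 1L)
  n <- dim(x)[3]
  out <- array(0, dim(x))
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    xb <- x[, , idx, drop = FALSE]
    dim(xb) <- c(dim(x)[1:2], length(idx), 1L)
    yb <- model_forward(object, xb)$y
    dim(yb) <- dim(x[, , idx, drop = FALSE])
    out[, , idx] <- yb
  }
  dim(out) <- dims
  out
}

# Deep copy / assignment helpers for parameter snapshots
clone_params <- function(params) rapply(params, identity, how = "replace")

set_params <- function(model, params) {
  model$params <- params
  model
}

#' A one-weight linear synthesis model
#'
#' The scalar map `t(S) = w * S + b`, wrapped as a model through the same
#' convolution kernels (a single linear 1x1 convolution).  Its FGSM
#' perturbation has a closed form, which makes it the reference case for
#' demonstrating and testing attack generation.
#'
#' @param w,b Scalar weight and bias.
#' @return An object of class `linear_synth` usable with
#'   [fgsm_perturb()] and [predict()].
#' @export
linear_synth_model <- function(w, b = 0) {
  structure(list(W = array(w, c(1, 1, 1, 1)), b = b), class = "linear_synth")
}

#' @export
predict.linear_synth <- function(object, x, ...) {
  dims <- dim(x)
  if (length(dims) == 2L) dim(x) <- c(dims, 1L)
  x4 <- x; dim(x4) <- c(dim(x), 1L)
  y <- conv_fwd(x4, object$W, object$b)$y
  dim(y) <- dims
  y
}

#' @export
input_gradient.linear_synth <- function(model, S, T) {
  dims <- dim(S)
  if (length(dims) == 2L) { dim(S) <- c(dims, 1L); dim(T) <- c(dims, 1L) }
  S4 <- S; dim(S4) <- c(dim(S), 1L)
  T4 <- T; dim(T4) <- dim(S4)
  fw <- conv_fwd(S4, model$W, model$b)
  dpred <- 2 * (fw$y - T4) / length(T4)
  g <- conv_bwd(dpred, model$W, fw$cache)$dx
  dim(g) <- dims
  g
}
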