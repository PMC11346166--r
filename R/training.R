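# Regular and adversarial training of synthesis networks.
#
# Optimizer: Adam with the AMSgrad correction, learning rate 1e-4, MSE loss,
# batch size 6 - the regime under which all architectures are compared.
# Adversarial training replaces each sample's clean loss by its FGSM
# counterpart with probability 1 - p_r (an independent Bernoulli draw per
# sample); gradients are not propagated through attack generation.

# --- parameter flattening -------------------------------------------------
# Gradients are accumulated block-by-block in backward order, so they are
# aligned with the parameter tree by path, not by position.

param_paths <- function(x, prefix = character()) {
  if (!is.list(x)) return(list(prefix))
  out <- list()
  for (nm in names(x)) out <- c(out, param_paths(x[[nm]], c(prefix, nm)))
  out
}

pluck_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

assign_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
  } else {
    x[[path[1]]] <- assign_path(x[[path[1]]], path[-1], value)
  }
  x
}

#' Training configuration
#'
#' Bundles the hyperparameters of one training run.  The defaults are the
#' regular full-data regime: 150 epochs, batch size 6, Adam with AMSgrad at
#' learning rate 1e-4, MSE loss, early stopping with patience 5 on the
#' validation loss.  Set `adversarial = TRUE` for Bernoulli loss-mixing
#' adversarial training with replacement probability `p_r` and FGSM
#' magnitude `eps`.
#'
#' @param epochs Maximum number of epochs.
#' @param batch_size Samples per gradient step.
#' @param lr Learning rate.
#' @param patience Early-stopping patience in epochs, or `NULL` to disable.
#' @param adversarial Logical; enable adversarial training.
#' @param p_r Probability that a sample keeps its clean loss (replacement
#'   probability of the Bernoulli mixing variable).
#' @param eps FGSM magnitude used during adversarial training.
#' @param seed Integer seed controlling shuffling and Bernoulli draws, or
#'   `NULL` to use the current RNG state.
#' @param keep_checkpoints Keep a weight snapshot for every epoch (memory
#'   permitting); the best-validation snapshot is always kept.
#' @param shuffle Reshuffle the training slices each epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 6L, lr = 1e-4,
                         patience = 5L, adversarial = FALSE, p_r = 0.5,
                         eps = 0.2, seed = NULL, keep_checkpoints = FALSE,
                         shuffle = TRUE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0,
            is.null(patience) || patience >= 1L,
            p_r >= 0, p_r <= 1, eps >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = if (is.null(patience)) NULL else as.integer(patience),
                 adversarial = isTRUE(adversarial), p_r = p_r, eps = eps,
                 seed = seed, keep_checkpoints = isTRUE(keep_checkpoints),
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), vmax = numeric(n), t = 0L)
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$vmax <- pmax(state$vmax, vhat)        # AMSgrad correction
  list(theta = theta - lr * mhat / (sqrt(state$vmax) + eps), state = state)
}

# Stack all slices of a list of subject volumes into (H, W, Ntot) source /
# target arrays (normalized units).
collect_slices <- function(subjects) {
  stopifnot(length(subjects) > 0)
  ns <- vapply(subjects, function(s) dim(s$source)[3], integer(1))
  d <- dim(subjects[[1]]$source)
  S <- array(0, c(d[1], d[2], sum(ns)))
  T <- array(0, c(d[1], d[2], sum(ns)))
  at <- 0L
  for (s in subjects) {
    n <- dim(s$source)[3]
    S[, , (at + 1L):(at + n)] <- s$source
    T[, , (at + 1L):(at + n)] <- s$target_norm
    at <- at + n
  }
  list(S = S, T = T)
}

batched_mse <- function(model, S, T, batch_size = 16L) {
  n <- dim(S)[3]
  total <- 0
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    r <- model_loss(model, S[, , idx, drop = FALSE], T[, , idx, drop = FALSE],
                    want_weight_grads = FALSE)
    total <- total + r$loss * length(idx)
  }
  total / n
}

#' Bernoulli-mixed adversarial batch loss
#'
#' Draws an independent Bernoulli(`p_r`) variable per sample; samples with a
#' zero draw have their input replaced by the FGSM perturbation at the
#' current weights.  The returned value is the mean over the batch of the
#' per-sample MSE under these inputs - the loss minimized during
#' adversarial training.  `p_r = 1` yields the clean batch loss exactly and
#' `p_r = 0` the fully adversarial loss.
#'
#' @param model A `unet_model`.
#' @param S,T Arrays (H, W, B) of inputs and targets.
#' @param eps FGSM magnitude.
#' @param p_r Probability of keeping the clean sample.
#' @return Scalar loss.
#' @export
adversarial_batch_loss <- function(model, S, T, eps = 0.2, p_r = 0.5) {
  mixed <- mix_adversarial_batch(model, S, T, eps, p_r)
  model_loss(model, mixed, T, want_weight_grads = FALSE)$loss
}

mix_adversarial_batch <- function(model, S, T, eps, p_r) {
  n <- dim(S)[3]
  beta <- stats::rbinom(n, 1L, p_r)
  adv <- which(beta == 0L)
  if (length(adv) > 0 && eps > 0) {
    S_adv <- fgsm_perturb(model, S[, , adv, drop = FALSE],
                          T[, , adv, drop = FALSE], eps)
    S[, , adv] <- S_adv
  }
  S
}

#' Train a synthesis network
#'
#' Fits `model` on the training slices of `split`, evaluating the clean
#' validation MSE after every epoch.  The returned fit carries the weights
#' of the epoch with minimal validation loss (the per-epoch checkpointing /
#' arg-min selection rule used throughout the search).  Early stopping
#' halts training once the validation loss has failed to improve for
#' `patience` consecutive epochs.  A non-finite loss aborts with a
#' diagnostic error of class `robunet_divergence`.
#'
#' @param model A freshly built (or previously trained) `unet_model`.
#' @param split A dataset split with `$train` and `$val` lists of subject
#'   volumes (see [generate_cohort()]).
#' @param config A [train_config()].
#' @return An object of class `trained_unet`: the fitted model plus
#'   `history` (per-epoch train/validation losses), `best_epoch`,
#'   `epochs_run` and, if requested, per-epoch `checkpoints`.
#' @export
train <- function(model, split, config = train_config()) {
  stopifnot(inherits(model, "unet_model"))
  if (length(split$train) == 0 || length(split$val) == 0)
    stop("split must have nonempty train and val parts")
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- collect_slices(split$train)
  va <- collect_slices(split$val)
  n <- dim(tr$S)[3]
  paths <- param_paths(model$params)
  theta <- unlist(lapply(paths, function(p) as.numeric(pluck_path(model$params, p))))
  lens <- vapply(paths, function(p) length(pluck_path(model$params, p)), integer(1))
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  dims <- lapply(paths, function(p) dim(pluck_path(model$params, p)))
  rebuild <- function(theta) {
    params <- model$params
    for (i in seq_along(paths)) {
      v <- theta[(offsets[i] + 1L):(offsets[i] + lens[i])]
      if (!is.null(dims[[i]])) dim(v) <- dims[[i]]
      params <- assign_path(params, paths[[i]], v)
    }
    params
  }
  flatten_grads <- function(grads) {
    unlist(lapply(paths, function(p) as.numeric(pluck_path(grads, p))))
  }
  opt <- adam_init(length(theta))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  checkpoints <- if (config$keep_checkpoints) list() else NULL
  best_val <- Inf; best_epoch <- 0L; best_theta <- theta
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (at in seq(1L, n, by = config$batch_size)) {
      idx <- ord[at:min(n, at + config$batch_size - 1L)]
      Sb <- tr$S[, , idx, drop = FALSE]
      Tb <- tr$T[, , idx, drop = FALSE]
      if (config$adversarial) {
        Sb <- mix_adversarial_batch(model, Sb, Tb, config$eps, config$p_r)
      }
      res <- model_loss(model, Sb, Tb, want_weight_grads = TRUE)
      if (!is.finite(res$loss)) {
        stop(structure(class = c("robunet_divergence", "error", "condition"),
                       list(message = sprintf(
                         "training diverged: non-finite loss at epoch %d", epoch),
                         call = sys.call())))
      }
      step <- adam_step(theta, flatten_grads(res$grads), opt, config$lr)
      theta <- step$theta
      opt <- step$state
      model$params <- rebuild(theta)
      ep_loss <- ep_loss + res$loss * length(idx)
    }
    val_loss <- batched_mse(model, va$S, va$T)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = val_loss))
    if (config$keep_checkpoints) checkpoints[[epoch]] <- model$params
    if (val_loss < best_val) {
      best_val <- val_loss
      best_epoch <- epoch
      best_theta <- theta
    }
    if (!is.null(config$patience) && epoch - best_epoch >= config$patience) break
  }
  model$params <- rebuild(best_theta)
  structure(list(model = model, history = history,
                 epochs_run = nrow(history), best_epoch = best_epoch,
                 best_val_loss = best_val, checkpoints = checkpoints,
                 config = config),
            class = "trained_unet")
}

#' Inner training loop of the architecture search
#'
#' Trains a candidate for a fixed 10 epochs (no early stopping) on the
#' subdataset's training part, snapshotting the weights after every epoch
#' and returning the snapshot with minimal subdataset-validation loss - the
#' weights under which the candidate's robustness is estimated.
#'
#' @param model A `unet_model`.
#' @param subdataset A split with `$train` and `$val` parts.
#' @param epochs,batch_size,lr Inner-loop hyperparameters.
#' @param seed Optional seed for reproducible shuffling.
#' @return A `trained_unet` with one checkpoint per epoch.
#' @export
nas_inner_train <- function(model, subdataset, epochs = 10L, batch_size = 6L,
                            lr = 1e-4, seed = NULL) {
  train(model, subdataset,
        train_config(epochs = epochs, batch_size = batch_size, lr = lr,
                     patience = NULL, seed = seed, keep_checkpoints = TRUE))
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("Trained U-Net: %d/%d epochs run, best validation MSE %.5g at epoch %d\n",
              x$epochs_run, x$config$epochs, x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.trained_unet <- function(object, ...) {
  print(object)
  print(utils::tail(object$history, 5))
  invisible(object$history)
}

#' @export
predict.trained_unet <- function(object, x, ...) predict(object$model, x, ...)

#' @export
input_gradient.trained_unet <- function(model, S, T) input_gradient(model$model, S, T)

#' Residual slices of a fit on a dataset
#' @param object A `trained_unet`.
#' @param subjects List of subject volumes (default unavailable; pass the
#'   split the residuals are wanted for).
#' @param ... Unused.
#' @return Array of prediction residuals (normalized units).
#' @export
residuals.trained_unet <- function(object, subjects, ...) {
  sl <- collect_slices(subjects)
  predict(object$model, sl$S) - sl$T
}

#' @export
plot.trained_unet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
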