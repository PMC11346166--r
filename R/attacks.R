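# Adversarial (FGSM) and Gaussian input corruption, and progressive
# corruption sweeps.

#' Fast gradient sign method perturbation
#'
#' Implements `S_adv = S + eps * sign(grad_S l(S, T))` with `l` the model's
#' training loss (MSE).  No clipping or projection is applied - the MR
#' inputs are z-scored and unbounded - and the model weights are left
#' unchanged.  `sign(0) = 0`, so pixels with zero gradient are not
#' perturbed; `eps = 0` returns `S` exactly.  The perturbation is a pure
#' function of (weights, S, T, eps): repeated calls agree bitwise.
#'
#' @param model A model with an [input_gradient()] method.
#' @param S Input slices, array (H, W) or (H, W, N).
#' @param T Targets of the same shape (normalized CT units for the
#'   synthesis task).
#' @param eps Perturbation magnitude (>= 0).
#' @param batch_size Slices per gradient pass (each slice's gradient is
#'   computed within its own batch, so batching does not change the
#'   result's sign pattern for MSE, which separates over samples up to a
#'   positive constant).
#' @return Array of the same shape as `S`.
#' @export
fgsm_perturb <- function(model, S, T, eps, batch_size = 16L) {
  stopifnot(eps >= 0)
  if (eps == 0) return(S)
  dims <- dim(S)
  if (length(dims) == 2L) { dim(S) <- c(dims, 1L); dim(T) <- c(dims, 1L) }
  n <- dim(S)[3]
  out <- S
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    g <- input_gradient(model, S[, , idx, drop = FALSE],
                        T[, , idx, drop = FALSE])
    out[, , idx] <- S[, , idx, drop = FALSE] + eps * sign(g)
  }
  dim(out) <- dims
  out
}

#' Additive Gaussian corruption
#'
#' Adds i.i.d. `N(0, sigma^2)` noise per pixel (the inputs are already
#' normalized to zero mean).  Uses R's RNG; wrap in `set.seed()` for a
#' reproducible noise field.  `sigma = 0` is the identity.
#'
#' @param S Numeric array.
#' @param sigma Noise standard deviation (>= 0).
#' @return Array of the same shape.
#' @export
gaussian_corrupt <- function(S, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(S)
  S + array(stats::rnorm(length(S), sd = sigma), dim(S))
}

#' Default progressive corruption grids
#'
#' FGSM magnitudes 0.02..0.2 in steps of 0.02; Gaussian standard
#' deviations 0.025..0.25 in steps of 0.025 (10 levels each).
#'
#' @return Numeric vector of levels.
#' @export
fgsm_grid <- function() seq(0.02, 0.2, by = 0.02)

#' @rdname fgsm_grid
#' @export
gaussian_grid <- function() seq(0.025, 0.25, by = 0.025)

#' Progressive corruption sweep
#'
#' Evaluates a model's region metrics at each corruption level of one kind
#' (`"fgsm"` or `"gaussian"`), per subject.  Levels must be nondecreasing;
#' a level of 0 reproduces the clean evaluation.  Gaussian levels draw
#' fresh noise per level from R's RNG (seed with `set.seed()` or the `seed`
#' argument for reproducible sweeps); FGSM levels are deterministic given
#' the weights.
#'
#' @param model A model usable with [evaluate_model()].
#' @param subjects List of `subject_volume`s.
#' @param kind `"fgsm"` or `"gaussian"`.
#' @param levels Nondecreasing numeric vector of levels (defaults to the
#'   kind's standard grid).
#' @param specs Region definitions.
#' @param seed Optional seed.
#' @return A data.frame of per-subject rows (columns of
#'   [evaluate_model()]), one block per level.
#' @export
corruption_sweep <- function(model, subjects, kind = c("fgsm", "gaussian"),
                             levels = NULL, specs = region_specs(),
                             seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(levels)) {
    levels <- if (kind == "fgsm") fgsm_grid() else gaussian_grid()
  }
  if (length(levels) == 0) stop("levels must be nonempty")
  if (is.unsorted(levels)) stop("levels must be nondecreasing")
  if (!is.null(seed)) set.seed(seed)
  cond <- if (kind == "fgsm") condition_fgsm else condition_gaussian
  out <- do.call(rbind, lapply(levels, function(lv) {
    evaluate_model(model, subjects, cond(lv), specs = specs)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize a sweep to mean +/- sd per level and region
#' @param sweep A data.frame from [corruption_sweep()].
#' @return A data.frame with per (kind, level, region) mean and sd across
#'   subjects.
#' @export
sweep_summary <- function(sweep) summarize_metrics(sweep)
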