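# HU-region Dice and MAE evaluation.
#
# Four regions are derived from Hounsfield thresholds: whole head
# (hu >= -500, i.e. not air), air (hu < -500), bone (hu > 500) and soft
# tissue (-500 < hu < 300); there is a genuine gap (300..500 HU) belonging
# to no region other than "whole".  Dice compares the prediction-derived
# mask against the ground-truth-derived mask; MAE is averaged over the
# ground-truth-derived mask only, so it cannot be gamed by mask prediction.
# All metrics are pooled over the full 3D volume of each subject.

#' Region definitions in Hounsfield units
#'
#' @param air_upper Upper (exclusive) HU bound of air; default -500.
#' @param bone_lower Lower (exclusive) HU bound of bone; default 500.
#' @param soft Open interval bounds of soft tissue; default (-500, 300).
#' @return Named list of region specification lists, one per region name
#'   (`whole`, `air`, `bone`, `soft`).
#' @export
region_specs <- function(air_upper = -500, bone_lower = 500,
                         soft = c(-500, 300)) {
  list(whole = list(name = "whole", lower = air_upper, upper = Inf,
                    lower_closed = TRUE),
       air = list(name = "air", lower = -Inf, upper = air_upper,
                  lower_closed = FALSE),
       bone = list(name = "bone", lower = bone_lower, upper = Inf,
                   lower_closed = FALSE),
       soft = list(name = "soft", lower = soft[1], upper = soft[2],
                   lower_closed = FALSE))
}

#' Threshold a HU volume into a region mask
#'
#' @param volume_hu Numeric array in Hounsfield units.
#' @param region A region name (`"whole"`, `"air"`, `"bone"`, `"soft"`) or
#'   one entry of [region_specs()].
#' @param specs Region definitions (used when `region` is a name).
#' @return Logical array of the same shape.
#' @export
region_mask <- function(volume_hu, region, specs = region_specs()) {
  if (is.character(region)) {
    region <- specs[[match.arg(region, names(specs))]]
  }
  lo <- if (isTRUE(region$lower_closed)) volume_hu >= region$lower
        else volume_hu > region$lower
  lo & volume_hu < region$upper
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks overlap perfectly by
#' convention (1); an empty ground truth with a nonempty prediction scores
#' 0 from the formula itself.
#'
#' @param mask_a,mask_b Logical arrays of identical shape.
#' @return Numeric in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b))
    stop("mask shapes differ")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) return(1)
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Mean absolute error over a region
#'
#' @param pred_hu,gt_hu Numeric arrays in Hounsfield units.
#' @param mask Logical array (normally derived from the ground truth).
#' @return Mean of `|pred - gt|` over the mask, or `NA_real_` (with a
#'   warning) when the mask is empty - an undefined region is reported as
#'   missing, never as 0.
#' @export
mae_region <- function(pred_hu, gt_hu, mask) {
  if (!any(mask)) {
    warning("empty region mask: MAE undefined, reported as NA")
    return(NA_real_)
  }
  mean(abs(pred_hu[mask] - gt_hu[mask]))
}

#' Evaluation conditions
#'
#' `condition_clean()` evaluates unmodified inputs; `condition_fgsm(eps)`
#' perturbs every slice with the fast gradient sign method at the model's
#' own gradients before prediction; `condition_gaussian(sigma)` adds
#' i.i.d. pixel noise.
#'
#' @param eps FGSM magnitude.
#' @param sigma Gaussian noise standard deviation.
#' @return A condition descriptor list.
#' @export
condition_clean <- function() list(kind = "clean", level = 0)

#' @rdname condition_clean
#' @export
condition_fgsm <- function(eps) {
  stopifnot(eps >= 0)
  list(kind = "fgsm", level = eps)
}

#' @rdname condition_clean
#' @export
condition_gaussian <- function(sigma) {
  stopifnot(sigma >= 0)
  list(kind = "gaussian", level = sigma)
}

condition_label <- function(condition) {
  if (condition$kind == "clean" || condition$level == 0) "clean"
  else sprintf("%s(%g)", condition$kind, condition$level)
}

#' Evaluate a model's region metrics on subject volumes
#'
#' For every subject the source slices are (optionally) corrupted per
#' `condition`, predicted, denormalized to Hounsfield units and pooled into
#' the 3D volume, on which per-region Dice (prediction mask vs ground-truth
#' mask) and MAE (over the ground-truth mask) are computed.
#'
#' @param model A model with [predict()] (and, for FGSM conditions,
#'   [input_gradient()]) methods; a `unet_model` or `trained_unet`.
#' @param subjects List of `subject_volume`s.
#' @param condition A condition descriptor ([condition_clean()] and
#'   friends).
#' @param specs Region definitions.
#' @param batch_size Slices per forward pass.
#' @return A data.frame with one row per subject x region: `subject_id`,
#'   `condition`, `kind`, `level`, `region`, `dice`, `mae`.
#' @export
evaluate_model <- function(model, subjects, condition = condition_clean(),
                           specs = region_specs(), batch_size = 16L) {
  if (condition$level == 0) condition <- condition_clean()
  rows <- lapply(subjects, function(s) {
    S <- s$source
    if (condition$kind == "fgsm" && condition$level > 0) {
      S <- fgsm_perturb(model, S, s$target_norm, condition$level,
                        batch_size = batch_size)
    } else if (condition$kind == "gaussian" && condition$level > 0) {
      S <- gaussian_corrupt(S, condition$level)
    }
    pred_hu <- denormalize_ct(predict(model, S, batch_size = batch_size))
    res <- lapply(names(specs), function(rn) {
      gt_mask <- region_mask(s$target_hu, specs[[rn]])
      pr_mask <- region_mask(pred_hu, specs[[rn]])
      data.frame(subject_id = s$subject_id,
                 condition = condition_label(condition),
                 kind = condition$kind, level = condition$level,
                 region = rn,
                 dice = dice(pr_mask, gt_mask),
                 mae = mae_region(pred_hu, s$target_hu, gt_mask))
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-subject metrics to mean and sd per region
#' @param metrics A data.frame from [evaluate_model()] (possibly several
#'   conditions bound together).
#' @return A data.frame with per (condition, region) mean and sd of Dice
#'   and MAE across subjects.
#' @export
summarize_metrics <- function(metrics) {
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  sp <- split(metrics, list(metrics$condition, metrics$region), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(condition = d$condition[1], region = d$region[1],
               kind = d$kind[1], level = d$level[1],
               dice_mean = mean(d$dice), dice_sd = stats::sd(d$dice),
               mae_mean = mean(d$mae), mae_sd = stats::sd(d$mae),
               n_subjects = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$region), ]
}
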