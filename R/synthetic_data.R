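# Paired pseudo-MR/CT head phantoms.
#
# Institutional MR/CT pairs cannot be redistributed, so the package
# generates synthetic subjects that reproduce the features the search and
# the metrics depend on: three Hounsfield regimes (air background at
# -1000 HU, a skull ring at 900-1500 HU, soft-tissue interior at 0-80 HU),
# smooth intra-subject anatomy drift across axial slices, per-subject
# geometry variation, and an MR appearance that is a non-monotone function
# of tissue class (bone dark, soft tissue bright, air dark) corrupted by a
# multiplicative bias field and additive Gaussian noise.  MR volumes are
# z-scored per subject; CT volumes are shifted by +1000 and standardized
# with the fixed mean 1250 and deviation 2500.

#' CT intensity normalization
#'
#' Hounsfield units are first shifted so that air (-1000 HU) maps to zero,
#' then standardized with the fixed mean 1250 and deviation 2500:
#' `n = ((hu + 1000) - 1250) / 2500`.  `denormalize_ct` is the exact
#' inverse.  Air is -0.5 in normalized units; 250 HU is 0.
#'
#' @param hu,n Numeric arrays in Hounsfield / normalized units.
#' @return Array of the same shape.
#' @examples
#' normalize_ct(-1000)  # -0.5
#' denormalize_ct(normalize_ct(37))
#' @export
normalize_ct <- function(hu) ((hu + 1000) - 1250) / 2500

#' @rdname normalize_ct
#' @export
denormalize_ct <- function(n) n * 2500 + 1250 - 1000

#' Per-volume z-score normalization
#' @param v Numeric array.
#' @return `v` centred to mean 0 and scaled to standard deviation 1.
#' @export
zscore_volume <- function(v) {
  (v - mean(v)) / stats::sd(v)
}

# Smooth random field in [-1, 1]-ish range: coarse Gaussian grid, bilinear
# interpolation up to size x size.
smooth_field <- function(size, knots = 4L, sd = 1) {
  coarse <- matrix(stats::rnorm(knots * knots, sd = sd), knots, knots)
  pos <- seq(1, knots, length.out = size)
  i0 <- pmin(floor(pos), knots - 1L); fi <- pos - i0
  row_interp <- coarse[i0, , drop = FALSE] * (1 - fi) +
    coarse[i0 + 1L, , drop = FALSE] * fi
  out <- row_interp[, i0, drop = FALSE] * rep(1 - fi, each = size) +
    row_interp[, i0 + 1L, drop = FALSE] * rep(fi, each = size)
  out
}

#' Generate one paired pseudo-MR/CT subject
#'
#' Builds an axial stack of elliptical head phantoms: air background
#' (-1000 HU), a skull ring (900-1500 HU) and a soft-tissue interior
#' (0-80 HU), with the head's radii drifting smoothly across slices and
#' random per-subject geometry.  The MR source is derived from the tissue
#' class through a non-monotone intensity map, modulated by a
#' multiplicative bias field and additive Gaussian noise, then z-scored
#' volume-wise.  Uses R's RNG (seed with `set.seed()` for bit-identical
#' volumes).
#'
#' @param subject_id Identifier string.
#' @param n_slices Number of axial slices (default 182).
#' @param size Slice height/width in pixels (default 256; must be an even
#'   number >= 8).  Running a depth-d network additionally requires
#'   divisibility by `2^d`, which is checked at forward time.
#' @return An object of class `subject_volume` with fields `subject_id`,
#'   `source` (z-scored MR), `target_hu`, `target_norm`, `labels`
#'   (0 = air, 1 = soft tissue, 2 = bone), each an (H, W, n_slices) array.
#' @export
generate_subject <- function(subject_id = "subj", n_slices = 182L, size = 256L) {
  n_slices <- as.integer(n_slices); size <- as.integer(size)
  if (n_slices < 1L) stop("n_slices must be >= 1")
  if (size < 8L || size %% 2L != 0L)
    stop("size must be an even integer >= 8")
  half <- size / 2
  # per-subject geometry
  ax0 <- stats::runif(1, 0.62, 0.78) * half
  ay0 <- stats::runif(1, 0.70, 0.86) * half
  cx <- half + stats::runif(1, -0.05, 0.05) * size
  cy <- half + stats::runif(1, -0.05, 0.05) * size
  th <- max(1 / half, stats::runif(1, 0.10, 0.16))   # relative ring thickness
  phase <- stats::runif(1, 0, pi)
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  hu <- array(-1000, c(size, size, n_slices))
  labels <- array(0L, c(size, size, n_slices))
  mr <- array(0, c(size, size, n_slices))
  for (z in seq_len(n_slices)) {
    u <- if (n_slices == 1L) 0.5 else (z - 1) / (n_slices - 1)
    scale <- 0.82 + 0.18 * sin(pi * u + phase * 0.1) + 0.04 * sin(3 * pi * u)
    # guard rails keep every tissue class nonempty on coarse grids
    ax <- max(ax0 * scale, 3); ay <- max(ay0 * scale, 3)
    th_eff <- max(th, 1.2 / min(ax, ay))
    r2 <- ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2
    inner2 <- ((xg - cx) / (ax * (1 - th_eff)))^2 + ((yg - cy) / (ay * (1 - th_eff)))^2
    bone <- r2 <= 1 & inner2 > 1
    soft <- inner2 <= 1
    lab <- matrix(0L, size, size)
    lab[bone] <- 2L
    lab[soft] <- 1L
    bone_tex <- 1200 + 280 * tanh(smooth_field(size, 4L, 0.6))
    soft_tex <- 40 + 38 * tanh(smooth_field(size, 5L, 0.6))
    slice_hu <- matrix(-1000, size, size)
    slice_hu[bone] <- bone_tex[bone]
    slice_hu[soft] <- soft_tex[soft]
    hu[, , z] <- slice_hu
    labels[, , z] <- lab
    # non-monotone MR appearance: air and bone dark, soft tissue bright
    mr_slice <- matrix(0.04, size, size)
    mr_slice[bone] <- 0.15 + 0.03 * tanh(smooth_field(size, 4L, 0.5))[bone]
    mr_slice[soft] <- 0.85 + 0.08 * tanh(smooth_field(size, 5L, 0.5))[soft]
    bias <- 1 + 0.25 * tanh(smooth_field(size, 3L, 0.5))
    mr[, , z] <- mr_slice * bias + stats::rnorm(size * size, sd = 0.03)
  }
  structure(list(subject_id = subject_id,
                 source = zscore_volume(mr),
                 target_hu = hu,
                 target_norm = normalize_ct(hu),
                 labels = labels),
            class = "subject_volume")
}

#' @export
print.subject_volume <- function(x, ...) {
  d <- dim(x$source)
  cat(sprintf("subject %s: %d slices of %dx%d (air %.0f%%, soft %.0f%%, bone %.0f%%)\n",
              x$subject_id, d[3], d[1], d[2],
              100 * mean(x$labels == 0L), 100 * mean(x$labels == 1L),
              100 * mean(x$labels == 2L)))
  invisible(x)
}

new_split <- function(train, val, test) {
  structure(list(train = train, val = val, test = test), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  n <- vapply(x[c("train", "val", "test")], length, integer(1))
  im <- vapply(x[c("train", "val", "test")], function(s) {
    if (length(s) == 0) 0L else sum(vapply(s, function(v) dim(v$source)[3], integer(1)))
  }, integer(1))
  cat(sprintf("cohort split: train %d subjects (%d images), val %d (%d), test %d (%d)\n",
              n[1], im[1], n[2], im[2], n[3], im[3]))
  invisible(x)
}

#' Images per split part
#' @param split A `cohort_split`.
#' @return Named integer vector (train, val, test) of slice counts.
#' @export
n_images <- function(split) {
  vapply(split[c("train", "val", "test")], function(s) {
    if (length(s) == 0) 0L else
      sum(vapply(s, function(v) dim(v$source)[3], integer(1)))
  }, integer(1))
}

#' Generate a subject-disjoint synthetic cohort
#'
#' Generates `n_train + n_val + n_test` subjects and assigns them to
#' subject-disjoint splits by random permutation.  The default sizes mirror
#' the study cohort: 63 training, 9 validation and 7 held-out test subjects
#' of 182 slices each, giving 11466/1638/1274 images.
#'
#' @param n_train,n_val,n_test Subjects per split.
#' @param n_slices Slices per subject.
#' @param size Slice size in pixels.
#' @param seed Optional seed for a reproducible cohort.
#' @return A `cohort_split`.
#' @export
generate_cohort <- function(n_train = 63L, n_val = 9L, n_test = 7L,
                            n_slices = 182L, size = 256L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- n_train + n_val + n_test
  subjects <- lapply(seq_len(total), function(i) {
    generate_subject(sprintf("subj%03d", i), n_slices = n_slices, size = size)
  })
  ord <- sample.int(total)
  new_split(train = subjects[ord[seq_len(n_train)]],
            val = subjects[ord[n_train + seq_len(n_val)]],
            test = subjects[ord[n_train + n_val + seq_len(n_test)]])
}

#' Form the search subdataset from the training subjects
#'
#' Selects `n_subjects` training subjects at random and partitions them
#' subject-disjointly into train/val/test parts by `ratio` (default 4:1:1
#' over 6 subjects, the cheap split on which every candidate architecture's
#' robustness is estimated).
#'
#' @param train_subjects List of subject volumes (e.g. `cohort$train`), or a
#'   `cohort_split` whose `$train` is used.
#' @param n_subjects Number of subjects to select.
#' @param ratio Length-3 integer ratio (train:val:test); its sum must
#'   divide `n_subjects`.
#' @param seed Optional seed.
#' @return A `cohort_split`.
#' @export
make_subdataset <- function(train_subjects, n_subjects = 6L, ratio = c(4L, 1L, 1L),
                            seed = NULL) {
  if (inherits(train_subjects, "cohort_split")) train_subjects <- train_subjects$train
  if (!is.null(seed)) set.seed(seed)
  n_subjects <- as.integer(n_subjects)
  ratio <- as.integer(ratio)
  if (length(ratio) != 3L || any(ratio < 0L))
    stop("ratio must be three non-negative integers")
  if (length(train_subjects) < n_subjects)
    stop("not enough training subjects: have ", length(train_subjects),
         ", need ", n_subjects)
  if (n_subjects %% sum(ratio) != 0L)
    stop(sprintf("ratio %s is not realizable with %d subjects",
                 paste(ratio, collapse = ":"), n_subjects))
  unit <- n_subjects %/% sum(ratio)
  counts <- ratio * unit
  chosen <- sample(seq_along(train_subjects), n_subjects)
  new_split(train = train_subjects[chosen[seq_len(counts[1])]],
            val = train_subjects[chosen[counts[1] + seq_len(counts[2])]],
            test = train_subjects[chosen[counts[1] + counts[2] + seq_len(counts[3])]])
}

#' Write/read a cohort as NIfTI volumes
#'
#' Each subject is stored as `<id>_mr.nii.gz` (z-scored source),
#' `<id>_ct.nii.gz` (Hounsfield units) and `<id>_labels.nii.gz`, with a
#' `manifest.json` recording split membership.  `read_cohort` reconstructs
#' the split; normalized CT is recomputed from the stored HU volume.
#'
#' @param split A `cohort_split`.
#' @param dir Directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `cohort_split`.
#' @export
write_cohort <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (part in c("train", "val", "test")) {
    ids <- character(0)
    for (s in split[[part]]) {
      RNifti::writeNifti(RNifti::asNifti(s$source),
                         file.path(dir, paste0(s$subject_id, "_mr.nii.gz")))
      RNifti::writeNifti(RNifti::asNifti(s$target_hu),
                         file.path(dir, paste0(s$subject_id, "_ct.nii.gz")))
      RNifti::writeNifti(RNifti::asNifti(s$labels),
                         file.path(dir, paste0(s$subject_id, "_labels.nii.gz")))
      ids <- c(ids, s$subject_id)
    }
    manifest[[part]] <- ids
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  load_subject <- function(id) {
    arr <- function(suffix) {
      a <- as.array(RNifti::readNifti(file.path(dir, paste0(id, suffix))))
      if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
      a
    }
    hu <- arr("_ct.nii.gz")
    structure(list(subject_id = id, source = arr("_mr.nii.gz"),
                   target_hu = hu, target_norm = normalize_ct(hu),
                   labels = array(as.integer(round(arr("_labels.nii.gz"))),
                                  dim(hu))),
              class = "subject_volume")
  }
  parts <- lapply(manifest[c("train", "val", "test")], function(ids) {
    lapply(as.character(unlist(ids)), load_subject)
  })
  new_split(parts$train, parts$val, parts$test)
}
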