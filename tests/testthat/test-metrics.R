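test_that("region thresholds implement the HU definitions", {
  vol <- array(c(-1000, -600, -400, 0, 250, 400, 600, 1200), c(2, 2, 2))
  expect_identical(sum(region_mask(vol, "air")), 2L)     # -1000, -600
  expect_identical(sum(region_mask(vol, "bone")), 2L)    # 600, 1200
  expect_identical(sum(region_mask(vol, "soft")), 3L)    # -400, 0, 250
  # 400 HU falls in the genuine gap between soft and bone
  expect_false(region_mask(vol, "soft")[vol == 400][1])
  expect_false(region_mask(vol, "bone")[vol == 400][1])
  # air and whole partition the volume under the defaults
  expect_true(all(xor(region_mask(vol, "air"), region_mask(vol, "whole"))))
  # an all-air volume
  allair <- array(-1000, c(3, 3))
  expect_true(all(region_mask(allair, "air")))
  expect_false(any(region_mask(allair, "bone")))
})

test_that("Dice handles identity, disjoint, partial and empty masks", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2))
  b <- array(c(FALSE, FALSE, TRUE, TRUE), c(2, 2))
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, b), 0)
  m1 <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), c(2, 4))
  m2 <- array(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE), c(2, 4))
  expect_identical(dice(m1, m2), 0.5)          # |A|=4, |B|=4, |A^B|=2
  none <- array(FALSE, c(2, 2))
  expect_identical(dice(none, none), 1)        # both-empty convention
  expect_identical(dice(a, none), 0)
  expect_error(dice(a, array(TRUE, c(3, 3))), "shapes differ")
  # symmetry and permutation invariance
  set.seed(1)
  x <- array(runif(64) > 0.5, c(4, 4, 4))
  y <- array(runif(64) > 0.5, c(4, 4, 4))
  expect_identical(dice(x, y), dice(y, x))
  p <- sample(64)
  expect_identical(dice(array(x[p], dim(x)), array(y[p], dim(y))), dice(x, y))
})

test_that("region MAE reports offsets exactly and empty regions as missing", {
  gt <- array(100, c(4, 4))
  mask <- array(TRUE, c(4, 4))
  expect_identical(mae_region(gt, gt, mask), 0)
  expect_identical(mae_region(gt + 10, gt, mask), 10)
  chk <- gt + 5 * rep_len(c(1, -1), 16)
  expect_identical(mae_region(chk, gt, mask), 5)
  expect_warning(v <- mae_region(gt, gt, array(FALSE, c(4, 4))), "empty")
  expect_true(is.na(v))
})

test_that("an oracle model scores Dice 1 and MAE 0 in all four regions", {
  set.seed(2)
  s <- generate_subject("orc", n_slices = 3, size = 16)
  om <- oracle_model(s)
  ev <- evaluate_model(om, list(s), condition_clean())
  expect_identical(nrow(ev), 4L)
  expect_true(all(ev$dice == 1))
  # denormalize(normalize(hu)) leaves ~1e-13 HU floating-point residue
  expect_lt(max(ev$mae), 1e-9)
})

test_that("volume-wise metrics equal a brute-force slice-pooled recomputation", {
  set.seed(3)
  s <- generate_subject("bf", n_slices = 4, size = 16)
  m <- build_model(tiny_genotype())
  ev <- evaluate_model(m, list(s), condition_clean())
  pred_hu <- denormalize_ct(predict(m, s$source))
  for (region in c("whole", "air", "bone", "soft")) {
    # independent recomputation: accumulate per-slice overlap counts and
    # absolute errors, then pool
    inter <- 0; na <- 0; nb <- 0; abs_sum <- 0; n_mask <- 0
    for (z in seq_len(dim(s$source)[3])) {
      gm <- region_mask(s$target_hu[, , z], region)
      pm <- region_mask(pred_hu[, , z], region)
      inter <- inter + sum(gm & pm)
      na <- na + sum(pm); nb <- nb + sum(gm)
      abs_sum <- abs_sum + sum(abs(pred_hu[, , z][gm] - s$target_hu[, , z][gm]))
      n_mask <- n_mask + sum(gm)
    }
    expect_equal(ev$dice[ev$region == region], 2 * inter / (na + nb),
                 tolerance = 1e-12)
    expect_equal(ev$mae[ev$region == region], abs_sum / n_mask,
                 tolerance = 1e-12)
  }
})

test_that("clean condition equals FGSM at eps = 0", {
  set.seed(4)
  s <- generate_subject("z", n_slices = 2, size = 16)
  m <- build_model(minimal_genotype())
  a <- evaluate_model(m, list(s), condition_clean())
  b <- evaluate_model(m, list(s), condition_fgsm(0))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("metrics survive the normalize/denormalize round trip", {
  set.seed(5)
  s <- generate_subject("rt", n_slices = 2, size = 16)
  hu2 <- denormalize_ct(normalize_ct(s$target_hu))
  for (region in c("whole", "air", "bone", "soft")) {
    m1 <- region_mask(s$target_hu, region)
    m2 <- region_mask(hu2, region)
    expect_lt(abs(dice(m1, m2) - 1), 1e-6)
  }
})
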