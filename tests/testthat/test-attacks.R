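test_that("FGSM follows the sign-gradient formula exactly", {
  set.seed(1)
  g <- tiny_genotype()
  m <- build_model(g)
  S <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  T <- array(rnorm(32 * 32 * 2), c(32, 32, 2))

  expect_identical(fgsm_perturb(m, S, T, 0), S)

  Sa <- fgsm_perturb(m, S, T, 0.2)
  grad <- input_gradient(m, S, T)
  d <- Sa - S
  nz <- grad != 0
  expect_true(all(abs(d[nz]) - 0.2 < 1e-14))
  expect_equal(max(abs(d)), 0.2, tolerance = 1e-14)
  expect_true(all(d[!nz] == 0))
  # pure function of (weights, S, T, eps): bitwise repeatable
  expect_identical(Sa, fgsm_perturb(m, S, T, 0.2))
})

test_that("FGSM on the linear model matches the closed-form oracle", {
  w <- -1.3; b <- 0.4
  lm <- linear_synth_model(w, b)
  set.seed(2)
  S <- array(rnorm(64), c(8, 8, 1))
  T <- array(rnorm(64), c(8, 8, 1))
  # l = mean((wS + b - T)^2); grad_S = 2w(wS + b - T)/n, so
  # S_adv = S + eps * sign(wS + b - T) * sign(w) elementwise
  expected <- S + 0.1 * sign(w * S + b - T) * sign(w)
  expect_equal(fgsm_perturb(lm, S, T, 0.1), expected, tolerance = 1e-12)
})

test_that("FGSM sign agrees with a finite-difference oracle on >=95% of pixels", {
  set.seed(3)
  g <- genotype(list(block_config("1110", 4, se = TRUE, se_ratio = 2)),
                list(block_config("0011", 4)))
  m <- build_model(g)
  S <- array(rnorm(64), c(8, 8, 1))
  T <- array(rnorm(64), c(8, 8, 1))
  grad <- input_gradient(m, S, T)
  h <- 1e-5
  loss_at <- function(Sx) robunet:::model_loss(m, Sx, T,
                                               want_weight_grads = FALSE)$loss
  fd_sign <- numeric(length(S))
  for (i in seq_along(S)) {
    Sp <- S; Sp[i] <- Sp[i] + h
    Sm <- S; Sm[i] <- Sm[i] - h
    fd_sign[i] <- sign(loss_at(Sp) - loss_at(Sm))
  }
  consider <- abs(grad) > 1e-10   # exclude ties at zero gradient
  agree <- mean(sign(grad[consider]) == fd_sign[consider])
  expect_gte(agree, 0.95)
})

test_that("Gaussian corruption has the requested noise scale and seed", {
  set.seed(4)
  S <- array(0, c(100, 100, 10))
  expect_identical(gaussian_corrupt(S, 0), S)
  set.seed(5); a <- gaussian_corrupt(S, 0.1)
  set.seed(5); b <- gaussian_corrupt(S, 0.1)
  expect_identical(a, b)
  n <- length(S)
  s_hat <- sd(c(a - S))
  # chi-square 3-sigma band on the sample sd of n iid normals
  expect_lt(abs(s_hat - 0.1), 3 * 0.1 / sqrt(2 * (n - 1)))
})

test_that("default corruption grids have ten levels at the stated steps", {
  expect_equal(fgsm_grid(), seq(0.02, 0.2, by = 0.02), tolerance = 1e-12)
  expect_length(fgsm_grid(), 10L)
  expect_equal(gaussian_grid(), seq(0.025, 0.25, by = 0.025),
               tolerance = 1e-12)
  expect_length(gaussian_grid(), 10L)
})

test_that("sweep at level zero equals the clean evaluation", {
  set.seed(6)
  subj <- list(generate_subject("t1", n_slices = 2, size = 16))
  m <- build_model(minimal_genotype())
  sw <- corruption_sweep(m, subj, "fgsm", levels = c(0, 0.1))
  clean <- evaluate_model(m, subj, condition_clean())
  lvl0 <- sw[sw$level == 0, names(clean)]
  rownames(lvl0) <- NULL
  expect_equal(lvl0, clean, tolerance = 1e-12)
  expect_error(corruption_sweep(m, subj, "fgsm", levels = c(0.2, 0.1)),
               "nondecreasing")
  expect_error(corruption_sweep(m, subj, "fgsm", levels = numeric(0)),
               "nonempty")
})

test_that("for a random-weight model FGSM at 0.2 is no better than clean", {
  # Monte-Carlo sanity: adversarial inputs should not help an untrained
  # model on average
  deltas <- numeric(5)
  for (s in 1:5) {
    set.seed(30 + s)
    subj <- list(generate_subject("u", n_slices = 2, size = 16))
    m <- build_model(tiny_genotype())
    clean <- evaluate_model(m, subj, condition_clean())
    rob <- evaluate_model(m, subj, condition_fgsm(0.2))
    deltas[s] <- mean(rob$dice[rob$region == "whole"]) -
      mean(clean$dice[clean$region == "whole"])
  }
  expect_lte(mean(deltas), 0.05)
})
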