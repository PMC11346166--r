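test_that("every connection pattern builds and preserves shape at depth 1", {
  set.seed(3)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  for (p in 1:15) {
    g <- genotype(list(block_config(p, 4L)), list(block_config(p, 4L)))
    m <- build_model(g)
    y <- predict(m, x)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
})

test_that("the reference depth-5 architecture builds and maps 64x64 to 64x64", {
  set.seed(4)
  m <- build_model(searched_genotype())
  x <- array(rnorm(64 * 64), c(64, 64, 1))
  y <- predict(m, x)
  expect_identical(dim(y), c(64L, 64L, 1L))
})

test_that("inputs not divisible by 2^depth raise a shape error", {
  set.seed(5)
  g <- genotype(list(block_config(1, 4), block_config(1, 4)),
                list(block_config(1, 4), block_config(1, 4)))
  m <- build_model(g)
  expect_error(predict(m, array(0, c(30, 30, 1))), "2\\^depth")
  expect_silent(predict(m, array(0, c(32, 32, 1))))
})

test_that("parameter count equals the hand-computed layer-by-layer sum", {
  set.seed(6)
  m <- build_model(minimal_genotype())
  # encoder: branch A1 1x1 conv 1->8 (16), fuse 1x1 8->8 (72),
  # downsample 4x4 8->8 (1032), post 3x3 8->8 (584)          = 1704
  # decoder input 8(prev)+8(skip)=16 channels:
  #   branch A1 1x1 16->8 (136), fuse (72), post (584)       = 792
  # head 1x1 8->1                                            = 9
  expect_identical(parameter_count(m), 1704L + 792L + 9L)

  # adding an SE block with ratio 4 on the encoder adds
  # 8*2+2 + 2*8+8 = 42 parameters
  g_se <- genotype(list(block_config("0001", 8L, se = TRUE, se_ratio = 4L)),
                   list(block_config("0001", 8L)))
  set.seed(6)
  expect_identical(parameter_count(build_model(g_se)), 2505L + 42L)
})

test_that("encoder halves resolution once per depth level", {
  set.seed(8)
  for (d in 1:3) {
    blocks <- function() lapply(seq_len(d), function(i) block_config(1, 4))
    m <- build_model(genotype(blocks(), blocks()))
    x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
    fw <- robunet:::model_forward(m, x, want_cache = TRUE)
    # the deepest encoder's post-convolution output has size 32 / 2^d
    deep <- fw$caches[[paste0("enc", d)]]$post$conv
    expect_identical(deep$H, as.integer(32 / 2^d))
  }
})

test_that("autodiff input gradient agrees with finite differences", {
  set.seed(9)
  g <- genotype(list(block_config("1011", 4, se = TRUE, se_ratio = 2)),
                list(block_config("0111", 4)))
  m <- build_model(g)
  S <- array(rnorm(8 * 8), c(8, 8, 1))
  T <- array(rnorm(8 * 8), c(8, 8, 1))
  grad <- input_gradient(m, S, T)
  expect_true(any(grad != 0))
  loss_at <- function(Sx) robunet:::model_loss(m, Sx, T,
                                               want_weight_grads = FALSE)$loss
  h <- 1e-5
  idx <- sample(length(S), 30)
  for (i in idx) {
    Sp <- S; Sp[i] <- Sp[i] + h
    Sm <- S; Sm[i] <- Sm[i] - h
    fd <- (loss_at(Sp) - loss_at(Sm)) / (2 * h)
    expect_lt(abs(fd - grad[i]) / max(1e-8, abs(fd)), 1e-3)
  }
})

test_that("SE recalibration gates channels uniformly over space", {
  set.seed(10)
  # layout (H, W, N, C): batch of 2 maps with 8 channels
  x <- array(rnorm(6 * 6 * 2 * 8), c(6, 6, 2, 8))
  # zero pre-activations force a sigmoid gate of exactly 0.5
  p <- list(W1 = matrix(0, 8, 2), b1 = numeric(2),
            W2 = matrix(0, 2, 8), b2 = numeric(8))
  y <- se_recalibrate(x, ratio = 4, params = p)
  expect_equal(y, 0.5 * x, tolerance = 1e-12)

  # ratio larger than C clamps the bottleneck to one unit, no failure
  y2 <- se_recalibrate(x, ratio = 16)
  expect_identical(dim(y2), dim(x))

  # per-channel output/input ratio is constant over the spatial grid
  set.seed(11)
  p3 <- robunet:::se_init(8L, 2L)
  y3 <- se_recalibrate(x, ratio = 2, params = p3)
  ratio <- y3 / x
  for (cc in 1:8) for (n in 1:2) {
    rc <- ratio[, , n, cc]
    expect_lt(diff(range(rc)), 1e-12)
  }
})

test_that("genotype-free linear model reproduces w*S + b", {
  lm <- linear_synth_model(2.5, -1)
  S <- array(seq(-1, 1, length.out = 16), c(4, 4, 1))
  expect_equal(predict(lm, S), 2.5 * S - 1, tolerance = 1e-12)
})
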