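test_that("adversarial batch loss has exact Bernoulli limits", {
  set.seed(1)
  split <- tiny_split(n_slices = 4, size = 16)
  sl <- robunet:::collect_slices(split$train)
  S <- sl$S[, , 1:4]; T <- sl$T[, , 1:4]
  m <- build_model(tiny_genotype())
  clean <- robunet:::model_loss(m, S, T, want_weight_grads = FALSE)$loss
  S_adv <- fgsm_perturb(m, S, T, 0.2)
  adv <- robunet:::model_loss(m, S_adv, T, want_weight_grads = FALSE)$loss
  expect_equal(adversarial_batch_loss(m, S, T, eps = 0.2, p_r = 1), clean,
               tolerance = 1e-12)
  expect_equal(adversarial_batch_loss(m, S, T, eps = 0.2, p_r = 0), adv,
               tolerance = 1e-12)
  # attacks raise the loss for this fixed model
  expect_gt(adv, clean)
})

test_that("p_r = 0.5 mixes clean and adversarial losses in expectation", {
  set.seed(2)
  split <- tiny_split(n_slices = 4, size = 16)
  sl <- robunet:::collect_slices(split$train)
  S <- sl$S[, , 1:6]; T <- sl$T[, , 1:6]
  m <- build_model(tiny_genotype())
  clean <- robunet:::model_loss(m, S, T, want_weight_grads = FALSE)$loss
  S_adv <- fgsm_perturb(m, S, T, 0.2)
  adv <- robunet:::model_loss(m, S_adv, T, want_weight_grads = FALSE)$loss
  n_draws <- 500L
  set.seed(3)
  draws <- vapply(seq_len(n_draws), function(i) {
    adversarial_batch_loss(m, S, T, eps = 0.2, p_r = 0.5)
  }, numeric(1))
  target <- 0.5 * clean + 0.5 * adv
  se <- sd(draws) / sqrt(n_draws)
  expect_lt(abs(mean(draws) - target), 3 * se)
})

test_that("early stopping fires after `patience` non-improving epochs", {
  set.seed(4)
  split <- tiny_split(n_train = 1, n_slices = 2, size = 16)
  m <- build_model(minimal_genotype())
  # a vanishing learning rate freezes the weights, so the validation loss
  # never improves after epoch 1: training must stop at epoch 1 + patience
  fit <- train(m, split, train_config(epochs = 50, lr = 1e-30, patience = 5,
                                      seed = 1))
  expect_identical(fit$epochs_run, 6L)
  expect_identical(fit$best_epoch, 1L)
  # and early stopping never exceeds the epoch budget
  fit2 <- train(m, split, train_config(epochs = 3, lr = 1e-30, patience = 5,
                                       seed = 1))
  expect_lte(fit2$epochs_run, 3L)
})

test_that("training is seeded, tracked, and selects the arg-min epoch", {
  set.seed(5)
  split <- tiny_split(n_slices = 4, size = 16)
  set.seed(6); m <- build_model(tiny_genotype())
  cfg <- train_config(epochs = 4, lr = 1e-3, patience = NULL, seed = 11)
  fit1 <- train(m, split, cfg)
  fit2 <- train(m, split, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(nrow(fit1$history), fit1$epochs_run)
  expect_identical(fit1$best_epoch, which.min(fit1$history$val_loss))
})

test_that("the inner search loop checkpoints every epoch and picks the best", {
  set.seed(7)
  split <- tiny_split(n_slices = 4, size = 16)
  set.seed(8); m <- build_model(minimal_genotype())
  fit <- nas_inner_train(m, split, epochs = 4, seed = 12)
  expect_length(fit$checkpoints, 4L)
  expect_identical(fit$model$params, fit$checkpoints[[fit$best_epoch]])
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("a short run halves the training loss on learnable phantoms", {
  set.seed(9)
  split <- tiny_split(n_slices = 8, size = 32)
  set.seed(10); m <- build_model(tiny_genotype())
  fit <- train(m, split, train_config(epochs = 10, lr = 3e-3, patience = NULL,
                                      seed = 13))
  expect_lt(tail(fit$history$train_loss, 1),
            0.5 * fit$history$train_loss[1])
  # losses are MSE, hence non-negative
  expect_true(all(fit$history$train_loss >= 0))
  expect_true(all(fit$history$val_loss >= 0))
})
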