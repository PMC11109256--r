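test_that("built models output simplex probabilities and count parameters", {
  m <- dla_build("none", seed = 1)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  pr <- predict(m, x)
  expect_equal(dim(pr), c(2, 5))
  expect_equal(rowSums(pr[paste0("p", 0:3)]), rep(1, 2), tolerance = 1e-6)
  expect_true(all(pr$predicted %in% 0:3))

  # sequential attention adds exactly the CA-MLP and SA-conv parameters:
  # C*h + h*C weights + h + C biases + (7*7*2 + 1), with C = 32, h = floor(32/16)
  m_seq <- dla_build("sequential", ratio = 16, seed = 1)
  C <- 32; h <- floor(C / 16)
  expect_equal(m_seq$n_params - m$n_params, (C * h + h * C) + h + C + (7 * 7 * 2 + 1))

  expect_identical(dla_build("sequential", seed = 5)$params,
                   dla_build("sequential", seed = 5)$params)
  expect_error(dla_build("resnet"), "unknown attention variant")
})

test_that("tiny backbone forward pass is fast enough for CPU batches", {
  m <- dla_build("sequential", seed = 0)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4))
  t0 <- Sys.time()
  predict(m, x)
  expect_lt(as.numeric(Sys.time() - t0), 1)
})

test_that("analytic gradients match finite differences for every variant", {
  set.seed(1)
  x <- array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  y <- c(1L, 2L, 3L)
  for (variant in c("none", "ca_only", "sa_only", "sequential", "parallel")) {
    m <- dla_build(variant, ratio = 4, num_classes = 3, channels = c(2L, 3L, 4L),
                   seed = 3)
    # jitter biases so no pre-activation sits exactly on a rectifier kink
    # (finite differences straddle the kink there and disagree with the
    # standard zero subgradient)
    for (nm in grep("_b", names(m$params), value = TRUE))
      m$params[[nm]] <- m$params[[nm]] + runif(length(m$params[[nm]]), 0.01, 0.05)
    out <- dlanet:::nn_loss_grad(m$params, x, y, variant)
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (i in sample(length(p), min(4, length(p)))) {
        eps <- 1e-5
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        lp <- dlanet:::nn_loss_grad(pp, x, y, variant)$loss
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        lm <- dlanet:::nn_loss_grad(pp, x, y, variant)$loss
        num <- (lp - lm) / (2 * eps)
        expect_equal(out$grads[[nm]][i], num, tolerance = 1e-4,
                     info = sprintf("%s / %s[%d]", variant, nm, i))
      }
    }
  }
})

test_that("stratified folds balance classes and resist shuffling", {
  y <- rep(0:3, each = 10)
  f <- stratified_folds(y, n_folds = 5, seed = 1)
  expect_equal(length(f), 40)
  expect_true(all(table(f) == 8))
  for (cl in 0:3) expect_true(all(table(f[y == cl]) == 2))

  # per-class fold-count multiset is invariant under row permutation
  y2 <- c(rep(0, 11), rep(1, 7), rep(2, 9), rep(3, 6))
  f2 <- stratified_folds(y2, 5, seed = 2)
  perm <- sample(length(y2))
  f3 <- stratified_folds(y2[perm], 5, seed = 2)
  for (cl in 0:3)
    expect_equal(sort(tabulate(f2[y2 == cl], 5)), sort(tabulate(f3[y2[perm] == cl], 5)))
  expect_true(all(abs(outer(tabulate(f2[y2 == 0], 5), tabulate(f2[y2 == 0], 5), "-")) <= 1))

  expect_error(stratified_folds(c(0, 0, 0, 1), 5), "stratification error")
})

test_that("a tiny model can overfit four samples to perfect accuracy", {
  set.seed(2)
  x <- replicate(4, matrix(runif(256), 16), simplify = FALSE)
  y <- c(0, 1, 2, 3)
  cfg <- train_config(learning_rate = 5e-3, batch_size = 4, max_epochs = 200,
                      lr_patience = 50, early_stop_patience = 200, seed = 1)
  m <- dla_build("sequential", ratio = 16, channels = c(4L, 8L, 16L), seed = 1)
  fit <- dla_fit(x, y, model = m, config = cfg)
  expect_true(max(fit$history$val_acc) == 1)
  expect_lt(fit$history$train_loss[fit$best_epoch],
            fit$history$train_loss[1])
})

test_that("training is deterministic under a fixed seed", {
  set.seed(3)
  x <- replicate(12, matrix(runif(256), 16), simplify = FALSE)
  y <- rep(0:3, 3)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4, max_epochs = 5,
                      seed = 7)
  f1 <- dla_fit(x, y, variant = "ca_only", config = cfg)
  f2 <- dla_fit(x, y, variant = "ca_only", config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("non-finite inputs abort training with a divergence error", {
  x <- replicate(4, matrix(NaN, 16, 16), simplify = FALSE)
  cfg <- train_config(max_epochs = 2, seed = 1)
  expect_error(dla_fit(x, c(0, 1, 2, 3), variant = "none", config = cfg),
               "divergence error.*epoch 1")
})

test_that("model methods print, summarise and expose coefficients", {
  set.seed(4)
  x <- replicate(8, matrix(runif(256), 16), simplify = FALSE)
  y <- rep(0:3, 2)
  fit <- dla_fit(x, y, variant = "sequential",
                 config = train_config(max_epochs = 3, seed = 1))
  expect_output(print(fit), "trained, best epoch")
  expect_output(summary(fit), "Parameter blocks")
  expect_named(coef(fit), names(fit$params))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
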