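# A small architecture (16 x 16 input, 5/3 kernels, pool 2) keeps the
# numerical checks fast; the default 64 x 64 geometry is exercised in the
# planted-recovery tests.
small_cfg <- function(task = "classification", n_targets = 3L, channels = 2L,
                      seed = 1L, epochs = 5L) {
  cnn_config(task = task, n_targets = n_targets, input_channels = channels,
             input_size = 16L, conv1_kernel = 5L, conv2_kernel = 3L,
             pool = 2L, conv1_filters = 4L, conv2_filters = 6L,
             fc_sizes = c(10L, 12L), epochs = epochs, batch_size = 4L,
             seed = seed)
}

test_that("configurations that collapse the spatial dimensions fail fast", {
  expect_error(cnn_config("classification", 5, 1, input_size = 20),
               "spatial")
  cfg <- cnn_config("classification", 101, 22)
  expect_equal(cfg$dims, list(s1 = 54L, p1 = 13L, s2 = 7L, p2 = 1L))
  expect_error(cnn_config("regression", 3, 1), "single output")
})

test_that("soft-max outputs are normalized probabilities; regression output is unbounded", {
  m <- build_model(small_cfg(n_targets = 7L))
  x <- array(stats::runif(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  pr <- predict_cnn(m, x)
  expect_equal(dim(pr), c(3L, 7L))
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-6)
  r <- build_model(small_cfg("regression", 1L))
  expect_equal(dim(predict_cnn(r, x)), c(3L, 1L))
})

test_that("the parameter count is a deterministic function of the configuration", {
  m1 <- build_model(small_cfg(seed = 1))
  m2 <- build_model(small_cfg(seed = 2))
  expect_equal(n_parameters(m1), n_parameters(m2))
  expect_false(identical(m1$params$W1, m2$params$W1))
  expect_identical(build_model(small_cfg(seed = 1))$params, m1$params)
  # hand-counted: conv (25*2*4 + 4) + conv (9*4*6 + 6) + fc (24*10 + 10)
  # + fc (10*12 + 12) + out (12*3 + 3)
  expect_equal(n_parameters(m1),
               (25 * 2 * 4 + 4) + (9 * 4 * 6 + 6) + (24 * 10 + 10) +
                 (10 * 12 + 12) + (12 * 3 + 3))
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  for (task in c("classification", "regression")) {
    cfg <- small_cfg(task, n_targets = if (task == "regression") 1L else 3L)
    model <- build_model(cfg)
    x <- array(stats::runif(16 * 16 * 2 * 2), c(16, 16, 2, 2))
    y <- if (task == "regression") c(80, 120) else c(0L, 2L)
    patches <- calospec:::input_patches(model, x)
    fwd <- calospec:::cnn_forward(model, patches, keep = TRUE)
    lg <- calospec:::cnn_loss_grad(task, fwd$out, y)
    grads <- calospec:::cnn_backward(model, patches, fwd, lg$grad)
    loss_at <- function(m) {
      f <- calospec:::cnn_forward(m, patches)
      calospec:::cnn_loss_grad(task, f$out, y)$loss
    }
    eps <- 1e-5
    for (nm in names(model$params)) {
      idx <- sample(length(model$params[[nm]]), min(4, length(model$params[[nm]])))
      for (j in idx) {
        mp <- model; mp$params[[nm]][j] <- mp$params[[nm]][j] + eps
        mm <- model; mm$params[[nm]][j] <- mm$params[[nm]][j] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(grads[[nm]][j], num, tolerance = 1e-4,
                     label = paste("grad", nm, j, task))
      }
    }
  }
})

test_that("MAPE matches hand arithmetic and guards zero truths", {
  expect_equal(mape(100, 90), 10)
  expect_equal(mape(c(100, 5), c(90, 10)), 55)
  expect_equal(mape(c(50, 50), c(50, 50)), 0)
  expect_error(mape(c(100, 0), c(90, 10)), "replace zero")
})

test_that("training is reproducible and overfits trivially separable data", {
  set.seed(9)
  n <- 20
  x <- array(0, c(16, 16, 1, n))
  y <- rep(0:1, each = n / 2)
  for (i in seq_len(n)) {
    x[, , 1, i] <- (if (y[i] == 1) 0.8 else 0.2) +
      stats::rnorm(256, 0, 0.02)
  }
  tr <- list(x = x[, , , seq(1, n, 2), drop = FALSE], y = y[seq(1, n, 2)])
  va <- list(x = x[, , , seq(2, n, 2), drop = FALSE], y = y[seq(2, n, 2)])
  cfg <- small_cfg(n_targets = 2L, channels = 1L, epochs = 80L)
  m1 <- train_cnn(build_model(cfg), tr, va)
  expect_equal(evaluate_cnn(m1, tr$x, tr$y)$accuracy, 100)
  m2 <- train_cnn(build_model(cfg), tr, va)
  expect_identical(m1$trace, m2$trace)
  expect_false(identical(
    m1$trace,
    train_cnn(build_model(small_cfg(n_targets = 2L, channels = 1L,
                                    epochs = 80L, seed = 2L)), tr, va)$trace))
})

test_that("regression drives MAPE near zero on a trivially learnable target", {
  set.seed(10)
  n <- 16
  x <- array(stats::runif(16 * 16 * n, 0.4, 0.6), c(16, 16, 1, n))
  y <- rep(120, n)
  tr <- list(x = x[, , , 1:10, drop = FALSE], y = y[1:10])
  va <- list(x = x[, , , 11:16, drop = FALSE], y = y[11:16])
  m <- train_cnn(build_model(small_cfg("regression", 1L, channels = 1L,
                                       epochs = 60L)), tr, va)
  expect_lt(evaluate_cnn(m, va$x, va$y)$mape, 2)
})

test_that("training rejects unprepared labels and empty splits", {
  x <- array(0.5, c(16, 16, 1, 4))
  cfg <- small_cfg("regression", 1L, channels = 1L)
  expect_error(train_cnn(build_model(cfg), list(x = x, y = c(0, 1, 2, 3)),
                         list(x = x, y = 1:4)), "replace zero")
  expect_error(train_cnn(build_model(cfg), list(x = x, y = numeric(0)),
                         list(x = x, y = 1:4)), "empty")
  ccfg <- small_cfg(n_targets = 2L, channels = 1L)
  expect_error(train_cnn(build_model(ccfg), list(x = x, y = c(0, 1, 2, 0)),
                         list(x = x, y = c(0, 1, 0, 1))), "n_targets")
})

test_that("evaluation reports have the stated structure and boundary behaviour", {
  set.seed(4)
  m <- build_model(small_cfg(n_targets = 3L, channels = 1L))
  x <- array(stats::runif(16 * 16 * 6), c(16, 16, 1, 6))
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  rep_c <- evaluate_cnn(m, x, y)
  expect_true(rep_c$accuracy >= 0 && rep_c$accuracy <= 100)
  expect_equal(sum(rep_c$confusion), 6)
  r <- build_model(small_cfg("regression", 1L, channels = 1L))
  rep_r <- evaluate_cnn(r, x, c(50, 60, 70, 80, 90, 100))
  expect_gte(rep_r$mape, 0)
  cdf <- rep_r$cumulative_mape
  expect_true(all(diff(cdf$mape) >= 0))
  expect_true(all(diff(cdf$fraction) > 0))
  expect_equal(cdf$fraction[nrow(cdf)], 1)
})
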