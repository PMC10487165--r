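#' Configuration of the food-analysis CNN
#'
#' A compact architecture: two convolution/max-pooling stages followed by a
#' fully connected perceptron. Kernel sizes are 11 x 11 and 7 x 7, both
#' pooling windows 4 x 4, and the two hidden fully connected layers have
#' 112 and 128 nodes; the output is a soft-max over `n_targets` classes
#' (classification) or a single linear unit (regression, `n_targets = 1`).
#' With 64 x 64 inputs the spatial trace is 64 -> 54 -> 13 -> 7 -> 1; any
#' configuration that collapses a spatial dimension below 1 fails at build
#' time. Convolution filter counts, the optimizer (Adam, learning rate
#' 1e-3) and the He-style weight initialisation are tunable; training is
#' fully reproducible given `seed`.
#'
#' @param task `"classification"` or `"regression"`.
#' @param n_targets number of outputs (number of classes, or 1).
#' @param input_channels number of input channels C.
#' @param input_size spatial input size (default 64).
#' @param conv1_kernel,conv2_kernel convolution kernel sizes.
#' @param pool max-pooling window (stride = window).
#' @param conv1_filters,conv2_filters filters per convolution layer.
#' @param fc_sizes sizes of the two hidden fully connected layers.
#' @param epochs training epochs (default 1000; desk-scale runs use far
#'   fewer).
#' @param batch_size mini-batch size (default 32).
#' @param learning_rate Adam learning rate.
#' @param seed integer seed controlling initialisation and batching.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(task = c("classification", "regression"),
                       n_targets, input_channels, input_size = 64L,
                       conv1_kernel = 11L, conv2_kernel = 7L, pool = 4L,
                       conv1_filters = 16L, conv2_filters = 32L,
                       fc_sizes = c(112L, 128L), epochs = 1000L,
                       batch_size = 32L, learning_rate = 1e-3, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_targets >= 1, input_channels >= 1, length(fc_sizes) == 2,
            batch_size >= 1, epochs >= 1, learning_rate > 0)
  if (task == "regression" && n_targets != 1) {
    stop("regression uses a single output")
  }
  s1 <- input_size - conv1_kernel + 1L
  p1 <- s1 %/% pool
  s2 <- p1 - conv2_kernel + 1L
  p2 <- s2 %/% pool
  if (s1 < 1 || p1 < 1 || s2 < 1 || p2 < 1) {
    stop("configuration collapses the spatial dimensions (",
         input_size, " -> ", s1, " -> ", p1, " -> ", s2, " -> ", p2, ")")
  }
  structure(list(task = task, n_targets = as.integer(n_targets),
                 input_channels = as.integer(input_channels),
                 input_size = as.integer(input_size),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv2_kernel = as.integer(conv2_kernel),
                 pool = as.integer(pool),
                 conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 fc_sizes = as.integer(fc_sizes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 dims = list(s1 = s1, p1 = p1, s2 = s2, p2 = p2)),
            class = "cnn_config")
}

# im2col index matrix for an (h, w, C) input and k x k kernels: row p is
# output position (r fastest), column order is channel-major, then kernel
# column offset, then kernel row offset.
im2col_index <- function(h, w, channels, k) {
  out_h <- h - k + 1L
  out_w <- w - k + 1L
  r <- rep(seq_len(out_h), times = out_w)
  cc <- rep(seq_len(out_w), each = out_h)
  base <- (cc - 1L) * h + r
  offs <- integer(0)
  for (ch in seq_len(channels) - 1L) {
    for (dj in seq_len(k) - 1L) {
      for (di in seq_len(k) - 1L) {
        offs <- c(offs, ch * h * w + dj * h + di)
      }
    }
  }
  outer(base, offs, `+`)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained CNN
#'
#' Allocates He-initialised weights for the configured architecture;
#' initialisation is deterministic given the config seed. The parameter
#' count is a deterministic function of the configuration.
#'
#' @param config a [cnn_config()].
#' @return object of class `cnn_model`: list with `config`, `params` and
#'   the im2col index caches.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  d <- config$dims
  k1 <- config$conv1_kernel; k2 <- config$conv2_kernel
  f1 <- config$conv1_filters; f2 <- config$conv2_filters
  flat <- d$p2^2 * f2
  params <- with_seed(mix_seed(config$seed, 7), {
    list(W1 = he_init(k1^2 * config$input_channels, f1,
                      k1^2 * config$input_channels),
         b1 = numeric(f1),
         W2 = he_init(k2^2 * f1, f2, k2^2 * f1),
         b2 = numeric(f2),
         Wf1 = he_init(flat, config$fc_sizes[1], flat),
         bf1 = numeric(config$fc_sizes[1]),
         Wf2 = he_init(config$fc_sizes[1], config$fc_sizes[2],
                       config$fc_sizes[1]),
         bf2 = numeric(config$fc_sizes[2]),
         Wo = he_init(config$fc_sizes[2], config$n_targets,
                      config$fc_sizes[2]),
         bo = numeric(config$n_targets))
  })
  structure(list(config = config, params = params,
                 idx1 = im2col_index(config$input_size, config$input_size,
                                     config$input_channels, k1),
                 idx2 = im2col_index(d$p1, d$p1, f1, k2)),
            class = "cnn_model")
}

#' Number of trainable parameters of a model
#' @param model a `cnn_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

maxpool_fwd <- function(a, pool) {
  d <- dim(a)
  ho <- d[1] %/% pool; wo <- d[2] %/% pool
  best <- array(-Inf, c(ho, wo, d[3]))
  arg <- array(1L, c(ho, wo, d[3]))
  k <- 0L
  for (dj in 0:(pool - 1L)) {
    for (di in 0:(pool - 1L)) {
      k <- k + 1L
      sub <- a[seq(1L + di, by = pool, length.out = ho),
               seq(1L + dj, by = pool, length.out = wo), , drop = FALSE]
      upd <- sub > best
      best[upd] <- sub[upd]
      arg[upd] <- k
    }
  }
  list(out = best, arg = arg)
}

maxpool_bwd <- function(dout, arg, din_dim, pool) {
  din <- array(0, din_dim)
  ho <- dim(dout)[1]; wo <- dim(dout)[2]
  k <- 0L
  for (dj in 0:(pool - 1L)) {
    for (di in 0:(pool - 1L)) {
      k <- k + 1L
      sel <- arg == k
      if (any(sel)) {
        rows <- seq(1L + di, by = pool, length.out = ho)
        cols <- seq(1L + dj, by = pool, length.out = wo)
        tmp <- din[rows, cols, , drop = FALSE]
        tmp[sel] <- dout[sel]
        din[rows, cols, ] <- tmp
      }
    }
  }
  din
}

add_bias <- function(z, b) {
  z + matrix(b, nrow(z), length(b), byrow = TRUE)
}

# Forward pass for a batch. `patches` is a list of cached im2col matrices
# of the inputs (one per image). Returns the output matrix and, when
# `keep = TRUE`, the per-image caches needed for backprop.
cnn_forward <- function(model, patches, keep = FALSE) {
  p <- model$params
  cfg <- model$config
  d <- cfg$dims
  f1 <- cfg$conv1_filters; f2 <- cfg$conv2_filters
  n <- length(patches)
  flat <- matrix(0, n, d$p2^2 * f2)
  caches <- if (keep) vector("list", n)
  for (i in seq_len(n)) {
    z1 <- add_bias(patches[[i]] %*% p$W1, p$b1)
    a1 <- array(pmax(z1, 0), c(d$s1, d$s1, f1))
    mp1 <- maxpool_fwd(a1, cfg$pool)
    patch2 <- matrix(mp1$out[model$idx2], d$s2^2, cfg$conv2_kernel^2 * f1)
    z2 <- add_bias(patch2 %*% p$W2, p$b2)
    a2 <- array(pmax(z2, 0), c(d$s2, d$s2, f2))
    mp2 <- maxpool_fwd(a2, cfg$pool)
    flat[i, ] <- as.vector(mp2$out)
    if (keep) {
      caches[[i]] <- list(z1pos = z1 > 0, arg1 = mp1$arg, patch2 = patch2,
                          z2pos = z2 > 0, arg2 = mp2$arg)
    }
  }
  h1 <- pmax(add_bias(flat %*% p$Wf1, p$bf1), 0)
  h2 <- pmax(add_bias(h1 %*% p$Wf2, p$bf2), 0)
  out <- add_bias(h2 %*% p$Wo, p$bo)
  list(out = out, flat = flat, h1 = h1, h2 = h2, caches = caches)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Loss and output gradient. y: 0-based class indices, or calorie truths.
# For regression the network operates on a standardized target scale
# (`center`, `scale`): pred_kcal = center + scale * out, so Adam's O(lr)
# parameter steps translate into label-sized output moves.
cnn_loss_grad <- function(task, out, y, center = 0, scale = 1) {
  n <- nrow(out)
  if (task == "classification") {
    pr <- softmax(out)
    iy <- cbind(seq_len(n), y + 1L)
    loss <- -mean(log(pmax(pr[iy], 1e-12)))
    g <- pr
    g[iy] <- g[iy] - 1
    list(loss = loss, grad = g / n)
  } else {
    pred <- center + scale * out[, 1]
    loss <- 100 * mean(abs(pred - y) / y)
    list(loss = loss,
         grad = matrix(100 * scale * sign(pred - y) / (y * n), ncol = 1))
  }
}

# Backward pass; returns gradients for every parameter.
cnn_backward <- function(model, patches, fwd, dout) {
  p <- model$params
  cfg <- model$config
  d <- cfg$dims
  f1 <- cfg$conv1_filters; f2 <- cfg$conv2_filters
  k2 <- cfg$conv2_kernel
  g <- list()
  g$Wo <- crossprod(fwd$h2, dout)
  g$bo <- colSums(dout)
  dh2 <- (dout %*% t(p$Wo)) * (fwd$h2 > 0)
  g$Wf2 <- crossprod(fwd$h1, dh2)
  g$bf2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(p$Wf2)) * (fwd$h1 > 0)
  g$Wf1 <- crossprod(fwd$flat, dh1)
  g$bf1 <- colSums(dh1)
  dflat <- dh1 %*% t(p$Wf1)
  g$W1 <- matrix(0, nrow(p$W1), ncol(p$W1))
  g$b1 <- numeric(f1)
  g$W2 <- matrix(0, nrow(p$W2), ncol(p$W2))
  g$b2 <- numeric(f2)
  for (i in seq_along(patches)) {
    cc <- fwd$caches[[i]]
    da2 <- maxpool_bwd(array(dflat[i, ], c(d$p2, d$p2, f2)), cc$arg2,
                       c(d$s2, d$s2, f2), cfg$pool)
    dz2 <- matrix(da2, d$s2^2, f2) * cc$z2pos
    g$W2 <- g$W2 + crossprod(cc$patch2, dz2)
    g$b2 <- g$b2 + colSums(dz2)
    dpatch2 <- dz2 %*% t(p$W2)
    dp1 <- array(0, c(d$p1, d$p1, f1))
    for (dj in 0:(k2 - 1L)) {
      for (di in 0:(k2 - 1L)) {
        cols <- (seq_len(f1) - 1L) * k2^2 + dj * k2 + di + 1L
        blk <- array(dpatch2[, cols], c(d$s2, d$s2, f1))
        dp1[seq_len(d$s2) + di, seq_len(d$s2) + dj, ] <-
          dp1[seq_len(d$s2) + di, seq_len(d$s2) + dj, ] + blk
      }
    }
    da1 <- maxpool_bwd(dp1, cc$arg1, c(d$s1, d$s1, f1), cfg$pool)
    dz1 <- matrix(da1, d$s1^2, f1) * cc$z1pos
    g$W1 <- g$W1 + crossprod(patches[[i]], dz1)
    g$b1 <- g$b1 + colSums(dz1)
  }
  g
}

# im2col the images of a 4-d array (h, w, C, N) into a list of matrices.
input_patches <- function(model, x) {
  n <- dim(x)[4]
  lapply(seq_len(n), function(i) {
    xi <- x[, , , i, drop = FALSE]
    matrix(xi[model$idx1], nrow(model$idx1), ncol(model$idx1))
  })
}

#' Train a CNN
#'
#' Mini-batch Adam training with the task's loss (cross-entropy for
#' classification, mean absolute percentage error for regression; zero
#' calorie labels must have been replaced upstream). Fully reproducible:
#' the same seed, data and configuration give identical loss traces.
#'
#' @param model an untrained [build_model()] output.
#' @param train,val lists with `x` (`size` x `size` x C x N array) and `y`
#'   (0-based class indices, or positive calorie truths).
#' @param verbose print the loss every 10 epochs.
#' @return the trained `cnn_model`, with a `trace` element: data.frame
#'   (epoch, train_loss, val_loss).
#' @export
train_cnn <- function(model, train, val, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  if (!length(train$y) || !length(val$y)) stop("empty training or validation split")
  if (cfg$task == "regression" && (any(train$y <= 0) || any(val$y <= 0))) {
    stop("regression truths must be positive; replace zero calories first")
  }
  if (cfg$task == "classification" &&
      (any(train$y < 0) || any(train$y >= cfg$n_targets))) {
    stop("class indices must lie in [0, n_targets)")
  }
  tr_patches <- input_patches(model, train$x)
  val_patches <- input_patches(model, val$x)
  n <- length(tr_patches)
  adam <- list(m = lapply(model$params, function(w) w * 0),
               v = lapply(model$params, function(w) w * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  model$y_center <- 0
  model$y_scale <- 1
  if (cfg$task == "regression") {
    model$y_center <- mean(train$y)
    model$y_scale <- max(stats::sd(train$y), 1e-8)
  }
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  with_seed(mix_seed(cfg$seed, 13), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        fwd <- cnn_forward(model, tr_patches[idx], keep = TRUE)
        lg <- cnn_loss_grad(cfg$task, fwd$out, train$y[idx],
                            model$y_center, model$y_scale)
        ep_loss <- ep_loss + lg$loss * length(idx)
        grads <- cnn_backward(model, tr_patches[idx], fwd, lg$grad)
        adam$t <- adam$t + 1
        for (nm in names(model$params)) {
          adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * grads[[nm]]
          adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
          vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      vfwd <- cnn_forward(model, val_patches)
      vloss <- cnn_loss_grad(cfg$task, vfwd$out, val$y,
                             model$y_center, model$y_scale)$loss
      trace[epoch, ] <- list(epoch, ep_loss / n, vloss)
      if (verbose && epoch %% 10 == 0) {
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        ep_loss / n, vloss))
      }
    }
  })
  model$trace <- trace
  model
}

#' Predict with a trained CNN
#'
#' @param model a trained `cnn_model`.
#' @param x input array `size` x `size` x C x N.
#' @return N x `n_targets` matrix: class probabilities (classification) or
#'   calorie predictions (regression, one column).
#' @export
predict_cnn <- function(model, x) {
  fwd <- cnn_forward(model, input_patches(model, x))
  if (model$config$task == "classification") {
    softmax(fwd$out)
  } else {
    center <- if (is.null(model$y_center)) 0 else model$y_center
    scale <- if (is.null(model$y_scale)) 1 else model$y_scale
    center + scale * fwd$out
  }
}

#' Mean absolute percentage error
#'
#' `100 * mean(|truth - pred| / truth)`. Zero truths are an error: they
#' signal that the upstream zero-calorie replacement was skipped.
#'
#' @param truth,pred numeric vectors, `truth > 0` element-wise.
#' @return MAPE in percent.
#' @examples
#' mape(c(100, 5), c(90, 10))
#' @export
mape <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (any(truth <= 0)) {
    stop("MAPE undefined for non-positive truths; replace zero calories first")
  }
  100 * mean(abs(truth - pred) / truth)
}

#' Evaluate a trained CNN
#'
#' Classification: overall and per-class accuracy (percent) and a
#' confusion matrix. Regression: overall and per-item MAPE, the Pearson
#' correlation between truth and prediction, and the cumulative
#' distribution of per-image absolute percentage errors.
#'
#' @param model a trained `cnn_model`.
#' @param x input array.
#' @param y labels (0-based class indices, or positive calorie truths).
#' @param item_ids optional grouping for per-item tables (defaults to the
#'   class label / truth value).
#' @return object of class `eval_report` (a list).
#' @export
evaluate_cnn <- function(model, x, y, item_ids = NULL) {
  task <- model$config$task
  pred <- predict_cnn(model, x)
  if (task == "classification") {
    cls <- max.col(pred, ties.method = "first") - 1L
    acc <- 100 * mean(cls == y)
    per <- tapply(cls == y, y, function(z) 100 * mean(z))
    cm <- table(truth = factor(y, levels = 0:(model$config$n_targets - 1L)),
                predicted = factor(cls, levels = 0:(model$config$n_targets - 1L)))
    structure(list(task = task, accuracy = acc,
                   per_item = data.frame(class_index = as.integer(names(per)),
                                         accuracy = as.numeric(per)),
                   confusion = cm),
              class = "eval_report")
  } else {
    p <- pred[, 1]
    if (is.null(item_ids)) item_ids <- y
    ape <- 100 * abs(y - p) / y
    per <- tapply(ape, item_ids, mean)
    r <- if (stats::sd(p) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(y, p)
    cdf <- data.frame(mape = sort(ape),
                      fraction = seq_along(ape) / length(ape))
    structure(list(task = task, mape = mape(y, p), pearson_r = r,
                   per_item = data.frame(item = names(per),
                                         mape = as.numeric(per)),
                   cumulative_mape = cdf),
              class = "eval_report")
  }
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "classification") {
    cat(sprintf("classification: accuracy %.2f%% over %d classes\n",
                x$accuracy, nrow(x$confusion)))
  } else {
    cat(sprintf("regression: MAPE %.2f%%, Pearson r %.3f\n",
                x$mape, x$pearson_r))
  }
  invisible(x)
}
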