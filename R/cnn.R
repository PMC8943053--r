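#' Configuration of the worm/non-worm CNN
#'
#' A shallow VGG-style stack for 80x80 grayscale masked ROIs: eight 3x3
#' stride-1 convolutions each followed by ReLU, a 2x2 stride-2 max-pool
#' after every second convolution (so 80 -> 40 -> 20 -> 10 -> 5), batch
#' normalisation on the third and seventh convolution, dropout before a
#' single fully connected layer with 2 output classes. Trained with
#' cross-entropy and Adam.
#'
#' @param channels Integer vector of length 8: output channels of each
#'   convolution. The `"paper"` preset `(32,64,64,128,128,256,256,256)`
#'   lands near 1.78 million trainable parameters; the `"small"` preset
#'   `(8,8,16,16,32,32,32,32)` trains in minutes on a CPU and is ample for
#'   synthetic ROI sets.
#' @param preset `"paper"` or `"small"`; ignored when `channels` is given.
#' @param dropout Dropout rate before the fully connected stage.
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience on validation accuracy.
#' @param seed Seed for splitting, initialisation, shuffling and dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(channels = NULL, preset = c("paper", "small"),
                       dropout = 0.5, learning_rate = 1e-4,
                       epochs = 50, batch_size = 64, patience = 5,
                       seed = 0) {
  preset <- match.arg(preset)
  if (is.null(channels)) {
    channels <- switch(preset,
      paper = c(32L, 64L, 64L, 128L, 128L, 256L, 256L, 256L),
      small = c(8L, 8L, 16L, 16L, 32L, 32L, 32L, 32L)
    )
  }
  if (length(channels) != 8) {
    stop("`channels` must have length 8 (eight convolution layers)",
         call. = FALSE)
  }
  structure(
    list(channels = as.integer(channels), dropout = dropout,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         bn_layers = c(3L, 7L), pool_after = c(2L, 4L, 6L, 8L),
         input_size = 80L, n_classes = 2L, seed = seed),
    class = "cnn_config"
  )
}

#' Preprocess a masked ROI image
#'
#' Masked background pixels (exactly 0) are shifted to the 95th percentile
#' (linear-interpolation convention) of the grey values in the unmasked
#' area, removing the artificial mask edge; the image is then min-max
#' scaled to `[0, 1]`. A constant image after filling maps to all zeros.
#'
#' @param image Numeric or integer matrix with at least one nonzero pixel.
#' @return Numeric matrix in `[0, 1]`.
#' @export
preprocess_roi <- function(image) {
  x <- image
  storage.mode(x) <- "double"
  nz <- x[x != 0]
  if (length(nz) == 0) stop("all-zero ROI image", call. = FALSE)
  fill <- stats::quantile(nz, 0.95, type = 7, names = FALSE)
  x[x == 0] <- fill
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) {
    return(matrix(0, nrow(x), ncol(x)))
  }
  (x - rng[1]) / diff(rng)
}

#' Build (initialise) the CNN model
#'
#' He-initialised weights for the configured stack, with the trainable
#' parameter count (convolution and fully connected weights and biases,
#' plus batch-norm scale/shift).
#'
#' @param config A [cnn_config()].
#' @return A `cnn_model`: weights plus `n_params`.
#' @export
build_model <- function(config = cnn_config()) {
  set.seed(config$seed)
  ch_in <- c(1L, config$channels[-8])
  conv <- vector("list", 8)
  n_params <- 0
  for (l in 1:8) {
    fan_in <- 9 * ch_in[l]
    W <- matrix(stats::rnorm(config$channels[l] * fan_in, 0,
                             sqrt(2 / fan_in)),
                nrow = config$channels[l])
    conv[[l]] <- list(W = W, b = numeric(config$channels[l]))
    n_params <- n_params + length(W) + config$channels[l]
  }
  bn <- list()
  for (l in config$bn_layers) {
    C <- config$channels[l]
    bn[[as.character(l)]] <- list(
      gamma = rep(1, C), beta = numeric(C),
      r_mean = numeric(C), r_var = rep(1, C)
    )
    n_params <- n_params + 2L * C
  }
  n_feat <- 5L * 5L * config$channels[8]
  fc <- list(
    W = matrix(stats::rnorm(2 * n_feat, 0, sqrt(2 / n_feat)), nrow = 2),
    b = numeric(2)
  )
  n_params <- n_params + length(fc$W) + 2L
  structure(
    list(conv = conv, bn = bn, fc = fc, config = config,
         n_params = n_params),
    class = "cnn_model"
  )
}

#' @exportS3Method base::print
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> channels (%s), %s trainable parameters\n",
    paste(x$config$channels, collapse = ","),
    format(x$n_params, big.mark = ",")
  ))
  invisible(x)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_stats <- function(x, C) {
  d <- dim(x)
  A <- matrix(x, d[1] * d[2], C * d[4])
  cs <- matrix(.colSums(A, nrow(A), ncol(A)), C, d[4])
  cs2 <- matrix(.colSums(A * A, nrow(A), ncol(A)), C, d[4])
  n <- d[1] * d[2] * d[4]
  mu <- .rowSums(cs, C, d[4]) / n
  va <- .rowSums(cs2, C, d[4]) / n - mu^2
  list(mu = mu, va = pmax(va, 0), n = n)
}

bn_apply <- function(x, C, mu, va, gamma, beta) {
  d <- dim(x)
  ch <- rep(rep(seq_len(C), each = d[1] * d[2]), d[4])
  xh <- (x - mu[ch]) / sqrt(va[ch] + BN_EPS)
  y <- gamma[ch] * xh + beta[ch]
  dim(y) <- d
  dim(xh) <- d
  list(y = y, xh = xh)
}

# forward pass; returns logits and (optionally) the caches for backward
cnn_forward <- function(model, X, training = FALSE, cache = FALSE,
                        dropout_mask = NULL) {
  cfg <- model$config
  caches <- if (cache) list() else NULL
  x <- X
  for (l in 1:8) {
    d <- dim(x)
    x_in <- x
    x <- conv2d_forward(x, as.integer(d), model$conv[[l]]$W, model$conv[[l]]$b)
    bn_cache <- NULL
    if (l %in% cfg$bn_layers) {
      key <- as.character(l)
      C <- cfg$channels[l]
      if (training) {
        st <- bn_stats(x, C)
        ap <- bn_apply(x, C, st$mu, st$va, model$bn[[key]]$gamma,
                       model$bn[[key]]$beta)
        bn_cache <- list(mu = st$mu, va = st$va, xh = ap$xh, n = st$n)
      } else {
        ap <- bn_apply(x, C, model$bn[[key]]$r_mean, model$bn[[key]]$r_var,
                       model$bn[[key]]$gamma, model$bn[[key]]$beta)
      }
      x <- ap$y
    }
    relu_mask <- x > 0
    x <- x * relu_mask
    pool_idx <- NULL
    if (l %in% cfg$pool_after) {
      pooled <- maxpool_forward(x, as.integer(dim(x)))
      if (cache) {
        caches[[l]] <- list(x_in = x_in, dims_in = as.integer(d),
                            bn = bn_cache, relu = relu_mask,
                            pool_idx = pooled$idx,
                            pool_dims_in = as.integer(dim(x)))
      }
      x <- pooled$y
    } else if (cache) {
      caches[[l]] <- list(x_in = x_in, dims_in = as.integer(d),
                          bn = bn_cache, relu = relu_mask, pool_idx = NULL)
    }
  }
  B <- dim(x)[4]
  xf <- matrix(x, ncol = B) # n_feat x B
  if (training && !is.null(dropout_mask)) xf <- xf * dropout_mask
  logits <- model$fc$W %*% xf + model$fc$b
  list(logits = logits, xf = xf, caches = caches,
       feat_dim = dim(x))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# full backward pass; y is a 0/1 matrix (2 x B) of one-hot labels
cnn_backward <- function(model, fwd, y, dropout_mask = NULL) {
  cfg <- model$config
  B <- ncol(y)
  p <- softmax_cols(fwd$logits)
  dlogits <- (p - y) / B
  grads <- list(conv = vector("list", 8), bn = list(), fc = NULL)
  grads$fc <- list(W = dlogits %*% t(fwd$xf), b = rowSums(dlogits))
  dxf <- t(model$fc$W) %*% dlogits
  if (!is.null(dropout_mask)) dxf <- dxf * dropout_mask
  dx <- array(dxf, fwd$feat_dim)
  for (l in 8:1) {
    cc <- cnn_cache_get(fwd$caches, l)
    if (!is.null(cc$pool_idx)) {
      dx <- maxpool_backward(dx, cc$pool_idx, cc$pool_dims_in)
    }
    dx <- dx * cc$relu
    if (l %in% cfg$bn_layers) {
      key <- as.character(l)
      C <- cfg$channels[l]
      bnc <- cc$bn
      d <- dim(dx)
      ch <- rep(rep(seq_len(C), each = d[1] * d[2]), d[4])
      xh <- bnc$xh
      dgamma <- .colSums(
        matrix(dx * xh, d[1] * d[2], C * d[4]), d[1] * d[2], C * d[4]
      )
      dgamma <- .rowSums(matrix(dgamma, C, d[4]), C, d[4])
      dbeta <- .colSums(matrix(dx, d[1] * d[2], C * d[4]), d[1] * d[2], C * d[4])
      dbeta <- .rowSums(matrix(dbeta, C, d[4]), C, d[4])
      g <- model$bn[[key]]$gamma
      inv_sd <- 1 / sqrt(bnc$va + BN_EPS)
      mean_dy <- dbeta / bnc$n
      mean_dyxh <- dgamma / bnc$n
      dx <- (g[ch] * inv_sd[ch]) *
        (dx - mean_dy[ch] - xh * mean_dyxh[ch])
      dim(dx) <- d
      grads$bn[[key]] <- list(gamma = dgamma, beta = dbeta)
    }
    bw <- conv2d_backward(cc$x_in, dx, cc$dims_in, model$conv[[l]]$W)
    grads$conv[[l]] <- list(W = bw$dw, b = as.numeric(bw$db))
    dx <- bw$dx
  }
  grads
}

cnn_cache_get <- function(caches, l) caches[[l]]

# update BN running stats from a training forward pass
bn_update_running <- function(model, fwd) {
  for (l in model$config$bn_layers) {
    key <- as.character(l)
    bnc <- cnn_cache_get(fwd$caches, l)$bn
    model$bn[[key]]$r_mean <- (1 - BN_MOMENTUM) * model$bn[[key]]$r_mean +
      BN_MOMENTUM * bnc$mu
    model$bn[[key]]$r_var <- (1 - BN_MOMENTUM) * model$bn[[key]]$r_var +
      BN_MOMENTUM * bnc$va * bnc$n / max(1, bnc$n - 1)
  }
  model
}

# flatten trainable parameters to a named list for the Adam updates
cnn_params <- function(model) {
  p <- list()
  for (l in 1:8) {
    p[[paste0("conv", l, ".W")]] <- model$conv[[l]]$W
    p[[paste0("conv", l, ".b")]] <- model$conv[[l]]$b
  }
  for (key in names(model$bn)) {
    p[[paste0("bn", key, ".gamma")]] <- model$bn[[key]]$gamma
    p[[paste0("bn", key, ".beta")]] <- model$bn[[key]]$beta
  }
  p[["fc.W"]] <- model$fc$W
  p[["fc.b"]] <- model$fc$b
  p
}

cnn_set_params <- function(model, p) {
  for (l in 1:8) {
    model$conv[[l]]$W <- p[[paste0("conv", l, ".W")]]
    model$conv[[l]]$b <- p[[paste0("conv", l, ".b")]]
  }
  for (key in names(model$bn)) {
    model$bn[[key]]$gamma <- p[[paste0("bn", key, ".gamma")]]
    model$bn[[key]]$beta <- p[[paste0("bn", key, ".beta")]]
  }
  model$fc$W <- p[["fc.W"]]
  model$fc$b <- p[["fc.b"]]
  model
}

cnn_grads_flat <- function(grads) {
  g <- list()
  for (l in 1:8) {
    g[[paste0("conv", l, ".W")]] <- grads$conv[[l]]$W
    g[[paste0("conv", l, ".b")]] <- grads$conv[[l]]$b
  }
  for (key in names(grads$bn)) {
    g[[paste0("bn", key, ".gamma")]] <- grads$bn[[key]]$gamma
    g[[paste0("bn", key, ".beta")]] <- grads$bn[[key]]$beta
  }
  g[["fc.W"]] <- grads$fc$W
  g[["fc.b"]] <- grads$fc$b
  g
}

#' Stratified train/validation/test split
#'
#' 80/10/10 split of indices, stratified by class, seed-reproducible.
#'
#' @param labels Factor of class labels.
#' @param seed Integer seed.
#' @param fractions Split fractions summing to 1 (train, validation, test).
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_train_val_test <- function(labels, seed = 0,
                                 fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  out <- list(train = integer(), val = integer(), test = integer())
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$val <- c(out$val, idx[n_tr + seq_len(n_va)])
    out$test <- c(out$test, idx[(n_tr + n_va + 1):n])
  }
  out
}

images_to_batch <- function(images, idx) {
  n <- length(idx)
  X <- array(0, dim = c(80, 80, 1, n))
  for (k in seq_len(n)) {
    X[, , 1, k] <- preprocess_roi(images[, , idx[k]])
  }
  X
}

cnn_predict_logits <- function(model, X) {
  cnn_forward(model, X, training = FALSE, cache = FALSE)$logits
}

cnn_accuracy <- function(model, images, labels, idx, batch = 128) {
  pred <- character(length(idx))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / batch))) {
    X <- images_to_batch(images, idx[s])
    lg <- cnn_predict_logits(model, X)
    pred[s] <- levels(labels)[apply(lg, 2, which.max)]
  }
  mean(pred == as.character(labels[idx]))
}

#' Train the worm/non-worm classifier
#'
#' Splits the labelled ROI set 80/10/10 (stratified by class), trains with
#' cross-entropy and Adam at the configured learning rate, early-stops on
#' validation accuracy, restores the best-validation weights, and reports
#' accuracy and F1 on the untouched test split.
#'
#' @param dataset List with `images` (`80 x 80 x n` array) and `labels`
#'   (factor with two levels, first level = positive/worm class).
#' @param config A [cnn_config()].
#' @param verbose Print per-epoch progress.
#' @return A `trained_classifier`: the model, training `history` tibble,
#'   `test_accuracy`, `test_f1`, and the split indices.
#' @export
train_classifier <- function(dataset, config = cnn_config(preset = "small"),
                             verbose = FALSE) {
  images <- dataset$images
  labels <- dataset$labels
  if (nlevels(droplevels(labels)) < 2) {
    stop("training requires both classes in the dataset", call. = FALSE)
  }
  split <- split_train_val_test(labels, seed = config$seed)
  model <- build_model(config)
  p <- cnn_params(model)
  m <- lapply(p, function(z) z * 0)
  v <- lapply(p, function(z) z * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  pos <- levels(labels)[1]
  y_of <- function(idx) {
    y <- matrix(0, 2, length(idx))
    y[1, labels[idx] == pos] <- 1
    y[2, labels[idx] != pos] <- 1
    y
  }
  best_val <- -Inf; best_p <- p; best_bn <- model$bn; stall <- 0
  history <- list()
  set.seed(config$seed + 1)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(split$train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    loss_sum <- 0
    for (bidx in batches) {
      X <- images_to_batch(images, bidx)
      n_feat <- 25L * config$channels[8]
      dm <- NULL
      if (config$dropout > 0) {
        dm <- matrix(
          stats::rbinom(n_feat * length(bidx), 1, 1 - config$dropout) /
            (1 - config$dropout),
          n_feat, length(bidx)
        )
      }
      model <- cnn_set_params(model, p)
      fwd <- cnn_forward(model, X, training = TRUE, cache = TRUE,
                         dropout_mask = dm)
      model <- bn_update_running(model, fwd)
      y <- y_of(bidx)
      pr <- softmax_cols(fwd$logits)
      loss_sum <- loss_sum - sum(y * log(pmax(pr, 1e-12))) / length(bidx)
      g <- cnn_grads_flat(cnn_backward(model, fwd, y, dropout_mask = dm))
      step <- step + 1
      lr_t <- config$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(p)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        p[[nm]] <- p[[nm]] - lr_t * m[[nm]] / (sqrt(v[[nm]]) + eps)
      }
    }
    model <- cnn_set_params(model, p)
    val_acc <- cnn_accuracy(model, images, labels, split$val)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = loss_sum / length(batches),
      val_accuracy = val_acc
    )
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, val acc %.3f",
                      epoch, loss_sum / length(batches), val_acc))
    }
    if (val_acc > best_val) {
      best_val <- val_acc; best_p <- p; best_bn <- model$bn; stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= config$patience) break
    }
  }
  model <- cnn_set_params(model, best_p)
  model$bn <- best_bn
  # test metrics on the held-out 10%
  probs <- predict_worm_prob(
    structure(list(model = model), class = "trained_classifier"),
    images[, , split$test, drop = FALSE]
  )
  truth_pos <- labels[split$test] == pos
  pred_pos <- probs > 0.5
  tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(
    list(
      model = model,
      history = dplyr::bind_rows(history),
      best_val_accuracy = best_val,
      test_accuracy = mean(pred_pos == truth_pos),
      test_f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
      split = split,
      positive_class = pos
    ),
    class = "trained_classifier"
  )
}

#' @exportS3Method base::print
print.trained_classifier <- function(x, ...) {
  cat(sprintf(
    "<trained_classifier> %d epochs, val acc %.3f, test acc %.3f, test F1 %.3f\n",
    nrow(x$history), x$best_val_accuracy, x$test_accuracy, x$test_f1
  ))
  invisible(x)
}

#' @export
glance.trained_classifier <- function(x, ...) {
  tibble::tibble(
    n_params = x$model$n_params,
    epochs_run = nrow(x$history),
    best_val_accuracy = x$best_val_accuracy,
    test_accuracy = x$test_accuracy,
    test_f1 = x$test_f1
  )
}

#' @export
tidy.trained_classifier <- function(x, ...) x$history

#' Worm probability for ROI images
#'
#' @param classifier A `trained_classifier`.
#' @param images `80 x 80 x n` array (or a single 80x80 matrix) of masked
#'   ROI images (raw grey values; preprocessing is applied internally).
#' @return Numeric vector of worm probabilities.
#' @export
predict_worm_prob <- function(classifier, images) {
  model <- classifier$model
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1)
  n <- dim(images)[3]
  out <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / 128))) {
    X <- images_to_batch(images, s)
    lg <- cnn_predict_logits(model, X)
    pr <- softmax_cols(lg)
    out[s] <- pr[1, ]
  }
  out
}
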