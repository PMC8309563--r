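# Per-channel 1D convolutional network (third pipeline).
#
# Architecture, per channel: conv (3 filters, width 20, stride 1, no
# padding) -> ReLU -> max-pool (size 3, non-overlapping) -> flatten. The
# channel outputs are concatenated and fed to two fully connected ReLU
# layers (1024 and 30 units) and an l-unit softmax output. Training
# minimizes class-weighted categorical cross-entropy with stochastic
# gradient descent plus momentum; all computations are plain matrix
# algebra, single-threaded apart from BLAS, so seeded runs are
# reproducible.

#' Configuration of the convolutional pipeline
#'
#' @param n_filters filters per channel (default 3).
#' @param kernel_size filter width in samples (default 20).
#' @param pool_size max-pooling size (default 3).
#' @param fc_sizes sizes of the two fully connected layers (default
#'   `c(1024, 30)`).
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(n_filters = 3, kernel_size = 20, pool_size = 3,
                       fc_sizes = c(1024, 30), epochs = 30,
                       batch_size = 128, learning_rate = 0.01,
                       momentum = 0.9, seed = 1) {
  if (pool_size < 1) stop("pool_size must be >= 1")
  if (length(fc_sizes) != 2) stop("fc_sizes must have length 2")
  structure(list(n_filters = n_filters, kernel_size = kernel_size,
                 pool_size = pool_size, fc_sizes = fc_sizes,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer-shape arithmetic of the convolutional pipeline
#'
#' Closed forms for the intermediate widths: convolution output length
#' `T - kernel_size + 1`, pooled length `floor(conv_len / pool_size)`,
#' per-channel flattened width `pool_len * n_filters`, and concatenated
#' width `m` times that.
#'
#' @param cfg a `cnn_config`.
#' @param T_len window length in samples.
#' @param m number of channels.
#' @return list with `conv_len`, `pool_len`, `flat_per_channel`, `concat`.
#' @export
#' @examples
#' cnn_shapes(cnn_config(), T_len = 64, m = 4) # 45, 15, 45, 180
cnn_shapes <- function(cfg, T_len, m) {
  if (cfg$kernel_size > T_len) stop("kernel wider than the window")
  conv_len <- T_len - cfg$kernel_size + 1
  pool_len <- floor(conv_len / cfg$pool_size)
  if (pool_len < 1) stop("pooling leaves no output")
  flat <- pool_len * cfg$n_filters
  list(conv_len = conv_len, pool_len = pool_len, flat_per_channel = flat,
       concat = m * flat)
}

init_mat <- function(nr, nc) {
  # uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
  lim <- 1 / sqrt(nr)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained convolutional model
#'
#' Initializes per-channel convolution filters and the fully connected
#' stack with a uniform fan-in scheme drawn from `cfg$seed`.
#'
#' @param cfg a `cnn_config`.
#' @param T_len window length in samples.
#' @param m number of channels.
#' @param classes character vector of class labels (output width `l`).
#' @return object of class `cnn_model`.
#' @export
build_cnn <- function(cfg, T_len, m, classes) {
  stopifnot(inherits(cfg, "cnn_config"))
  classes <- sort(unique(as.character(classes)))
  l <- length(classes)
  shp <- cnn_shapes(cfg, T_len, m)
  with_seed(derive_seed(cfg$seed, 1L), {
    par <- list()
    for (ch in seq_len(m)) {
      par[[paste0("Wc", ch)]] <- init_mat(cfg$kernel_size, cfg$n_filters)
      par[[paste0("bc", ch)]] <- numeric(cfg$n_filters)
    }
    par$W1 <- init_mat(shp$concat, cfg$fc_sizes[1])
    par$b1 <- numeric(cfg$fc_sizes[1])
    par$W2 <- init_mat(cfg$fc_sizes[1], cfg$fc_sizes[2])
    par$b2 <- numeric(cfg$fc_sizes[2])
    par$W3 <- init_mat(cfg$fc_sizes[2], l)
    par$b3 <- numeric(l)
    structure(list(cfg = cfg, T_len = T_len, m = m, classes = classes,
                   shapes = shp, par = par, trained_epochs = 0L,
                   final_loss = NA_real_, channel_center = NULL,
                   channel_scale = NULL),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(paste0("<cnn_model> %d channels x T=%d -> conv %d -> pool %d",
                     " -> concat %d -> FC %d -> FC %d -> %d classes\n"),
              x$m, x$T_len, x$shapes$conv_len, x$shapes$pool_len,
              x$shapes$concat, x$cfg$fc_sizes[1], x$cfg$fc_sizes[2],
              length(x$classes)))
  cat(sprintf("  trained %d epochs; final loss %.4f\n", x$trained_epochs,
              x$final_loss))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# im2col for one channel matrix x (k x T): returns (k*conv_len) x ks.
im2col <- function(x, ks, conv_len) {
  k <- nrow(x)
  colidx <- as.vector(vapply(seq_len(conv_len),
                             function(j) j:(j + ks - 1),
                             integer(ks)))
  a <- array(x[, colidx], dim = c(k, ks, conv_len))
  matrix(aperm(a, c(1, 3, 2)), k * conv_len, ks)
}

# Forward pass; returns activations needed for backprop when cache = TRUE.
cnn_forward <- function(model, xs, cache = FALSE) {
  cfg <- model$cfg
  shp <- model$shapes
  k <- nrow(xs[[1]])
  pool <- cfg$pool_size
  used <- shp$pool_len * pool
  cols <- vector("list", model$m)
  convs <- vector("list", model$m)
  pools <- vector("list", model$m)
  flat <- vector("list", model$m)
  for (ch in seq_len(model$m)) {
    a <- im2col(xs[[ch]], cfg$kernel_size, shp$conv_len)
    z <- relu(sweep(a %*% model$par[[paste0("Wc", ch)]], 2,
                    model$par[[paste0("bc", ch)]], `+`))
    zarr <- array(z, dim = c(k, shp$conv_len, cfg$n_filters))
    zuse <- array(zarr[, seq_len(used), , drop = FALSE],
                  dim = c(k, pool, shp$pool_len, cfg$n_filters))
    p <- zuse[, 1, , , drop = FALSE]
    if (pool > 1) {
      for (j in 2:pool) p <- pmax(p, zuse[, j, , , drop = FALSE])
    }
    p <- array(p, dim = c(k, shp$pool_len, cfg$n_filters))
    if (cache) {
      cols[[ch]] <- a
      convs[[ch]] <- zarr
      pools[[ch]] <- p
    }
    flat[[ch]] <- matrix(p, k, shp$flat_per_channel)
  }
  f <- do.call(cbind, flat)
  h1 <- relu(sweep(f %*% model$par$W1, 2, model$par$b1, `+`))
  h2 <- relu(sweep(h1 %*% model$par$W2, 2, model$par$b2, `+`))
  o <- sweep(h2 %*% model$par$W3, 2, model$par$b3, `+`)
  p_out <- softmax_rows(o)
  if (!cache) return(list(prob = p_out))
  list(prob = p_out, f = f, h1 = h1, h2 = h2, cols = cols, convs = convs,
       pools = pools)
}

cnn_gradients <- function(model, fw, xs, y_idx, sample_w) {
  cfg <- model$cfg
  shp <- model$shapes
  k <- nrow(fw$prob)
  pool <- cfg$pool_size
  used <- shp$pool_len * pool
  d_o <- fw$prob
  d_o[cbind(seq_len(k), y_idx)] <- d_o[cbind(seq_len(k), y_idx)] - 1
  d_o <- d_o * (sample_w / sum(sample_w))
  g <- list()
  g$W3 <- crossprod(fw$h2, d_o)
  g$b3 <- colSums(d_o)
  dh2 <- (d_o %*% t(model$par$W3)) * (fw$h2 > 0)
  g$W2 <- crossprod(fw$h1, dh2)
  g$b2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(model$par$W2)) * (fw$h1 > 0)
  g$W1 <- crossprod(fw$f, dh1)
  g$b1 <- colSums(dh1)
  d_f <- dh1 %*% t(model$par$W1)
  for (ch in seq_len(model$m)) {
    cols_range <- ((ch - 1) * shp$flat_per_channel + 1):
      (ch * shp$flat_per_channel)
    d_pool <- array(d_f[, cols_range, drop = FALSE],
                    dim = c(k, shp$pool_len, cfg$n_filters))
    zarr <- fw$convs[[ch]]
    zuse <- array(zarr[, seq_len(used), , drop = FALSE],
                  dim = c(k, pool, shp$pool_len, cfg$n_filters))
    p <- fw$pools[[ch]]
    d_conv <- array(0, dim = c(k, pool, shp$pool_len, cfg$n_filters))
    assigned <- array(FALSE, dim = c(k, shp$pool_len, cfg$n_filters))
    for (j in seq_len(pool)) {
      zj <- array(zuse[, j, , , drop = FALSE],
                  dim = c(k, shp$pool_len, cfg$n_filters))
      sel <- !assigned & (zj == p)
      d_conv[, j, , ][sel] <- d_pool[sel]
      assigned <- assigned | sel
    }
    d_z <- array(0, dim = c(k, shp$conv_len, cfg$n_filters))
    d_z[, seq_len(used), ] <- array(d_conv,
                                    dim = c(k, used, cfg$n_filters))
    d_z <- d_z * (zarr > 0)
    d_z_mat <- matrix(d_z, k * shp$conv_len, cfg$n_filters)
    g[[paste0("Wc", ch)]] <- crossprod(fw$cols[[ch]], d_z_mat)
    g[[paste0("bc", ch)]] <- colSums(d_z_mat)
  }
  g
}

tensor_channels <- function(model, seg) {
  k <- dim(seg$values)[1]
  T_len <- dim(seg$values)[2]
  lapply(seq_len(dim(seg$values)[3]), function(ch) {
    x <- matrix(seg$values[, , ch], k, T_len)
    if (!is.null(model$channel_center)) {
      x <- (x - model$channel_center[ch]) / model$channel_scale[ch]
    }
    x
  })
}

#' Train the convolutional model
#'
#' Standardizes each input channel by its global training mean and
#' standard deviation (stored in the model and re-applied at prediction
#' time; the ~1 g gravity offset would otherwise dominate the early
#' optimization), then minimizes class-weighted categorical cross-entropy
#' by minibatch stochastic gradient descent with momentum. Batch order is
#' reshuffled
#' each epoch from the configuration seed, so a given
#' (configuration, data) pair always reproduces the identical trained
#' model and final loss. `epochs = 0` returns the model unchanged.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param seg a labeled `segment_tensor`; labels must be a subset of the
#'   model's classes and cover >= 2 classes.
#' @param class_weights named per-class loss weights (e.g. from
#'   [class_weights()]); `NULL` for unweighted training.
#' @param epochs override of `cfg$epochs`.
#' @return the trained `cnn_model` (fields `trained_epochs`, `final_loss`
#'   updated).
#' @export
train_cnn <- function(model, seg, class_weights = NULL, epochs = NULL) {
  stopifnot(inherits(model, "cnn_model"), inherits(seg, "segment_tensor"))
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$epochs
  if (epochs == 0) return(model)
  y <- seg$labels
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (!all(y %in% model$classes)) stop("label outside the model's classes")
  y_idx <- match(y, model$classes)
  n <- length(y)
  w <- if (is.null(class_weights)) rep(1, n) else
    unname(class_weights[y])
  if (is.null(model$channel_center)) {
    model$channel_center <- apply(seg$values, 3, mean)
    scl <- apply(seg$values, 3, stats::sd)
    scl[scl == 0] <- 1
    model$channel_scale <- scl
  }
  xs <- tensor_channels(model, seg)
  vel <- lapply(model$par, function(p) p * 0)
  loss <- NA_real_
  with_seed(derive_seed(cfg$seed, 2L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      ep_w <- 0
      for (b in batches) {
        xb <- lapply(xs, function(x) x[b, , drop = FALSE])
        fw <- cnn_forward(model, xb, cache = TRUE)
        pb <- fw$prob[cbind(seq_along(b), y_idx[b])]
        ep_loss <- ep_loss + sum(-w[b] * log(pmax(pb, 1e-12)))
        ep_w <- ep_w + sum(w[b])
        g <- cnn_gradients(model, fw, xb, y_idx[b], w[b])
        for (nm in names(g)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g[[nm]]
          model$par[[nm]] <- model$par[[nm]] + vel[[nm]]
        }
      }
      loss <- ep_loss / ep_w
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d; lower the learning rate",
                     ep))
      }
    }
  })
  model$trained_epochs <- model$trained_epochs + as.integer(epochs)
  model$final_loss <- loss
  model
}

#' Predict with the convolutional model
#'
#' @param model a `cnn_model`.
#' @param seg a `segment_tensor` with matching window length and channel
#'   count.
#' @param type `"class"` for labels (argmax of the softmax output) or
#'   `"prob"` for the K x l probability matrix.
#' @return character vector of labels, or a probability matrix whose rows
#'   sum to 1.
#' @export
predict_cnn <- function(model, seg, type = c("class", "prob")) {
  stopifnot(inherits(model, "cnn_model"), inherits(seg, "segment_tensor"))
  type <- match.arg(type)
  if (dim(seg$values)[2] != model$T_len ||
      dim(seg$values)[3] != model$m) {
    stop("window length or channel count mismatch with the trained model")
  }
  k <- dim(seg$values)[1]
  if (k == 0) {
    return(if (type == "class") character(0) else
      matrix(numeric(0), 0, length(model$classes)))
  }
  prob <- cnn_forward(model, tensor_channels(model, seg))$prob
  colnames(prob) <- model$classes
  if (type == "prob") return(prob)
  model$classes[apply(prob, 1, which.max)]
}
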