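# Per-channel linear discriminant projection (second pipeline, stage 1).

# Ledoit-Wolf shrinkage intensity toward a scaled identity target, from the
# pooled within-class centered observations (rows of z).
ledoit_wolf_intensity <- function(z) {
  n <- nrow(z)
  p <- ncol(z)
  s <- crossprod(z) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2) / p
  if (d2 <= 0) return(0)
  sq_norms <- rowSums(z^2)
  # (1/n^2) sum_i ||z_i z_i' - S||_F^2 / p
  b2 <- (sum(sq_norms^2) - n * sum(s^2)) / (n^2 * p)
  max(0, min(1, b2 / d2))
}

#' Fit per-channel linear discriminant projections
#'
#' Treats each channel's raw T-sample window as a T-dimensional input
#' vector and fits, per channel, a linear discriminant analysis (LDA)
#' projection onto at most `l - 1` directions that maximize between-class
#' relative to within-class scatter. The within-class scatter is shrunk
#' toward a scaled identity (Ledoit-Wolf intensity by default) so the
#' problem stays well conditioned even when T exceeds the per-class window
#' counts.
#'
#' @param seg a `segment_tensor` with labels covering >= 2 classes.
#' @param n_components number of discriminant directions per channel; at
#'   most `n_classes - 1`.
#' @param shrinkage `"auto"` for the Ledoit-Wolf intensity, or a number in
#'   `[0, 1]`.
#' @return object of class `channel_projection`: per-channel lists with
#'   `center` and `scaling` (T x n_components), plus metadata.
#' @export
lda_fit <- function(seg, n_components = NULL, shrinkage = "auto") {
  stopifnot(inherits(seg, "segment_tensor"))
  y <- seg$labels
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("LDA needs at least 2 classes")
  max_comp <- length(classes) - 1
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    stop(sprintf("n_components must be <= %d (number of classes - 1)",
                 max_comp))
  }
  T_len <- dim(seg$values)[2]
  m <- dim(seg$values)[3]
  k <- dim(seg$values)[1]
  y_idx <- split(seq_len(k), y)
  channels <- vector("list", m)
  for (ch in seq_len(m)) {
    x <- matrix(seg$values[, , ch], k, T_len)
    mu <- colMeans(x)
    # pooled within-class centering
    z <- x
    sb <- matrix(0, T_len, T_len)
    for (cl in classes) {
      idx <- y_idx[[cl]]
      mc <- colMeans(x[idx, , drop = FALSE])
      z[idx, ] <- sweep(x[idx, , drop = FALSE], 2, mc)
      dm <- mc - mu
      sb <- sb + length(idx) * tcrossprod(dm)
    }
    sb <- sb / k
    sw <- crossprod(z) / k
    a <- if (identical(shrinkage, "auto")) ledoit_wolf_intensity(z) else
      as.numeric(shrinkage)
    target <- diag(mean(diag(sw)), T_len)
    sw_reg <- (1 - a) * sw + a * target
    # whitened symmetric eigenproblem: M = L^-1 Sb L^-T with Sw = L L'
    cc <- chol(sw_reg) # upper triangular, Sw = t(cc) %*% cc
    tmp <- forwardsolve(t(cc), sb)
    m_sym <- t(forwardsolve(t(cc), t(tmp)))
    m_sym <- (m_sym + t(m_sym)) / 2
    e <- eigen(m_sym, symmetric = TRUE)
    scaling <- backsolve(cc, e$vectors[, seq_len(n_components), drop = FALSE])
    # deterministic sign: largest-magnitude loading positive
    for (j in seq_len(ncol(scaling))) {
      i_max <- which.max(abs(scaling[, j]))
      if (scaling[i_max, j] < 0) scaling[, j] <- -scaling[, j]
    }
    channels[[ch]] <- list(center = mu, scaling = scaling, shrinkage = a)
  }
  names(channels) <- dimnames(seg$values)[[3]]
  structure(list(channels = channels, n_components = n_components,
                 classes = classes, T_len = T_len),
            class = "channel_projection")
}

#' Project windows through fitted channel discriminants
#'
#' Applies the per-channel LDA maps and concatenates the projected
#' coordinates in fixed channel order (Ax, Ay, Az, An), yielding a
#' K x (m * n_components) feature matrix.
#'
#' @param proj a `channel_projection` from [lda_fit()].
#' @param seg a `segment_tensor` with matching window length and channels.
#' @return a `feature_matrix`.
#' @export
lda_transform <- function(proj, seg) {
  stopifnot(inherits(proj, "channel_projection"),
            inherits(seg, "segment_tensor"))
  m <- dim(seg$values)[3]
  if (m != length(proj$channels)) stop("channel count mismatch")
  if (dim(seg$values)[2] != proj$T_len) stop("window length mismatch")
  k <- dim(seg$values)[1]
  blocks <- lapply(seq_len(m), function(ch) {
    x <- matrix(seg$values[, , ch], k, proj$T_len)
    sweep(x, 2, proj$channels[[ch]]$center) %*% proj$channels[[ch]]$scaling
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- as.vector(vapply(names(proj$channels), function(nm) {
    paste0(nm, "_ld", seq_len(proj$n_components))
  }, character(proj$n_components)))
  feature_matrix(out, seg$labels)
}
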