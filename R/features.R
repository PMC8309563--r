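# Handcrafted time/frequency feature extraction (first pipeline, stage 1).

feature_metric_names <- c("mean", "var", "sd", "max", "min", "rms",
                          "kurtosis", "skewness", "l2norm", "l1norm",
                          "fft_energy", "fft_maxmag", "fft_domfreq")

#' Names of the 55 handcrafted features
#'
#' Thirteen metrics per channel (Ax, Ay, Az, An) — ten time-domain metrics
#' (mean, variance, standard deviation, maximum, minimum, RMS, kurtosis,
#' skewness, Euclidean norm, l1-norm) and three spectral metrics (FFT
#' energy, maximum non-DC FFT magnitude, dominant non-DC frequency bin) —
#' plus the lag-0 Pearson cross-correlations of the three raw-axis pairs:
#' 13 x 4 + 3 = 55.
#'
#' @return character vector of length 55.
#' @export
feature_names <- function() {
  chans <- c("Ax", "Ay", "Az", "An")
  c(as.vector(t(outer(chans, feature_metric_names, paste, sep = "_"))),
    "corr_Ax_Ay", "corr_Ax_Az", "corr_Ay_Az")
}

# Per-window, per-channel metrics for a K x T matrix, vectorized over
# windows. Moments use population (1/T) denominators; kurtosis is the
# non-excess fourth standardized moment; zero-variance windows get
# kurtosis = skewness = 0.
channel_features <- function(x) {
  T_len <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  m2 <- rowMeans(xc^2)
  m3 <- rowMeans(xc^3)
  m4 <- rowMeans(xc^4)
  pos <- m2 > 0
  kurt <- ifelse(pos, m4 / ifelse(pos, m2^2, 1), 0)
  skew <- ifelse(pos, m3 / ifelse(pos, m2^1.5, 1), 0)
  sumsq <- rowSums(x^2)
  # magnitude spectrum of the un-windowed segment; DC excluded from the
  # maximum and dominant bin so the gravity offset does not dominate
  sp <- Mod(stats::mvfft(t(x)))       # T x K
  energy <- colSums(sp^2) / T_len     # Parseval: equals rowSums(x^2)
  half <- 2:(floor(T_len / 2) + 1)    # non-DC bins up to Nyquist
  sp_half <- sp[half, , drop = FALSE]
  maxmag <- apply(sp_half, 2, max)
  domfreq <- apply(sp_half, 2, which.max) # bin index, 1 = fundamental
  cbind(mean = mu, var = m2, sd = sqrt(m2),
        max = apply(x, 1, max), min = apply(x, 1, min),
        rms = sqrt(rowMeans(x^2)), kurtosis = kurt, skewness = skew,
        l2norm = sqrt(sumsq), l1norm = rowSums(abs(x)),
        fft_energy = energy, fft_maxmag = maxmag, fft_domfreq = domfreq)
}

# Lag-0 Pearson cross-correlation per window between two K x T matrices,
# population denominators; 0 when either channel is constant.
pairwise_corr <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowMeans(ac * bc)
  den <- sqrt(rowMeans(ac^2) * rowMeans(bc^2))
  ifelse(den > 0, num / den, 0)
}

#' Extract the 55 handcrafted features per window
#'
#' Computes, for every window of a segment tensor, the feature vector
#' described in [feature_names()]. Extraction is deterministic and the
#' feature order is fixed.
#'
#' @param seg a `segment_tensor` with K >= 1 windows.
#' @return object of class `feature_matrix`: list with `values` (K x 55
#'   numeric matrix with column names), `feature_names` and `labels`.
#' @export
extract_features <- function(seg) {
  stopifnot(inherits(seg, "segment_tensor"))
  k <- dim(seg$values)[1]
  if (k == 0) stop("cannot extract features from an empty tensor")
  if (!all(is.finite(seg$values))) {
    stop("windows contain non-finite samples")
  }
  ax <- seg$values[, , 1, drop = TRUE]
  ay <- seg$values[, , 2, drop = TRUE]
  az <- seg$values[, , 3, drop = TRUE]
  an <- seg$values[, , 4, drop = TRUE]
  if (k == 1) {
    ax <- matrix(ax, 1); ay <- matrix(ay, 1)
    az <- matrix(az, 1); an <- matrix(an, 1)
  }
  values <- cbind(channel_features(ax), channel_features(ay),
                  channel_features(az), channel_features(an),
                  pairwise_corr(ax, ay), pairwise_corr(ax, az),
                  pairwise_corr(ay, az))
  colnames(values) <- feature_names()
  feature_matrix(values, seg$labels)
}

#' Construct a feature matrix
#'
#' @param values K x F numeric matrix (column names become feature names).
#' @param labels K activity labels (optional for unlabeled data).
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (!is.null(labels) && length(labels) != nrow(values)) {
    stop("labels must match the number of rows")
  }
  structure(
    list(values = values, feature_names = colnames(values), labels = labels),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Fit z-score normalization parameters
#'
#' Per-feature centering and scaling parameters estimated on the training
#' matrix only (population standard deviation). Zero-variance features get
#' scale 1 so they map to exactly 0.
#'
#' @param train a `feature_matrix`.
#' @return object of class `zscore_params` with `center` and `scale`.
#' @export
zscore_fit <- function(train) {
  stopifnot(inherits(train, "feature_matrix"))
  x <- train$values
  if (nrow(x) == 0) stop("empty training matrix")
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  scale[scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "zscore_params")
}

#' Apply z-score normalization
#'
#' @param params a `zscore_params` from [zscore_fit()].
#' @param fm a `feature_matrix` with matching columns.
#' @return the normalized `feature_matrix`.
#' @export
zscore_apply <- function(params, fm) {
  stopifnot(inherits(params, "zscore_params"), inherits(fm, "feature_matrix"))
  if (ncol(fm$values) != length(params$center)) {
    stop("feature count mismatch")
  }
  out <- sweep(sweep(fm$values, 2, params$center), 2, params$scale, `/`)
  feature_matrix(out, fm$labels)
}
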