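test_that("extraction yields the 55 named features", {
  seg <- make_sine_tensor(k = 6)
  fm <- extract_features(seg)
  expect_equal(ncol(fm$values), 55)
  expect_identical(colnames(fm$values), feature_names())
  expect_equal(anyDuplicated(feature_names()), 0)
  expect_true(all(is.finite(fm$values)))
  # deterministic extraction
  expect_identical(fm$values, extract_features(seg)$values)
})

test_that("constant windows follow the zero-variance conventions", {
  vals <- array(0.7, c(2, 64, 4),
                dimnames = list(NULL, NULL, c("Ax", "Ay", "Az", "An")))
  seg <- structure(list(values = vals, labels = c("a", "b"),
                        subject_ids = c(1L, 1L), trial_ids = c(1L, 1L)),
                   class = "segment_tensor")
  fm <- extract_features(seg)
  v <- fm$values[1, ]
  expect_equal(unname(v["Ax_mean"]), 0.7)
  expect_equal(unname(v["Ax_max"]), 0.7)
  expect_equal(unname(v["Ax_min"]), 0.7)
  expect_equal(unname(v["Ax_rms"]), 0.7)
  expect_equal(unname(v["Ax_var"]), 0)
  expect_equal(unname(v["Ax_sd"]), 0)
  expect_equal(unname(v["Ax_kurtosis"]), 0)
  expect_equal(unname(v["Ax_skewness"]), 0)
  expect_equal(unname(v["corr_Ax_Ay"]), 0)
  expect_error(extract_features(structure(list(
    values = array(NaN, c(1, 4, 4)), labels = "a",
    subject_ids = 1L, trial_ids = 1L), class = "segment_tensor")),
    "non-finite")
})

test_that("sinusoid RMS and Parseval hold on every window", {
  # direct-summation oracle: full-cycle sinusoid of amplitude A
  T_len <- 64
  amp <- 1.3
  t <- (seq_len(T_len) - 1) / T_len
  x <- amp * sin(2 * pi * 4 * t)
  vals <- array(rep(x, 4), c(1, T_len, 4),
                dimnames = list(NULL, NULL, c("Ax", "Ay", "Az", "An")))
  seg <- structure(list(values = vals, labels = "a", subject_ids = 1L,
                        trial_ids = 1L), class = "segment_tensor")
  fm <- extract_features(seg)
  expect_equal(unname(fm$values[1, "Ax_rms"]), amp / sqrt(2),
               tolerance = 1e-12)
  # Parseval on arbitrary windows: FFT energy equals the sum of squares
  seg2 <- make_sine_tensor(k = 20, noise = 0.3, seed = 8)
  fm2 <- extract_features(seg2)
  for (ch in c("Ax", "Ay", "Az", "An")) {
    ssq <- rowSums(seg2$values[, , ch]^2)
    expect_equal(unname(fm2$values[, paste0(ch, "_fft_energy")]), ssq,
                 tolerance = 1e-6)
  }
})

test_that("z-score normalization uses train-only population moments", {
  fm <- feature_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                       labels = c("x", "y", "x"))
  zp <- zscore_fit(fm)
  z <- zscore_apply(zp, fm)
  expect_equal(unname(z$values[, "a"]),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(unname(z$values[, "b"]), c(0, 0, 0))
  # refit on transformed data is a no-op transform
  expect_equal(zscore_apply(zscore_fit(z), z)$values, z$values,
               tolerance = 1e-12)
  # train-only parameters applied to fresh data keep train statistics
  seg <- make_sine_tensor(k = 30, seed = 2)
  f2 <- extract_features(seg)
  zp2 <- zscore_fit(f2)
  z2 <- zscore_apply(zp2, f2)
  expect_true(all(abs(colMeans(z2$values)) < 1e-9))
})

test_that("ReliefF matches the exhaustive-neighbour oracle exactly", {
  set.seed(5)
  n <- 40
  y <- rep(c("a", "b", "c"), length.out = n)
  x <- cbind(sep = as.numeric(factor(y)) + rnorm(n, 0, 0.05),
             noise1 = rnorm(n), noise2 = rnorm(n),
             const = rep(2, n), dup = as.numeric(factor(y)) +
               rnorm(n, 0, 0.05))
  fm <- feature_matrix(x, y)
  fw <- relieff_rank(fm, k_neighbors = 3, n_samples = "all")
  expect_equal(unname(fw$weights), relieff_oracle(x, y, 3),
               tolerance = 1e-12)
})

test_that("ReliefF ranks a perfectly separating feature first", {
  set.seed(6)
  n <- 50
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(sep = ifelse(y == "a", 0, 1) + rnorm(n, 0, 0.01),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  fm <- feature_matrix(x, y)
  fw <- relieff_rank(fm, k_neighbors = 1, n_samples = "all")
  expect_equal(fw$order[1], 1L)
  # a constant feature has weight exactly 0
  x2 <- cbind(x, const = rep(3, n))
  fw2 <- relieff_rank(feature_matrix(x2, y), k_neighbors = 1,
                      n_samples = "all")
  expect_identical(unname(fw2$weights["const"]), 0)
  # duplicating a feature column keeps the original relative order
  x3 <- cbind(x, dup_sep = x[, "sep"])
  fw3 <- relieff_rank(feature_matrix(x3, y), k_neighbors = 1,
                      n_samples = "all")
  orig_order <- fw$order
  kept <- fw3$order[fw3$order <= 4]
  expect_identical(kept, orig_order)
  # single-class input is rejected
  expect_error(relieff_rank(feature_matrix(x, rep("a", n))), "2 classes")
})

test_that("ReliefF subsampling is seed-deterministic", {
  seg <- make_sine_tensor(k = 40, seed = 3)
  fm <- extract_features(seg)
  f1 <- relieff_rank(fm, n_samples = 10, seed = 5)
  f2 <- relieff_rank(fm, n_samples = 10, seed = 5)
  f3 <- relieff_rank(fm, n_samples = 10, seed = 6)
  expect_identical(f1$weights, f2$weights)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("one-vs-all RBF SVM separates Gaussian blobs and memorizes them", {
  set.seed(11)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  centers <- ifelse(y == "a", 0, 3)
  x <- cbind(centers + rnorm(n, 0, 0.1), centers + rnorm(n, 0, 0.1))
  colnames(x) <- c("f1", "f2")
  fm <- feature_matrix(x, y)
  m <- train_svm(fm, gamma = 0.001, cost = 1000)
  expect_identical(predict_svm(m, fm), y)
  # prediction at a memorized training point returns its label
  one <- feature_matrix(x[7, , drop = FALSE])
  expect_identical(predict_svm(m, one), y[7])
  expect_error(train_svm(feature_matrix(x, rep("a", n))), "single class")
})
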