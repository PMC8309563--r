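test_that("layer-shape arithmetic matches the closed forms", {
  shp <- cnn_shapes(cnn_config(), T_len = 64, m = 4)
  expect_equal(shp$conv_len, 45)
  expect_equal(shp$pool_len, 15)
  expect_equal(shp$flat_per_channel, 45)
  expect_equal(shp$concat, 180)
  # arbitrary geometries
  for (case in list(c(100, 7, 2, 3), c(32, 32, 1, 2), c(50, 5, 4, 1))) {
    cfg <- cnn_config(kernel_size = case[2], pool_size = case[3])
    shp <- cnn_shapes(cfg, T_len = case[1], m = case[4])
    expect_equal(shp$conv_len, case[1] - case[2] + 1)
    expect_equal(shp$pool_len, (case[1] - case[2] + 1) %/% case[3])
    expect_equal(shp$concat, case[4] * shp$pool_len * 3)
  }
  expect_error(cnn_shapes(cnn_config(kernel_size = 65), 64, 4), "wider")
})

test_that("output layer width equals the class count and softmax rows sum to 1", {
  seg <- make_sine_tensor(k = 10, freqs = c(2, 5), seed = 3)
  model <- build_cnn(cnn_config(seed = 4), 64, 4, c(seg$labels, "extra"))
  expect_equal(ncol(model$par$W3), 3)
  pr <- predict_cnn(model, seg, type = "prob")
  expect_equal(dim(pr), c(10, 3))
  expect_equal(unname(rowSums(pr)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(pr >= 0))
  # argmax consistency
  lab <- predict_cnn(model, seg)
  expect_identical(lab, model$classes[apply(pr, 1, which.max)])
})

test_that("training is bit-reproducible under a fixed seed", {
  seg <- make_sine_tensor(k = 30, freqs = c(2, 6), seed = 5)
  cfg <- cnn_config(epochs = 3, seed = 17)
  m1 <- train_cnn(build_cnn(cfg, 64, 4, seg$labels), seg)
  m2 <- train_cnn(build_cnn(cfg, 64, 4, seg$labels), seg)
  expect_identical(m1$final_loss, m2$final_loss)
  expect_identical(m1$par, m2$par)
  cfg2 <- cnn_config(epochs = 3, seed = 18)
  m3 <- train_cnn(build_cnn(cfg2, 64, 4, seg$labels), seg)
  expect_false(identical(m1$final_loss, m3$final_loss))
})

test_that("zero epochs leave the initialized model unchanged", {
  seg <- make_sine_tensor(k = 10, seed = 6)
  model <- build_cnn(cnn_config(seed = 2), 64, 4, seg$labels)
  trained <- train_cnn(model, seg, epochs = 0)
  expect_identical(trained$par, model$par)
  expect_equal(trained$trained_epochs, 0L)
})

test_that("the network overfits a small separable training set", {
  # 60 windows, 3 well-separated sinusoid classes
  seg <- make_sine_tensor(k = 60, freqs = c(2, 6, 11), noise = 0.05,
                          seed = 7)
  cfg <- cnn_config(epochs = 50, seed = 21)
  model <- build_cnn(cfg, 64, 4, seg$labels)
  model <- train_cnn(model, seg, class_weights = class_weights(seg$labels))
  expect_identical(predict_cnn(model, seg), seg$labels)
})

test_that("class-weighted gradients equal duplication of minority samples", {
  # one batch: weighting class b by 2 must match including its samples
  # twice with unit weights (same normalized gradient direction)
  seg <- make_sine_tensor(k = 8, freqs = c(2, 6), seed = 8)
  model <- build_cnn(cnn_config(seed = 5), 64, 4, seg$labels)
  xs <- harens:::tensor_channels(model, seg)
  y_idx <- match(seg$labels, model$classes)
  w <- ifelse(seg$labels == "c2", 2, 1)
  fw <- harens:::cnn_forward(model, xs, cache = TRUE)
  g_w <- harens:::cnn_gradients(model, fw, xs, y_idx, w)
  dup <- c(seq_len(8), which(seg$labels == "c2"))
  seg2 <- harens:::subset_segments(seg, dup)
  xs2 <- harens:::tensor_channels(model, seg2)
  fw2 <- harens:::cnn_forward(model, xs2, cache = TRUE)
  g_d <- harens:::cnn_gradients(model, fw2, xs2, match(seg2$labels,
                                                       model$classes),
                                rep(1, length(dup)))
  for (nm in c("W1", "W3", "Wc1")) {
    expect_equal(g_w[[nm]], g_d[[nm]], tolerance = 1e-10)
  }
})

test_that("backpropagation matches numeric gradients", {
  set.seed(1)
  k <- 6; T_len <- 16; m <- 2
  vals <- array(rnorm(k * T_len * m), c(k, T_len, m),
                dimnames = list(NULL, NULL, c("Ax", "Ay")))
  seg <- structure(list(values = vals, labels = rep(c("a", "b", "c"), 2),
                        subject_ids = rep(1L, k),
                        trial_ids = rep(1L, k)), class = "segment_tensor")
  cfg <- cnn_config(n_filters = 2, kernel_size = 5, pool_size = 3,
                    fc_sizes = c(7, 4), seed = 3)
  model <- build_cnn(cfg, T_len, m, c("a", "b", "c"))
  xs <- harens:::tensor_channels(model, seg)
  y_idx <- match(seg$labels, model$classes)
  w <- rep(1, k)
  loss_fn <- function(mod) {
    fw <- harens:::cnn_forward(mod, xs)
    sum(-w * log(fw$prob[cbind(seq_len(k), y_idx)])) / sum(w)
  }
  fw <- harens:::cnn_forward(model, xs, cache = TRUE)
  g <- harens:::cnn_gradients(model, fw, xs, y_idx, w)
  eps <- 1e-6
  set.seed(2)
  for (nm in names(g)) {
    p <- model$par[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      mp <- model; mp$par[[nm]][i] <- p[i] + eps
      mm <- model; mm$par[[nm]][i] <- p[i] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   info = paste("param", nm))
    }
  }
})
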