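test_that("majority vote follows the plurality rule with the third-pipeline tie-break", {
  expect_identical(majority_vote("A3", "A3", "A4"), "A3")
  expect_identical(majority_vote("A5", "A5", "A5"), "A5")
  expect_identical(majority_vote("A1", "A2", "A3"), "A3")
  # exhaustive over all label triples for 10 classes
  classes <- unname(activity_classes())
  grid <- expand.grid(l1 = classes, l2 = classes, l3 = classes,
                      stringsAsFactors = FALSE)
  got <- majority_vote(grid$l1, grid$l2, grid$l3)
  oracle <- apply(grid, 1, function(r) {
    counts <- table(unlist(r))
    if (max(counts) == 1) r[["l3"]] else names(which.max(counts))
  })
  expect_identical(got, unname(oracle))
  # whenever two pipelines agree, the vote returns their label,
  # independent of argument order
  agree <- grid$l1 == grid$l2 | grid$l1 == grid$l3 | grid$l2 == grid$l3
  maj <- ifelse(grid$l1 == grid$l2 | grid$l1 == grid$l3, grid$l1, grid$l2)
  expect_identical(got[agree], maj[agree])
})

test_that("confusion matrices count actual rows and predicted columns", {
  C <- confusion(c("A3", "A4"), c("A3", "A4"), c("A3", "A4"))
  expect_equal(unname(diag(C)), c(1, 1))
  expect_equal(sum(C) - sum(diag(C)), 0)
  C2 <- confusion(c("A3", "A3", "A4"), c("A3", "A4", "A4"),
                  c("A3", "A4"))
  expect_equal(C2["A3", "A3"], 1)
  expect_equal(C2["A3", "A4"], 1)
  expect_equal(C2["A4", "A4"], 1)
  expect_equal(sum(C2), 3)
  expect_error(confusion("A3", c("A3", "A4")), "length mismatch")
  expect_error(confusion("A3", "A9", c("A3", "A4")), "outside")
})

test_that("per-class metrics match hand computation", {
  C <- matrix(c(5, 1, 2, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  pc <- per_class_metrics(C)
  expect_equal(pc$precision[1], 5 / 7, tolerance = 1e-12)
  expect_equal(pc$recall[1], 5 / 6, tolerance = 1e-12)
  expect_equal(pc$f1[1], 2 * (5 / 7) * (5 / 6) / (5 / 7 + 5 / 6),
               tolerance = 1e-12)
  expect_equal(pc$support, c(6, 4))
  # perfect diagonal
  D <- diag(3); dimnames(D) <- list(letters[1:3], letters[1:3])
  pcd <- per_class_metrics(D)
  expect_true(all(pcd$precision == 1 & pcd$recall == 1 & pcd$f1 == 1))
  # zero-division convention
  Z <- matrix(c(2, 0, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(pcz <- per_class_metrics(Z), "zero")
  expect_equal(pcz$precision[2], 0)
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(round(f1_score(1.00, 0.67), 2), 0.80)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(0.5, 0.5), 0.5)
})

test_that("macro, micro and weighted averages follow their definitions", {
  set.seed(3)
  true <- sample(c("a", "b", "c"), 200, replace = TRUE,
                 prob = c(0.6, 0.3, 0.1))
  pred <- ifelse(runif(200) < 0.7, true,
                 sample(c("a", "b", "c"), 200, replace = TRUE))
  rep_ <- classification_report(true, pred)
  pc <- rep_$per_class
  expect_equal(unname(rep_$macro["precision"]), mean(pc$precision))
  expect_equal(unname(rep_$macro["f1"]), mean(pc$f1))
  expect_equal(unname(rep_$weighted["recall"]),
               sum(pc$recall * pc$support) / sum(pc$support))
  # micro identity: precision = recall = F1 = accuracy
  acc <- mean(true == pred)
  expect_equal(unname(rep_$micro), rep(acc, 3), tolerance = 1e-12)
  # weighted recall equals accuracy
  expect_equal(unname(rep_$weighted["recall"]), acc, tolerance = 1e-12)
  # equal supports make weighted equal macro
  pc_eq <- data.frame(class = c("a", "b"), precision = c(0.8, 0.6),
                      recall = c(0.7, 0.5), f1 = c(0.74, 0.55),
                      support = c(10, 10))
  expect_equal(averaged_metrics(pc_eq, "weighted"),
               averaged_metrics(pc_eq, "macro"))
  # the harmonic macro-F1 variant differs when per-class F1s are skewed
  pc_sk <- data.frame(class = c("a", "b"), precision = c(1, 0.5),
                      recall = c(0.2, 1), f1 = c(f1_score(1, 0.2),
                                                 f1_score(0.5, 1)),
                      support = c(5, 5))
  m_mean <- averaged_metrics(pc_sk, "macro", macro_f1 = "mean")
  m_harm <- averaged_metrics(pc_sk, "macro", macro_f1 = "harmonic")
  expect_equal(unname(m_harm["f1"]),
               unname(f1_score(m_harm["precision"], m_harm["recall"])))
  expect_false(isTRUE(all.equal(m_mean["f1"], m_harm["f1"])))
})

test_that("class weights are inverse-frequency normalized", {
  expect_equal(unname(class_weights(rep(c("a", "b"), c(20, 20)))),
               c(1, 1))
  w <- class_weights(rep(c("a", "b"), c(10, 30)))
  expect_equal(unname(w), c(2, 2 / 3), tolerance = 1e-12)
  # rarest class always carries the largest weight
  set.seed(9)
  for (i in 1:10) {
    counts <- sample(1:50, 4)
    labs <- rep(letters[1:4], counts)
    w <- class_weights(labs)
    expect_equal(names(which.max(w)), letters[which.min(counts)])
  }
})

test_that("report printing rounds half away from zero to two decimals", {
  out <- capture.output(print(classification_report(c("a", "a", "b"),
                                                    c("a", "b", "b"))))
  expect_true(any(grepl("macro avg", out)))
  expect_identical(harens:::round_half_up(0.005, 2), 0.01)
  expect_identical(harens:::round_half_up(0.985, 2), 0.99)
  expect_identical(harens:::round_half_up(-0.005, 2), -0.01)
})
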