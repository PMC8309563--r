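# One-vs-all RBF support vector machine (first pipeline, stage 3).

#' Train a one-vs-all RBF-kernel SVM
#'
#' Fits one binary RBF-kernel SVM per class (that class against the rest)
#' on an already-normalized feature matrix. Prediction assigns each segment
#' to the class whose binary separator gives the largest decision value.
#' Per-class penalty weights scale the cost of misclassifying the positive
#' class, countering class imbalance.
#'
#' @param fm a `feature_matrix` with labels covering >= 2 classes. Features
#'   are used as-is (z-score them first; see [zscore_fit()]).
#' @param class_weights named per-class weights (e.g. from
#'   [class_weights()]); `NULL` for unweighted training.
#' @param gamma RBF kernel width parameter (default 0.001).
#' @param cost soft-margin penalty C (default 1000).
#' @return object of class `ova_svm`.
#' @export
train_svm <- function(fm, class_weights = NULL, gamma = 0.001, cost = 1000) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$labels
  if (is.null(y)) stop("train_svm needs labeled data")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training labels contain a single class")
  x <- fm$values
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    w <- c(pos = if (is.null(class_weights)) 1 else
      unname(class_weights[cl]), rest = 1)
    e1071::svm(x, yy, type = "C-classification", kernel = "radial",
               gamma = gamma, cost = cost, class.weights = w,
               scale = FALSE)
  })
  names(models) <- classes
  structure(list(models = models, classes = classes, gamma = gamma,
                 cost = cost),
            class = "ova_svm")
}

#' Predict with a one-vs-all SVM
#'
#' @param model an `ova_svm` from [train_svm()].
#' @param fm a `feature_matrix` normalized with the training parameters.
#' @return character vector of predicted labels (argmax of the per-class
#'   decision values; ties go to the first class in sorted order).
#' @export
predict_svm <- function(model, fm) {
  stopifnot(inherits(model, "ova_svm"), inherits(fm, "feature_matrix"))
  x <- fm$values
  if (nrow(x) == 0) return(character(0))
  scores <- vapply(model$classes, function(cl) {
    pr <- predict(model$models[[cl]], x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # decision values are oriented toward the first label in the column
    # name ("pos/rest" vs "rest/pos")
    if (startsWith(colnames(dv)[1], "pos")) dv[, 1] else -dv[, 1]
  }, numeric(nrow(x)))
  if (nrow(x) == 1) scores <- matrix(scores, nrow = 1)
  model$classes[apply(scores, 1, which.max)]
}
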