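# Majority-vote fusion and multiclass evaluation metrics.

#' Fuse three pipeline decisions by majority vote
#'
#' Returns, per segment, the plurality label among the three pipeline
#' predictions. When at least two pipelines agree the result is their
#' shared label, regardless of argument order. When all three disagree the
#' third pipeline's label is returned: the convolutional pipeline is the
#' strongest standalone model, so it serves as the deterministic
#' tie-breaker.
#'
#' @param l1,l2,l3 character vectors of predicted labels (first, second and
#'   third pipeline), equal length.
#' @return character vector of fused labels.
#' @export
#' @examples
#' majority_vote("A3", "A4", "A3") # "A3"
majority_vote <- function(l1, l2, l3) {
  if (length(l1) != length(l2) || length(l1) != length(l3)) {
    stop("prediction vectors must have equal length")
  }
  out <- l3
  out[l1 == l2] <- l1[l1 == l2]
  out
}

#' Confusion matrix
#'
#' Counts of segments from each actual class (rows) assigned to each
#' predicted class (columns), over a fixed class ordering.
#'
#' @param true,pred character vectors of equal length >= 1.
#' @param class_order character vector fixing the row/column order; every
#'   observed label must appear in it.
#' @return an l x l integer matrix with dimnames.
#' @export
confusion <- function(true, pred, class_order = sort(unique(c(true, pred)))) {
  if (length(true) != length(pred)) stop("length mismatch")
  if (length(true) == 0) stop("empty label vectors")
  bad <- setdiff(unique(c(true, pred)), class_order)
  if (length(bad) > 0) {
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "))
  }
  tf <- factor(true, levels = class_order)
  pf <- factor(pred, levels = class_order)
  unclass(table(actual = tf, predicted = pf))
}

#' Per-class precision, recall, F1 and support
#'
#' From a confusion matrix `C` with rows = actual and columns = predicted:
#' `TP_i = C[i, i]`, `FP_i = colSum - TP`, `FN_i = rowSum - TP`,
#' `P_i = TP/(TP+FP)`, `R_i = TP/(TP+FN)`, and F1 their harmonic mean.
#' Classes with no predicted (or no actual) instances get precision
#' (recall) 0 with a warning.
#'
#' @param C square non-negative count matrix.
#' @return data frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
per_class_metrics <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("confusion matrix must be square")
  tp <- diag(C)
  fp <- colSums(C) - tp
  fn <- rowSums(C) - tp
  if (any(tp + fp == 0) || any(tp + fn == 0)) {
    warning("class with zero predicted or actual count; metric defined as 0")
  }
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = rownames(C) %||% as.character(seq_len(nrow(C))),
             precision = unname(precision), recall = unname(recall),
             f1 = unname(f1), support = unname(rowSums(C)),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Averaged multiclass metrics
#'
#' Macro averaging takes the unweighted mean of the per-class values; the
#' macro F1 is by default the mean of the per-class F1 scores (the
#' convention of standard classification-report tables), with the harmonic
#' mean of macro precision and macro recall available via
#' `macro_f1 = "harmonic"`. Weighted averaging weights each class by its
#' support. Micro averaging pools TP/FP/FN counts over classes; for
#' single-label multiclass data micro precision, recall and F1 all equal
#' the overall accuracy.
#'
#' @param per_class data frame from [per_class_metrics()].
#' @param mode `"macro"`, `"micro"` or `"weighted"`.
#' @param C the confusion matrix (required for `mode = "micro"`).
#' @param macro_f1 `"mean"` (default) or `"harmonic"`.
#' @return named numeric vector with `precision`, `recall`, `f1`.
#' @export
averaged_metrics <- function(per_class, mode = c("macro", "micro", "weighted"),
                             C = NULL, macro_f1 = c("mean", "harmonic")) {
  mode <- match.arg(mode)
  macro_f1 <- match.arg(macro_f1)
  if (mode == "micro") {
    if (is.null(C)) stop("micro averaging needs the confusion matrix")
    C <- as.matrix(C)
    tp <- sum(diag(C))
    fp <- sum(colSums(C) - diag(C))
    fn <- sum(rowSums(C) - diag(C))
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    return(c(precision = p, recall = r, f1 = 2 * p * r / (p + r)))
  }
  if (sum(per_class$support) == 0) stop("zero total support")
  w <- if (mode == "weighted") {
    per_class$support / sum(per_class$support)
  } else {
    rep(1 / nrow(per_class), nrow(per_class))
  }
  p <- sum(w * per_class$precision)
  r <- sum(w * per_class$recall)
  f1 <- if (mode == "macro" && macro_f1 == "harmonic") {
    2 * p * r / (p + r)
  } else {
    sum(w * per_class$f1)
  }
  c(precision = p, recall = r, f1 = f1)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param precision,recall numeric vectors in `[0, 1]`.
#' @return numeric vector of F1 scores.
#' @export
#' @examples
#' f1_score(1.00, 0.67) # 0.80 at 2 decimals
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Inverse-frequency class weights
#'
#' Weight of class i is `K_total / (l_present * K_i)`, where `l_present`
#' is the number of classes observed: balanced classes get weight 1 and
#' the rarest class always gets the largest weight.
#'
#' @param labels character vector of training labels.
#' @return named numeric vector of weights.
#' @export
#' @examples
#' class_weights(rep(c("a", "b"), c(10, 30))) # 2.0, 0.667
class_weights <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  counts <- table(labels)
  w <- length(labels) / (length(counts) * counts)
  out <- as.numeric(w)
  names(out) <- names(w)
  out
}

#' Full classification report
#'
#' Confusion matrix, per-class metrics, and macro/micro/weighted averages
#' with overall accuracy, for a set of true and predicted labels.
#'
#' @param true,pred character vectors of equal length.
#' @param class_order fixed class ordering for the confusion matrix.
#' @param macro_f1 macro-F1 convention, see [averaged_metrics()].
#' @return object of class `classification_report`: list with `confusion`,
#'   `per_class`, `macro`, `micro`, `weighted`, `accuracy`, `n`.
#' @export
classification_report <- function(true, pred,
                                  class_order = sort(unique(c(true, pred))),
                                  macro_f1 = "mean") {
  C <- confusion(true, pred, class_order)
  pc <- suppressWarnings(per_class_metrics(C))
  structure(
    list(confusion = C, per_class = pc,
         macro = averaged_metrics(pc, "macro", macro_f1 = macro_f1),
         micro = averaged_metrics(pc, "micro", C = C),
         weighted = averaged_metrics(pc, "weighted"),
         accuracy = sum(diag(C)) / sum(C), n = sum(C)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  fmt <- function(v) sprintf(paste0("%.", digits, "f"),
                             round_half_up(v, digits))
  cat(sprintf("<classification_report> %d segments, accuracy %s\n", x$n,
              fmt(x$accuracy)))
  df <- x$per_class
  out <- data.frame(class = df$class, precision = fmt(df$precision),
                    recall = fmt(df$recall), f1 = fmt(df$f1),
                    support = df$support)
  out <- rbind(out,
               data.frame(class = "macro avg", precision = fmt(x$macro[1]),
                          recall = fmt(x$macro[2]), f1 = fmt(x$macro[3]),
                          support = x$n),
               data.frame(class = "weighted avg",
                          precision = fmt(x$weighted[1]),
                          recall = fmt(x$weighted[2]),
                          f1 = fmt(x$weighted[3]), support = x$n))
  print(out, row.names = FALSE)
  invisible(x)
}
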