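# K-nearest-neighbour classification (second pipeline, stage 2).

#' Store a KNN training set
#'
#' @param fm a labeled `feature_matrix`.
#' @param k number of neighbours (1 <= k <= number of training rows).
#' @return object of class `knn_model`.
#' @export
knn_train <- function(fm, k = 5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("knn_train needs labeled data")
  if (k < 1 || k > nrow(fm$values)) {
    stop("k must be between 1 and the training size")
  }
  structure(list(x = fm$values, labels = fm$labels, k = as.integer(k)),
            class = "knn_model")
}

#' Predict labels with K nearest neighbours
#'
#' Majority label among the `k` Euclidean-nearest training rows. Vote ties
#' are broken by the class with the smaller mean neighbour distance, then
#' by lexicographic label order; distance ties rank earlier training rows
#' first. All tie-breaks are deterministic.
#'
#' @param model a `knn_model` from [knn_train()].
#' @param fm a `feature_matrix` with matching columns.
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(model, fm) {
  stopifnot(inherits(model, "knn_model"), inherits(fm, "feature_matrix"))
  q <- fm$values
  if (ncol(q) != ncol(model$x)) stop("feature count mismatch")
  n_q <- nrow(q)
  if (n_q == 0) return(character(0))
  # squared Euclidean cross-distances via the expansion
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(q^2), rowSums(model$x^2), `+`) -
    2 * tcrossprod(q, model$x)
  d2[d2 < 0] <- 0
  k <- model$k
  out <- character(n_q)
  for (i in seq_len(n_q)) {
    nb <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    lab <- model$labels[nb]
    votes <- table(lab)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(cl) mean(d2[i, nb[lab == cl]]),
                       numeric(1))
      top <- top[mean_d == min(mean_d)]
      top <- sort(top)[1]
    }
    out[i] <- top
  }
  out
}
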