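# ReliefF feature relevance ranking (first pipeline, stage 2).

#' Rank features with the multiclass ReliefF algorithm
#'
#' Estimates per-feature relevance by contrasting nearest neighbours:
#' features that differ between an instance and its nearest same-class
#' neighbours ("hits") are penalized, and features that differ between the
#' instance and the nearest neighbours of every other class ("misses",
#' weighted by class priors) are rewarded. Per-feature differences are
#' Manhattan distances normalized by the feature's range over the whole
#' matrix, so weights are bounded by 1 in absolute value. With
#' `n_samples = "all"` the update runs over every instance in index order;
#' otherwise `n_samples` instances are sampled without replacement under
#' `seed`, which makes the ranking reproducible.
#'
#' For a sampled instance `R` of class `y` with `k` nearest hits `H` and,
#' per other class `c`, `k` nearest misses `M_c`, each feature weight is
#' updated by
#' `W_f <- W_f - sum(diff_f(R, H))/(nk) +
#'  sum_c P(c)/(1 - P(y)) * sum(diff_f(R, M_c))/(nk)`.
#'
#' @param fm a `feature_matrix` with labels covering >= 2 classes.
#' @param k_neighbors number of hits/misses per class (default 10).
#' @param n_samples number of sampled instances, or `"all"`.
#' @param seed integer seed for instance sampling.
#' @return object of class `feature_weights`: list with `weights` (named
#'   numeric, one per feature) and `order` (feature indices by descending
#'   weight; ties broken by feature index).
#' @export
relieff_rank <- function(fm, k_neighbors = 10, n_samples = "all", seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  y <- fm$labels
  if (is.null(y)) stop("relieff_rank needs labeled data")
  classes <- unique(y)
  if (length(classes) < 2) stop("ReliefF needs at least 2 classes")
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  n <- nrow(x)
  p <- ncol(x)
  rng <- apply(x, 2, max) - apply(x, 2, min)
  rng[rng == 0] <- 1 # constant features contribute zero difference anyway
  xn <- sweep(x, 2, rng, `/`) # range-normalized once, reused throughout
  priors <- table(y)[classes] / n
  if (identical(n_samples, "all")) {
    sampled <- seq_len(n)
  } else {
    if (n_samples > n) stop("n_samples exceeds the number of instances")
    sampled <- with_seed(seed, sample.int(n, n_samples))
  }
  w <- numeric(p)
  nk <- length(sampled) * k_neighbors
  class_idx <- split(seq_len(n), y)
  for (i in sampled) {
    # Manhattan distance in range-normalized space to every other instance
    d <- rowSums(abs(sweep(xn, 2, xn[i, ], `-`)))
    yi <- y[i]
    hits <- setdiff(class_idx[[yi]], i)
    nh <- head(hits[order(d[hits], hits)], k_neighbors)
    if (length(nh) > 0) {
      diffs <- abs(sweep(xn[nh, , drop = FALSE], 2, xn[i, ], `-`))
      w <- w - colSums(diffs) * (k_neighbors / length(nh)) / nk
    }
    for (cl in classes) {
      if (cl == yi) next
      miss <- class_idx[[cl]]
      nm <- head(miss[order(d[miss], miss)], k_neighbors)
      if (length(nm) == 0) next
      diffs <- abs(sweep(xn[nm, , drop = FALSE], 2, xn[i, ], `-`))
      scale <- priors[[cl]] / (1 - priors[[yi]])
      w <- w + scale * colSums(diffs) * (k_neighbors / length(nm)) / nk
    }
  }
  names(w) <- fm$feature_names
  structure(list(weights = w, order = order(-w, seq_len(p))),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat("<feature_weights> top features:\n")
  top <- head(x$order, 5)
  for (i in top) {
    cat(sprintf("  %-18s %+.4f\n", names(x$weights)[i], x$weights[i]))
  }
  invisible(x)
}

#' Keep the top-ranked features of a matrix
#'
#' @param fm a `feature_matrix`.
#' @param fw a `feature_weights` from [relieff_rank()].
#' @param n_keep how many top features to retain (default: all, i.e. rank
#'   only).
#' @return a `feature_matrix` restricted to the selected columns, in
#'   ranking order.
#' @export
select_features <- function(fm, fw, n_keep = ncol(fm$values)) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(fw, "feature_weights"))
  keep <- head(fw$order, n_keep)
  feature_matrix(fm$values[, keep, drop = FALSE], fm$labels)
}
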