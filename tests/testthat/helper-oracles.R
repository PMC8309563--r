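# Independent brute-force oracles, written with explicit loops and no
# shared code with the package implementations.

# Exhaustive-neighbour ReliefF accumulation.
relieff_oracle <- function(x, y, k) {
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, max) - apply(x, 2, min)
  rng[rng == 0] <- 1
  classes <- unique(y)
  priors <- sapply(classes, function(cl) mean(y == cl))
  names(priors) <- classes
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) {
      d[j] <- sum(abs(x[i, ] - x[j, ]) / rng)
    }
    hits <- which(y == y[i] & seq_len(n) != i)
    hits <- hits[order(d[hits], hits)]
    nh <- hits[seq_len(min(k, length(hits)))]
    if (length(nh) > 0) {
      for (f in seq_len(p)) {
        w[f] <- w[f] - sum(abs(x[nh, f] - x[i, f]) / rng[f]) /
          length(nh) / n
      }
    }
    for (cl in classes) {
      if (cl == y[i]) next
      miss <- which(y == cl)
      miss <- miss[order(d[miss], miss)]
      nm <- miss[seq_len(min(k, length(miss)))]
      if (length(nm) == 0) next
      for (f in seq_len(p)) {
        w[f] <- w[f] + priors[[cl]] / (1 - priors[[y[i]]]) *
          sum(abs(x[nm, f] - x[i, f]) / rng[f]) / length(nm) / n
      }
    }
  }
  w
}

# All-pairs KNN with the package's deterministic tie rules.
knn_oracle <- function(train_x, train_y, test_x, k) {
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      d[j] <- sum((test_x[i, ] - train_x[j, ])^2)
    }
    nb <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      md <- sapply(top, function(cl) mean(d[nb[train_y[nb] == cl]]))
      top <- top[md == min(md)]
      top <- sort(top)[1]
    }
    out[i] <- top
  }
  out
}
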