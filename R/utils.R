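# Internal helpers shared across modules.

#' Derive a child seed from a root seed and integer keys
#'
#' All stochastic stages (subject profiles, trial realizations, ReliefF
#' sampling, network initialization, per-fold work) draw their seeds through
#' this one mixing function, so that results are a pure function of the root
#' seed and are unaffected by execution order or parallel scheduling.
#'
#' The mix is a multiplicative-congruential step per key, kept below 2^31 so
#' the result is always a valid R integer seed.
#'
#' @param root integer root seed.
#' @param ... integer keys (e.g. subject id, trial number, fold index).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3, 2)
derive_seed <- function(root, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(root) %% m
  for (k in c(...)) {
    # 69069 * m < 2^53: exact in double arithmetic
    s <- (s * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Rotation matrix from small Euler angles (radians), R = Rz %*% Ry %*% Rx.
rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  rx_m <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  ry_m <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rz_m <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz_m %*% ry_m %*% rx_m
}

# Round half away from zero to `digits` decimals (display convention for
# classification reports; base round() uses round-half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}
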