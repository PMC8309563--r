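# Fixtures built in code, shared across test files.

# A minimal recording with a single constant label.
make_const_recording <- function(n = 192, label = "walk", fs = 64,
                                 value = c(0.1, 0.2, 0.9)) {
  recording(subject_id = 1, trial_no = 1,
            timestamp_ms = (seq_len(n) - 1) * 1000 / fs,
            ax = rep(value[1], n), ay = rep(value[2], n),
            az = rep(value[3], n),
            label = rep(label, n), fs = fs)
}

# A segment tensor with synthetic sinusoidal windows, built directly.
make_sine_tensor <- function(k = 12, T_len = 64, freqs = c(2, 5),
                             noise = 0.01, seed = 1) {
  set.seed(seed)
  labels <- rep(paste0("c", seq_along(freqs)), length.out = k)
  vals <- array(0, c(k, T_len, 4),
                dimnames = list(NULL, NULL, c("Ax", "Ay", "Az", "An")))
  t <- (seq_len(T_len) - 1) / T_len
  for (i in seq_len(k)) {
    f <- freqs[match(labels[i], paste0("c", seq_along(freqs)))]
    base <- sin(2 * pi * f * t + runif(1, 0, 2 * pi))
    for (ch in 1:3) {
      vals[i, , ch] <- base * (0.5 + 0.2 * ch) + rnorm(T_len, 0, noise)
    }
    vals[i, , 4] <- sqrt(vals[i, , 1]^2 + vals[i, , 2]^2 + vals[i, , 3]^2)
  }
  structure(list(values = vals, labels = labels,
                 subject_ids = rep(1L, k), trial_ids = rep(1L, k)),
            class = "segment_tensor")
}

# Small easy dataset for orchestration tests (kept tiny for speed).
make_tiny_dataset <- function(n_subjects = 2, n_trials = 1, seed = 7) {
  generate_dataset(n_subjects, n_trials, seed = seed)
}
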