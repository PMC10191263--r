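# Shared fixtures, built in code and memoized for the test session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_env)) assign(key, builder(), envir = fixture_env)
  get(key, envir = fixture_env)
}

# A small random spectrogram with two snippets.
tiny_stim <- function(n_freq = 18, T = 200, seed = 1, n_snippets = 2) {
  set.seed(seed)
  starts <- as.integer(seq(1, T, length.out = n_snippets + 1))[seq_len(n_snippets)]
  spectrogram(matrix(abs(rnorm(n_freq * T)), n_freq, T),
              center_freqs = exp(seq(log(200), log(20000), length.out = n_freq)),
              snippet_starts = starts)
}

# Small dataset for fast fit tests (not the acceptance fixture).
small_dataset <- function() {
  memo("small_dataset", function() {
    simulate_dataset(n_neurons = 12, subspace_dim = 4, n_sites = 2,
                     n_est_snippets = 30, n_val_snippets = 6,
                     snr_range = c(0.4, 0.8), seed = 77)
  })
}

fast_config <- function(seed = 5, ...) {
  fit_config(learning_rate = 7e-3, max_epochs = 120, patience = 12,
             n_init = 2, seed = seed, ...)
}

# Brute-force evaluation of the LN double-sum convolution equation
# r_lin(t) = sum_f sum_u h[f,u] s(f, t-u), zero-padded before each snippet.
brute_force_rlin <- function(S, h, starts = 1L) {
  T <- ncol(S); U <- ncol(h); F <- nrow(S)
  ends <- c(starts[-1] - 1L, T)
  seg_start <- function(t) max(starts[starts <= t])
  r <- numeric(T)
  for (t in seq_len(T)) {
    s0 <- seg_start(t)
    for (f in seq_len(F)) {
      for (u in 0:(U - 1)) {
        if (t - u >= s0) r[t] <- r[t] + h[f, u + 1] * S[f, t - u]
      }
    }
  }
  r
}
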