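# Synthetic stimuli and ground-truth populations with the statistical
# structure the analyses assume: a stimulus ensemble of concatenated ~1 s
# snippets, neurons tuned within a shared low-dimensional spectro-temporal
# subspace, heterogeneous per-neuron SNR, and a low-repeat estimation /
# high-repeat validation design.

#' Generate a synthetic stimulus ensemble
#'
#' Produces concatenated snippets of naturalistic log-spectrogram noise:
#' 2D Gaussian noise shaped to a `1/f^slope` joint spectro-temporal
#' modulation spectrum, squashed into the frontend's output range `[0, 5]`
#' around a mid-level mean, with a silent gap appended to each snippet.
#'
#' @param n_snippets Number of snippets (at least 2).
#' @param snippet_duration Sound duration per snippet in seconds (default 1).
#' @param n_freq Channel count (default 18).
#' @param seed RNG seed; output is fully reproducible.
#' @param bin_size Time bin in seconds (default 0.010).
#' @param amplitude Overall level scale; 0 gives all-floor spectrograms.
#' @param slope Modulation-spectrum exponent (default 1, i.e. 1/f).
#' @param gap_duration Silent gap appended per snippet in seconds
#'   (default 0.1).
#' @return A [spectrogram] with one `snippet_starts` entry per snippet.
#' @export
generate_stimuli <- function(n_snippets, snippet_duration = 1, n_freq = 18,
                             seed = 1, bin_size = 0.010, amplitude = 1,
                             slope = 1, gap_duration = 0.1) {
  if (n_snippets < 2) abort("need at least 2 snippets")
  Tb <- round(snippet_duration / bin_size)
  Tg <- round(gap_duration / bin_size)
  # separable 1/f^slope amplitude filter per modulation axis (overall DC
  # removed), so each marginal modulation power spectrum falls as
  # 1/f^(2*slope)
  ff <- c(seq(0, floor(n_freq / 2)), seq(-ceiling(n_freq / 2) + 1, -1)) / n_freq
  ft <- c(seq(0, floor(Tb / 2)), seq(-ceiling(Tb / 2) + 1, -1)) / Tb
  hf <- 1 / pmax(abs(ff), 1 / n_freq)^slope
  ht <- 1 / pmax(abs(ft), 1 / Tb)^slope
  H <- outer(hf, ht)
  H[1, 1] <- 0
  snippets <- with_seed(seed, lapply(seq_len(n_snippets), function(i) {
    z <- matrix(rnorm(n_freq * Tb), n_freq, Tb)
    zf <- stats::fft(z) * H
    x <- Re(stats::fft(zf, inverse = TRUE)) / length(zf)
    x <- (x - mean(x)) / max(sd(x), 1e-12)
    vals <- amplitude * pmax(pmin(2.5 + 0.8 * x, 5), 0)
    cbind(vals, matrix(0, n_freq, Tg))
  }))
  lens <- vapply(snippets, ncol, integer(1))
  spectrogram(do.call(cbind, snippets),
              center_freqs = exp(seq(log(200), log(20000), length.out = n_freq)),
              bin_size = bin_size,
              snippet_starts = cumsum(c(1L, lens[-length(lens)])))
}

# Smooth random temporal kernel: unit-norm, zero-mean, decaying envelope.
random_taps <- function(n_taps) {
  raw <- rnorm(n_taps + 6)
  sm <- stats::filter(raw, stats::dnorm(-3:3, sd = 1.2), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(n_taps)]
  sm <- sm * exp(-(seq_len(n_taps) - 1) / (n_taps / 2.5))
  sm <- sm - mean(sm)
  s <- sqrt(sum(sm^2))
  if (s < 1e-9) sm <- c(1, rep(0, n_taps - 1)) else sm <- sm / s
  sm * sample(c(-1, 1), 1) * runif(1, 0.8, 1.2)
}

#' Generate a ground-truth neural population
#'
#' Builds a true encoding model whose neurons all read from a shared
#' low-dimensional bank of nonlinear spectro-temporal channels (Gaussian
#' spectral weights, smooth temporal kernels, offset ReLU), each neuron
#' applying its own channel weighting and a calibrated double exponential
#' output nonlinearity. Per-neuron target SNR (signal-variance fraction) is
#' drawn uniformly in `snr_range`.
#'
#' With `orthogonal_sites`, neurons at those sites read an entirely
#' separate channel bank (twice `subspace_dim` channels are built), giving
#' a population whose held-out site shares no tuning subspace with the
#' rest -- the negative control for generalization protocols.
#'
#' @param n_neurons Population size (default 60).
#' @param subspace_dim Shared channel count (default 10).
#' @param n_sites Number of recording sites; neurons are assigned in equal
#'   blocks (default 3).
#' @param snr_range Range of per-neuron signal-variance fractions
#'   (default `c(0.15, 0.85)`).
#' @param seed RNG seed.
#' @param n_freq,n_taps Channel count and temporal kernel length.
#' @param orthogonal_sites Site labels whose neurons use a disjoint channel
#'   bank (default none).
#' @return Object of class `gt_population`: the true `model_spec` and
#'   parameters, per-neuron SNR, site labels and readout-channel support.
#' @export
generate_population <- function(n_neurons = 60, subspace_dim = 10, n_sites = 3,
                                snr_range = c(0.15, 0.85), seed = 1,
                                n_freq = 18, n_taps = 25,
                                orthogonal_sites = NULL) {
  if (n_neurons < 1 || subspace_dim < 1) abort("n_neurons and subspace_dim must be positive")
  site_ids <- paste0("site", sort(rep(seq_len(n_sites), length.out = n_neurons)))
  neuron_ids <- sprintf("n%03d", seq_len(n_neurons))
  two_banks <- !is.null(orthogonal_sites)
  D <- subspace_dim * (1L + two_banks)
  spec <- model_spec("1D-CNN", n_neurons = n_neurons, n_freq = n_freq,
                     n_units = D, hidden = D, n_taps = n_taps)
  with_seed(seed, {
    mu <- rep(seq(1, n_freq - 2, length.out = subspace_dim), 1 + two_banks) +
      rnorm(D, 0, 0.5)
    sigma <- runif(D, 1, 2.5)
    taps <- t(vapply(seq_len(D), function(i) random_taps(n_taps), numeric(n_taps)))
    # calibration stimulus to place activation offsets and rate scales
    cal <- generate_stimuli(20, seed = child_seed(seed, "cal"), n_freq = n_freq)
    W <- gauss_weights(mu, sigma, n_freq)
    pre <- cc_conv1d(W %*% cal$values, taps, cal$snippet_starts)
    relu_off <- apply(pre, 1, quantile, 0.3)
    H <- pmax(pre - relu_off, 0)
    in_bank2 <- site_ids %in% orthogonal_sites
    Wout <- matrix(0, n_neurons, D)
    for (i in seq_len(n_neurons)) {
      units <- if (two_banks && in_bank2[i]) subspace_dim + seq_len(subspace_dim)
               else seq_len(subspace_dim)
      Wout[i, units] <- rnorm(subspace_dim) / sqrt(subspace_dim)
    }
    y <- Wout %*% H
    sdy <- apply(y, 1, sd); sdy[sdy < 1e-9] <- 1
    my <- rowMeans(y)
    dexp_pars <- list(b = runif(n_neurons, 1, 5),
                      a = runif(n_neurons, 20, 60),
                      s = my + 0.3 * sdy,
                      k = 1.5 / sdy)
    params <- list(
      list(mu = mu, sigma = sigma),            # gauss
      list(taps = taps),                       # conv
      list(offset = relu_off),                 # relu
      list(W = diag(D)),                       # hidden mix = identity
      list(offset = rep(0, D)),                # hidden relu: pass-through
      list(W = Wout),                          # readout
      dexp_pars                                # double exponential
    )
    snr <- runif(n_neurons, snr_range[1], snr_range[2])
    structure(list(spec = spec, params = params, subspace_dim = subspace_dim,
                   snr = snr, neuron_ids = neuron_ids, site_ids = site_ids,
                   orthogonal_sites = orthogonal_sites, seed = seed),
              class = "gt_population")
  })
}

#' @export
print.gt_population <- function(x, ...) {
  cat(sprintf("<gt_population> %d neurons, %d-dim shared subspace, %d site(s)%s\n",
              length(x$neuron_ids), x$subspace_dim, length(unique(x$site_ids)),
              if (!is.null(x$orthogonal_sites))
                paste0(" (orthogonal: ", paste(x$orthogonal_sites, collapse = ","), ")")
              else ""))
  invisible(x)
}

#' Simulate trial responses from a ground-truth population
#'
#' Computes noise-free rates from the true model and adds trial-to-trial
#' variability: Gaussian noise scaled per neuron so the repeat-wise
#' signal-variance fraction matches the neuron's target SNR (rates floored
#' at zero), or Poisson spike counts drawn per bin.
#'
#' @param pop A [generate_population()] result.
#' @param stim A [spectrogram] of stimulus snippets.
#' @param n_repeats Number of trials `M`.
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @param seed RNG seed.
#' @return A [trial_raster] `N x T x M`.
#' @export
simulate_responses <- function(pop, stim, n_repeats, noise_model = "gaussian",
                               seed = 1) {
  if (!noise_model %in% c("gaussian", "poisson"))
    abort("noise_model must be 'gaussian' or 'poisson'")
  R <- model_forward(pop$spec, pop$params, stim)
  N <- nrow(R); T <- ncol(R)
  rates <- array(0, c(N, T, n_repeats))
  with_seed(seed, {
    if (noise_model == "gaussian") {
      sig_sd <- apply(R, 1, sd)
      noise_sd <- sig_sd * sqrt((1 - pop$snr) / pop$snr)
      for (m in seq_len(n_repeats)) {
        rates[, , m] <- pmax(R + rnorm(N * T) * noise_sd, 0)
      }
    } else {
      bs <- stim$bin_size
      for (m in seq_len(n_repeats)) {
        rates[, , m] <- matrix(stats::rpois(N * T, pmax(R, 0) * bs), N, T) / bs
      }
    }
  })
  trial_raster(rates, bin_size = stim$bin_size, neuron_ids = pop$neuron_ids,
               site_ids = pop$site_ids)
}

#' Simulate a complete synthetic dataset
#'
#' The desk-scale fixture for end-to-end validation: disjoint estimation
#' and validation stimulus ensembles (single-repeat estimation, multi-repeat
#' validation), a ground-truth population with a shared low-dimensional
#' subspace across recording sites, and heterogeneous per-neuron SNR.
#'
#' @param n_neurons,subspace_dim,n_sites,snr_range,orthogonal_sites Passed
#'   to [generate_population()].
#' @param n_est_snippets,n_val_snippets Snippet counts for the two sets
#'   (defaults 120 and 12).
#' @param snippet_duration Seconds of sound per snippet (default 1).
#' @param n_repeats_val Validation repeats (default 20).
#' @param noise_model Trial-noise model (default `"gaussian"`).
#' @param seed Top-level seed; all component seeds derive from it.
#' @return An [strf_dataset()] with the ground truth attached.
#' @export
simulate_dataset <- function(n_neurons = 60, subspace_dim = 10, n_sites = 3,
                             n_est_snippets = 120, n_val_snippets = 12,
                             snippet_duration = 1, n_repeats_val = 20,
                             snr_range = c(0.15, 0.85), noise_model = "gaussian",
                             orthogonal_sites = NULL, seed = 1) {
  est_stim <- generate_stimuli(n_est_snippets, snippet_duration,
                               seed = child_seed(seed, "est-stim"))
  val_stim <- generate_stimuli(n_val_snippets, snippet_duration,
                               seed = child_seed(seed, "val-stim"))
  pop <- generate_population(n_neurons, subspace_dim, n_sites, snr_range,
                             seed = child_seed(seed, "pop"),
                             orthogonal_sites = orthogonal_sites)
  est_raster <- simulate_responses(pop, est_stim, 1, noise_model,
                                   seed = child_seed(seed, "est-resp"))
  val_raster <- simulate_responses(pop, val_stim, n_repeats_val, noise_model,
                                   seed = child_seed(seed, "val-resp"))
  strf_dataset(est_stim, est_raster, val_stim, val_raster, truth = pop,
               meta = list(seed = seed, noise_model = noise_model,
                           snr_range = snr_range, subspace_dim = subspace_dim))
}
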