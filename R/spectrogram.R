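#' Spectrogram container
#'
#' A log-compressed power spectrogram: an `F x T` matrix of nonnegative
#' values with channel center frequencies and a fixed time-bin width.
#' When several stimulus snippets are concatenated along the time axis,
#' `snippet_starts` records the first column of each snippet; temporal
#' convolutions never carry context across snippet boundaries.
#'
#' @param values Nonnegative numeric matrix, frequency channels x time bins.
#' @param center_freqs Strictly increasing vector of channel center
#'   frequencies in Hz, one per row of `values`.
#' @param bin_size Time-bin width in seconds (default 0.010).
#' @param snippet_starts Integer vector of 1-based start columns of each
#'   snippet; the first element must be 1.
#' @return An object of class `spectrogram`.
#' @export
spectrogram <- function(values, center_freqs, bin_size = 0.010,
                        snippet_starts = 1L) {
  values <- as.matrix(values)
  if (anyNA(values)) abort("spectrogram values must not contain NA")
  if (any(values < 0)) abort("spectrogram values must be nonnegative")
  if (length(center_freqs) != nrow(values))
    abort("length(center_freqs) must equal nrow(values)")
  if (any(diff(center_freqs) <= 0))
    abort("center_freqs must be strictly increasing")
  if (bin_size <= 0) abort("bin_size must be positive")
  snippet_starts <- as.integer(snippet_starts)
  if (snippet_starts[1] != 1L || is.unsorted(snippet_starts, strictly = TRUE))
    abort("snippet_starts must be strictly increasing and begin at 1")
  structure(
    list(values = values, center_freqs = as.numeric(center_freqs),
         bin_size = bin_size, snippet_starts = snippet_starts),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d channels x %d bins (%.0f ms bins, %d snippet(s), %.0f-%.0f Hz)\n",
    nrow(x$values), ncol(x$values), x$bin_size * 1000,
    length(x$snippet_starts), min(x$center_freqs), max(x$center_freqs)))
  invisible(x)
}

#' @export
dim.spectrogram <- function(x) dim(x$values)

#' Concatenate spectrogram snippets along time
#'
#' @param snippets List of `spectrogram` objects with identical channels.
#' @return A single `spectrogram` whose `snippet_starts` marks each piece.
#' @export
bind_snippets <- function(snippets) {
  stopifnot(length(snippets) >= 1)
  f0 <- snippets[[1]]$center_freqs
  for (s in snippets) {
    if (!isTRUE(all.equal(s$center_freqs, f0)))
      abort("all snippets must share center frequencies")
  }
  lens <- vapply(snippets, function(s) ncol(s$values), integer(1))
  spectrogram(
    do.call(cbind, lapply(snippets, `[[`, "values")),
    center_freqs = f0, bin_size = snippets[[1]]$bin_size,
    snippet_starts = cumsum(c(1L, lens[-length(lens)]))
  )
}

# Second-order gammatone impulse response, sampled at fs, truncated where the
# temporal envelope falls below 1e-6 of its peak.
gammatone_ir <- function(cf, fs, order = 2) {
  erb <- 24.7 * (4.37 * cf / 1000 + 1)
  b <- 1.019 * erb
  t_peak <- (order - 1) / (2 * pi * b)
  # envelope t^(order-1) exp(-2 pi b t): find decay point numerically
  env_pk <- if (order == 1) 1 else t_peak^(order - 1) * exp(-2 * pi * b * t_peak)
  t_max <- t_peak
  repeat {
    t_max <- t_max + 1 / (2 * pi * b)
    env <- t_max^(order - 1) * exp(-2 * pi * b * t_max)
    if (env < 1e-6 * env_pk || t_max > 0.2) break
  }
  n <- max(8L, ceiling(t_max * fs))
  t <- (seq_len(n) - 1) / fs
  ir <- t^(order - 1) * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  ir / sqrt(sum(ir^2))
}

# FFT-based linear convolution, keeping the first length(x) samples.
fft_filter <- function(x, h) {
  n <- length(x) + length(h) - 1
  nfft <- 2^ceiling(log2(n))
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                     stats::fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_along(x)]
}

#' Gammatone log-spectrogram frontend
#'
#' Converts an audio waveform into the model input: a bank of second-order
#' gammatone filters with log-spaced center frequencies, power envelopes
#' averaged within fixed time bins, then log compression. The frontend is
#' fixed -- none of its parameters are fit.
#'
#' Compression maps bin power `p` to `log10(1 + p / (epsilon * ref))` where
#' `ref` is the maximum bin power of the waveform, so silence maps to the
#' floor value 0 and the output is nonnegative and monotone in power.
#'
#' @param waveform Numeric vector of audio samples.
#' @param sample_rate Sampling rate in Hz; must exceed `2 * f_high`.
#' @param n_channels Number of filterbank channels (default 18).
#' @param f_low,f_high Lowest and highest center frequencies in Hz
#'   (defaults 200 and 20000); centers are log-spaced, endpoints inclusive.
#' @param out_rate Output sampling rate in Hz (default 100, i.e. 10 ms bins).
#' @param epsilon Compression floor as a fraction of the reference power
#'   (default 1e-5).
#' @param envelope Envelope extraction before binning: `"power"` (squared
#'   filter output averaged per bin, the default) or `"halfwave"` (half-wave
#'   rectified output squared, then averaged).
#' @return A [spectrogram].
#' @export
gammatone_spectrogram <- function(waveform, sample_rate, n_channels = 18,
                                  f_low = 200, f_high = 20000, out_rate = 100,
                                  epsilon = 1e-5,
                                  envelope = c("power", "halfwave")) {
  envelope <- match.arg(envelope)
  if (length(waveform) == 0) abort("waveform must be nonempty")
  if (f_low >= f_high) abort("f_low must be below f_high")
  if (sample_rate <= 2 * f_high)
    abort("f_high is at or above the Nyquist frequency")
  cfs <- exp(seq(log(f_low), log(f_high), length.out = n_channels))
  dur <- length(waveform) / sample_rate
  T_out <- ceiling(dur * out_rate)
  bin_of <- pmin(T_out, floor((seq_along(waveform) - 1) / sample_rate * out_rate) + 1L)
  P <- matrix(0, n_channels, T_out)
  denom <- tabulate(bin_of, nbins = T_out)
  for (j in seq_len(n_channels)) {
    y <- fft_filter(waveform, gammatone_ir(cfs[j], sample_rate))
    if (envelope == "halfwave") y <- pmax(y, 0)
    p <- y^2
    P[j, ] <- as.numeric(rowsum(p, bin_of, reorder = TRUE)) / denom
  }
  ref <- max(P)
  if (ref <= 0) ref <- 1
  vals <- log10(1 + P / (epsilon * ref))
  spectrogram(vals, center_freqs = cfs, bin_size = 1 / out_rate)
}

#' Read a WAV audio file
#'
#' Minimal RIFF/WAVE reader for PCM (8/16/24/32-bit integer) and 32/64-bit
#' IEEE float data; multi-channel audio is averaged to mono. Samples are
#' returned in [-1, 1].
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    abort("not a RIFF/WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) abort("missing fmt or data chunk in WAV file")
  bytes <- fmt$bits / 8
  n <- length(data) %/% bytes
  x <- if (fmt$audio_format == 3) { # IEEE float
    readBin(data, "numeric", n = n, size = bytes, endian = "little")
  } else if (fmt$audio_format == 1) {
    if (fmt$bits == 8) {
      readBin(data, "integer", n = n, size = 1, signed = FALSE,
              endian = "little") / 127.5 - 1
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data[seq_len(n * 3)]), 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388607
    } else {
      readBin(data, "integer", n = n, size = bytes, signed = TRUE,
              endian = "little") / (2^(fmt$bits - 1) - 1)
    }
  } else abort(sprintf("unsupported WAV audio format code %d", fmt$audio_format))
  if (fmt$n_channels > 1) {
    n_frames <- length(x) %/% fmt$n_channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$n_channels)], fmt$n_channels))
  }
  list(samples = as.numeric(x), sample_rate = fmt$sample_rate)
}

#' Frequency response of the frontend's gammatone filters
#'
#' Magnitude response of each filterbank channel at the given frequencies,
#' evaluated directly from the sampled impulse responses. Used for
#' validation of the filterbank.
#'
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @inheritParams gammatone_spectrogram
#' @return Matrix `n_channels x length(freqs)` of magnitude responses.
#' @export
gammatone_response <- function(freqs, sample_rate, n_channels = 18,
                               f_low = 200, f_high = 20000) {
  cfs <- exp(seq(log(f_low), log(f_high), length.out = n_channels))
  out <- matrix(0, n_channels, length(freqs))
  for (j in seq_len(n_channels)) {
    ir <- gammatone_ir(cfs[j], sample_rate)
    n <- seq_along(ir) - 1
    for (k in seq_along(freqs)) {
      z <- sum(ir * exp(-2i * pi * freqs[k] * n / sample_rate))
      out[j, k] <- Mod(z)
    }
  }
  out
}
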