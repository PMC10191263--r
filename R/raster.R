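#' Trial raster container
#'
#' Spike rates per neuron, time bin and stimulus repeat: an `N x T x M`
#' array of nonnegative rates in spikes/s.
#'
#' @param rates Numeric array `N x T x M` (neurons x time x repeats),
#'   finite and nonnegative.
#' @param bin_size Time-bin width in seconds.
#' @param neuron_ids Unique neuron identifiers (default `n1..nN`).
#' @param site_ids Recording-site label per neuron (default one site).
#' @return An object of class `trial_raster`.
#' @export
trial_raster <- function(rates, bin_size = 0.010, neuron_ids = NULL,
                         site_ids = NULL) {
  rates <- as.array(rates)
  if (length(dim(rates)) == 2) dim(rates) <- c(dim(rates), 1L)
  if (length(dim(rates)) != 3) abort("rates must be an N x T x M array")
  if (!all(is.finite(rates)) || any(rates < 0))
    abort("rates must be finite and nonnegative")
  n <- dim(rates)[1]
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(n))
  if (anyDuplicated(neuron_ids)) abort("neuron_ids must be unique")
  if (is.null(site_ids)) site_ids <- rep("site1", n)
  if (length(neuron_ids) != n || length(site_ids) != n)
    abort("neuron_ids and site_ids must have one entry per neuron")
  structure(
    list(rates = rates, bin_size = bin_size,
         neuron_ids = as.character(neuron_ids),
         site_ids = as.character(site_ids)),
    class = "trial_raster"
  )
}

#' @export
print.trial_raster <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<trial_raster> %d neurons x %d bins x %d repeat(s), %.0f ms bins, %d site(s)\n",
              d[1], d[2], d[3], x$bin_size * 1000, length(unique(x$site_ids))))
  invisible(x)
}

#' @export
dim.trial_raster <- function(x) dim(x$rates)

#' Peristimulus time histogram
#'
#' Collapses a trial raster to the trial-averaged time-varying rate.
#'
#' @param raster A [trial_raster].
#' @return Numeric matrix `N x T` of mean rates (spikes/s).
#' @export
psth <- function(raster) {
  stopifnot(inherits(raster, "trial_raster"))
  d <- dim(raster$rates)
  out <- apply(raster$rates, c(1, 2), mean)
  dimnames(out) <- list(raster$neuron_ids, NULL)
  out
}

#' Bin spike times into a trial raster
#'
#' Converts spike timestamps to binned rates. The integral of rate over
#' time within each trial equals that trial's spike count exactly.
#'
#' @param spike_times List over neurons; each element a list over trials of
#'   numeric spike-time vectors in seconds, all within `[0, duration)`.
#'   Every neuron must have the same number of trials.
#' @param duration Trial duration in seconds.
#' @param bin_size Bin width in seconds (default 0.010).
#' @param neuron_ids,site_ids Optional identifiers passed to [trial_raster].
#' @return A [trial_raster] with `T = ceiling(duration / bin_size)` bins.
#' @export
bin_spikes <- function(spike_times, duration, bin_size = 0.010,
                       neuron_ids = NULL, site_ids = NULL) {
  if (duration <= 0 || bin_size <= 0) abort("duration and bin_size must be positive")
  n <- length(spike_times)
  m <- length(spike_times[[1]])
  if (any(vapply(spike_times, length, integer(1)) != m))
    abort("all neurons must have the same number of trials")
  T_out <- ceiling(duration / bin_size)
  rates <- array(0, c(n, T_out, m))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      st <- spike_times[[i]][[j]]
      if (length(st) == 0) next
      if (any(st < 0 | st >= duration))
        abort("spike times must lie within [0, duration)")
      idx <- pmin(T_out, floor(st / bin_size) + 1L)
      rates[i, , j] <- tabulate(idx, nbins = T_out) / bin_size
    }
  }
  trial_raster(rates, bin_size = bin_size, neuron_ids = neuron_ids,
               site_ids = site_ids)
}
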