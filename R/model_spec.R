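#' Declare a model architecture
#'
#' Builds a declarative description of one of the six architectures as a
#' sequence of layer primitives. All architectures take an `F x T`
#' log-spectrogram and predict firing rates; population architectures share
#' all layers up to a final per-neuron dense readout with a double
#' exponential output nonlinearity.
#'
#' Architectures and their size arguments:
#' \describe{
#'   \item{`LN`}{Rank-`rank` factorized linear-nonlinear model: Gaussian
#'     spectral weights (`rank` components), `rank x n_taps` temporal
#'     filters summed over components, then the output nonlinearity. With
#'     `n_neurons > 1`, independent per-neuron LN models are batched into
#'     one spec (no parameters are shared).}
#'   \item{`single-CNN`}{`n_units` Gaussian-weighted 1D convolutional units
#'     with offset-ReLU activations, then a single dense output unit;
#'     `n_neurons` must be 1.}
#'   \item{`pop-LN`}{`n_units` 1D convolutional units with no activation
#'     function, then `n_neurons` dense output units.}
#'   \item{`1D-CNN`}{`n_units` 1D convolutional units (ReLU), a hidden dense
#'     layer of `hidden` units (ReLU), then the output layer.}
#'   \item{`1Dx2-CNN`}{Two 1D convolutional layers (`n_units1` units with
#'     `n_taps1` taps, then `n_units2` units with dense channel weights and
#'     `n_taps2` taps), a hidden dense layer, then the output layer.}
#'   \item{`2D-CNN`}{Three stacked 2D convolutional layers of
#'     `n_conv_units` units each (`kf x kt` kernels, causal in time,
#'     centered in frequency), flattened, a hidden dense layer, then the
#'     output layer.}
#' }
#'
#' @param architecture One of `"LN"`, `"single-CNN"`, `"pop-LN"`,
#'   `"1D-CNN"`, `"1Dx2-CNN"`, `"2D-CNN"`.
#' @param n_neurons Number of output neurons `N`.
#' @param n_freq Spectrogram channel count `F` (default 18).
#' @param rank LN factorization rank `D` (default 1).
#' @param n_units,n_units1,n_units2 Convolutional unit counts.
#' @param hidden Hidden dense unit count.
#' @param n_taps,n_taps1,n_taps2 Temporal filter lengths in bins (defaults:
#'   25 bins = 250 ms; 15 and 10 bins for the two `1Dx2-CNN` layers).
#' @param n_conv_units 2D convolutional units per layer (default 10).
#' @param kf,kt 2D kernel spectral/temporal span (defaults 3 and 8).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture, n_neurons = 1, n_freq = 18,
                       rank = 1, n_units = NULL, hidden = NULL,
                       n_taps = 25, n_units1 = NULL, n_units2 = NULL,
                       n_taps1 = 15, n_taps2 = 10,
                       n_conv_units = 10, kf = 3, kt = 8) {
  architecture <- match.arg(architecture,
    c("LN", "single-CNN", "pop-LN", "1D-CNN", "1Dx2-CNN", "2D-CNN"))
  n <- as.integer(n_neurons)
  if (n < 1 || n_freq < 1) abort("n_neurons and n_freq must be positive")
  chk <- function(x, nm) {
    if (is.null(x) || x < 1) abort(paste(nm, "must be a positive integer"))
    as.integer(x)
  }
  layers <- switch(architecture,
    "LN" = {
      rank <- chk(rank, "rank")
      list(
        list(type = "gauss", n_units = n * rank, n_freq = n_freq),
        list(type = "conv", n_units = n * rank, n_taps = as.integer(n_taps)),
        list(type = "sumgroups", groups = rep(seq_len(n), each = rank)),
        list(type = "dexp", n_units = n)
      )
    },
    "single-CNN" = {
      if (n != 1) abort("single-CNN predicts one neuron (n_neurons must be 1)")
      u <- chk(n_units, "n_units")
      list(
        list(type = "gauss", n_units = u, n_freq = n_freq),
        list(type = "conv", n_units = u, n_taps = as.integer(n_taps)),
        list(type = "relu", n_units = u),
        list(type = "mix", n_out = 1L, n_in = u),
        list(type = "dexp", n_units = 1L)
      )
    },
    "pop-LN" = {
      u <- chk(n_units, "n_units")
      list(
        list(type = "gauss", n_units = u, n_freq = n_freq),
        list(type = "conv", n_units = u, n_taps = as.integer(n_taps)),
        list(type = "mix", n_out = n, n_in = u),
        list(type = "dexp", n_units = n)
      )
    },
    "1D-CNN" = {
      u <- chk(n_units, "n_units"); h <- chk(hidden, "hidden")
      list(
        list(type = "gauss", n_units = u, n_freq = n_freq),
        list(type = "conv", n_units = u, n_taps = as.integer(n_taps)),
        list(type = "relu", n_units = u),
        list(type = "mix", n_out = h, n_in = u),
        list(type = "relu", n_units = h),
        list(type = "mix", n_out = n, n_in = h),
        list(type = "dexp", n_units = n)
      )
    },
    "1Dx2-CNN" = {
      u1 <- chk(n_units1, "n_units1"); u2 <- chk(n_units2, "n_units2")
      h <- chk(hidden, "hidden")
      list(
        list(type = "gauss", n_units = u1, n_freq = n_freq),
        list(type = "conv", n_units = u1, n_taps = as.integer(n_taps1)),
        list(type = "relu", n_units = u1),
        list(type = "mix", n_out = u2, n_in = u1),
        list(type = "conv", n_units = u2, n_taps = as.integer(n_taps2)),
        list(type = "relu", n_units = u2),
        list(type = "mix", n_out = h, n_in = u2),
        list(type = "relu", n_units = h),
        list(type = "mix", n_out = n, n_in = h),
        list(type = "dexp", n_units = n)
      )
    },
    "2D-CNN" = {
      u <- chk(n_conv_units, "n_conv_units"); h <- chk(hidden, "hidden")
      kf <- as.integer(kf); kt <- as.integer(kt)
      if (kf %% 2 == 0) abort("kf must be odd (centered spectral kernel)")
      list(
        list(type = "expand2d"),
        list(type = "conv2d", n_units = u, n_in = 1L, kf = kf, kt = kt),
        list(type = "relu", n_units = u),
        list(type = "conv2d", n_units = u, n_in = u, kf = kf, kt = kt),
        list(type = "relu", n_units = u),
        list(type = "conv2d", n_units = u, n_in = u, kf = kf, kt = kt),
        list(type = "relu", n_units = u),
        list(type = "flatten2d", n_in = u, n_freq = n_freq),
        list(type = "mix", n_out = h, n_in = u * n_freq),
        list(type = "relu", n_units = h),
        list(type = "mix", n_out = n, n_in = h),
        list(type = "dexp", n_units = n)
      )
    }
  )
  structure(
    list(architecture = architecture, n_neurons = n, n_freq = as.integer(n_freq),
         rank = if (architecture == "LN") as.integer(rank) else NULL,
         layers = layers),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, %d neuron(s), F = %d\n", x$architecture,
              x$n_neurons, x$n_freq))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    sz <- switch(ly$type,
      gauss = sprintf("%d units", ly$n_units),
      conv = sprintf("%d units x %d taps", ly$n_units, ly$n_taps),
      conv2d = sprintf("%d units, %dx%d kernels over %d channels",
                       ly$n_units, ly$kf, ly$kt, ly$n_in),
      mix = sprintf("%d x %d", ly$n_out, ly$n_in),
      relu = sprintf("%d units", ly$n_units),
      dexp = sprintf("%d outputs", ly$n_units),
      sumgroups = sprintf("%d -> %d", length(ly$groups), max(ly$groups)),
      "")
    cat(sprintf("  [%d] %-10s %s\n", i, ly$type, sz))
  }
  invisible(x)
}

#' Exemplar model specifications
#'
#' The representative size for each architecture used throughout the
#' analyses (near-asymptotic prediction accuracy at matched complexity):
#' LN rank 5; single-CNN 6 units; pop-LN 120 units; 1D-CNN 100 units /
#' 120 hidden; 1Dx2-CNN 70 + 80 units (150/100 ms) / 100 hidden; 2D-CNN
#' three layers of ten 3x8 kernels / 90 hidden.
#'
#' @param architecture Architecture name, as in [model_spec()].
#' @param n_neurons Output neuron count.
#' @param n_freq Spectrogram channel count.
#' @return A `model_spec`.
#' @export
exemplar_spec <- function(architecture, n_neurons = 1, n_freq = 18) {
  switch(architecture,
    "LN" = model_spec("LN", n_neurons, n_freq, rank = 5),
    "single-CNN" = model_spec("single-CNN", 1, n_freq, n_units = 6),
    "pop-LN" = model_spec("pop-LN", n_neurons, n_freq, n_units = 120),
    "1D-CNN" = model_spec("1D-CNN", n_neurons, n_freq, n_units = 100, hidden = 120),
    "1Dx2-CNN" = model_spec("1Dx2-CNN", n_neurons, n_freq, n_units1 = 70,
                            n_units2 = 80, hidden = 100),
    "2D-CNN" = model_spec("2D-CNN", n_neurons, n_freq, n_conv_units = 10,
                          hidden = 90),
    abort(paste("unknown architecture:", architecture))
  )
}

# Template of parameter shapes per layer.
param_template <- function(layer) {
  switch(layer$type,
    gauss = list(mu = layer$n_units, sigma = layer$n_units),
    conv = list(taps = c(layer$n_units, layer$n_taps)),
    relu = list(offset = layer$n_units),
    mix = list(W = c(layer$n_out, layer$n_in)),
    scale = list(w = layer$n_units),
    bias = list(b = layer$n_units),
    conv2d = list(K = c(layer$n_units, layer$n_in, layer$kf, layer$kt)),
    dexp = list(b = layer$n_units, a = layer$n_units,
                s = layer$n_units, k = layer$n_units),
    list()
  )
}

n_layer_params <- function(layer) {
  sum(vapply(param_template(layer), prod, numeric(1)))
}

#' Flatten model parameters to a vector
#'
#' @param spec A `model_spec`.
#' @param params Per-layer parameter list, as produced by
#'   [initialize_params()].
#' @return Numeric vector of all trainable values in declaration order.
#' @export
pack_params <- function(spec, params) {
  out <- numeric(0)
  for (i in seq_along(spec$layers)) {
    tpl <- param_template(spec$layers[[i]])
    for (nm in names(tpl)) out <- c(out, as.numeric(params[[i]][[nm]]))
  }
  out
}

#' Rebuild per-layer parameters from a flat vector
#'
#' @param spec A `model_spec`.
#' @param vec Numeric vector of length `count_parameters(spec)$total_all`.
#' @return Per-layer parameter list.
#' @export
unpack_params <- function(spec, vec) {
  params <- vector("list", length(spec$layers))
  pos <- 0L
  for (i in seq_along(spec$layers)) {
    tpl <- param_template(spec$layers[[i]])
    pl <- list()
    for (nm in names(tpl)) {
      len <- prod(tpl[[nm]])
      v <- vec[pos + seq_len(len)]
      pl[[nm]] <- if (length(tpl[[nm]]) > 1) array(v, tpl[[nm]]) else v
      pos <- pos + len
    }
    params[[i]] <- pl
  }
  if (pos != length(vec)) abort("parameter vector length does not match spec")
  params
}

# Box constraints for the flat parameter vector: Gaussian widths are floored
# at 0.25 channels and centers limited to [-2, F+1] (slightly outside the
# channel range, for edge-tuned units).
param_bounds <- function(spec) {
  lower <- numeric(0); upper <- numeric(0)
  for (layer in spec$layers) {
    tpl <- param_template(layer)
    for (nm in names(tpl)) {
      len <- prod(tpl[[nm]])
      lo <- rep(-Inf, len); hi <- rep(Inf, len)
      if (layer$type == "gauss" && nm == "mu") {
        lo <- rep(-2, len); hi <- rep(layer$n_freq + 1, len)
      }
      if (layer$type == "gauss" && nm == "sigma") lo <- rep(0.25, len)
      lower <- c(lower, lo); upper <- c(upper, hi)
    }
  }
  list(lower = lower, upper = upper)
}

#' Count trainable parameters
#'
#' Counts trainable values per layer: 2 per Gaussian spectral unit (center
#' and width), one value per FIR tap, fan-in per dense unit, the full kernel
#' per 2D convolutional unit, 1 per offset-ReLU unit and 4 per output
#' nonlinearity. With `count_offsets = FALSE` (the default headline
#' convention) the activation offsets of the spectrogram-facing
#' convolutional layer are not counted; the breakdown always reports both
#' conventions.
#'
#' @param spec A `model_spec`.
#' @param count_offsets Include first-convolutional-layer activation offsets
#'   in the total (default `FALSE`).
#' @return List with `total` (headline convention), `total_all` (every
#'   trainable value; always equals the packed parameter-vector length) and
#'   a `breakdown` tibble (layer, type, n_params, n_params_all).
#' @export
count_parameters <- function(spec, count_offsets = FALSE) {
  types <- vapply(spec$layers, `[[`, character(1), "type")
  first_conv <- which(types %in% c("conv", "conv2d"))[1]
  # the activation directly following the first convolutional layer
  first_relu <- NA_integer_
  if (!is.na(first_conv)) {
    cand <- which(types == "relu")
    cand <- cand[cand > first_conv]
    if (length(cand) > 0 && types[first_conv] == "conv2d") first_relu <- cand[1]
    if (length(cand) > 0 && types[first_conv] == "conv" &&
        cand[1] <= first_conv + 1) first_relu <- cand[1]
  }
  n_all <- vapply(spec$layers, n_layer_params, numeric(1))
  n_conv <- n_all
  if (!count_offsets && !is.na(first_relu)) n_conv[first_relu] <- 0
  breakdown <- tibble::tibble(
    layer = seq_along(types), type = types,
    n_params = n_conv, n_params_all = n_all
  )
  list(total = sum(n_conv), total_all = sum(n_all), breakdown = breakdown)
}

# Per-role initialization distributions. Random draws for entries
# 1..n_init-1; the final entry is the mean of each distribution. `rate_scale`
# sets the firing-rate scale of the output nonlinearity (b ~ U(0, r),
# a ~ U(0, 4r)); weights are zero-mean with ~1/sqrt(fan-in) spread.
draw_layer_params <- function(layer, mean_init = FALSE, rate_scale = 1) {
  rn <- function(n, sd) if (mean_init) rep(0, n) else rnorm(n, 0, sd)
  switch(layer$type,
    gauss = {
      nf <- layer$n_freq; u <- layer$n_units
      list(mu = if (mean_init) rep((nf - 1) / 2, u) else runif(u, 0, nf - 1),
           sigma = if (mean_init) rep(2, u) else runif(u, 0.5, 3.5))
    },
    conv = list(taps = matrix(rn(layer$n_units * layer$n_taps,
                                 1 / sqrt(layer$n_taps)),
                              layer$n_units, layer$n_taps)),
    relu = list(offset = rn(layer$n_units, 0.1)),
    mix = list(W = matrix(rn(layer$n_out * layer$n_in, 1 / sqrt(layer$n_in)),
                          layer$n_out, layer$n_in)),
    scale = list(w = if (mean_init) rep(1, layer$n_units)
                     else rnorm(layer$n_units, 1, 0.1)),
    bias = list(b = rn(layer$n_units, 0.1)),
    conv2d = list(K = array(rn(layer$n_units * layer$n_in * layer$kf * layer$kt,
                               1 / sqrt(layer$n_in * layer$kf * layer$kt)),
                            c(layer$n_units, layer$n_in, layer$kf, layer$kt))),
    dexp = {
      u <- layer$n_units
      list(b = if (mean_init) rep(rate_scale / 2, u) else runif(u, 0, rate_scale),
           a = if (mean_init) rep(2 * rate_scale, u) else runif(u, 0, 4 * rate_scale),
           s = rn(u, 1),
           k = if (mean_init) rep(1, u) else runif(u, 0.5, 1.5))
    },
    list()
  )
}

#' Initialize model parameters
#'
#' Draws `n_init - 1` random parameter sets from documented per-role
#' distributions and appends one deterministic set equal to the mean of
#' every distribution (the final entry). With `n_init = 1` only the mean
#' initialization is returned.
#'
#' @param spec A `model_spec`.
#' @param n_init Number of initializations (default 10).
#' @param seed RNG seed; draws are reproducible and the mean entry is
#'   seed-independent.
#' @param rate_scale Firing-rate scale (spikes/s) for the output
#'   nonlinearity's baseline/amplitude distributions (default 1).
#' @return List of `n_init` per-layer parameter lists.
#' @export
initialize_params <- function(spec, n_init = 10, seed = 1, rate_scale = 1) {
  if (n_init < 1) abort("n_init must be at least 1")
  with_seed(seed, {
    out <- vector("list", n_init)
    if (n_init > 1) {
      for (i in seq_len(n_init - 1)) {
        out[[i]] <- lapply(spec$layers, draw_layer_params,
                           mean_init = FALSE, rate_scale = rate_scale)
      }
    }
    out[[n_init]] <- lapply(spec$layers, draw_layer_params,
                            mean_init = TRUE, rate_scale = rate_scale)
    out
  })
}
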