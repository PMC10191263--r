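# Forward and backward passes through a layer sequence.

as_stim_matrix <- function(stim) {
  if (inherits(stim, "spectrogram")) {
    list(X = stim$values, starts = stim$snippet_starts)
  } else {
    list(X = as.matrix(stim), starts = 1L)
  }
}

# Index of the first output layer: the final dense readout when present,
# otherwise the output nonlinearity (batched LN, whose readout is the fixed
# group sum).
output_layer_start <- function(spec) {
  types <- vapply(spec$layers, `[[`, character(1), "type")
  k <- length(types)
  stopifnot(types[k] == "dexp")
  if (k > 1 && types[k - 1] == "mix") k - 1L else k
}

model_forward_layers <- function(layers, params, X, starts,
                                 keep_cache = FALSE, linear_output = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    if (linear_output && layers[[i]]$type == "dexp") {
      if (keep_cache) caches[i] <- list(NULL)
      next
    }
    fw <- layer_forward(layers[[i]], params[[i]], X, starts)
    X <- fw$out
    if (keep_cache) caches[i] <- list(fw$cache)
  }
  list(out = X, caches = caches)
}

#' Deterministic forward pass of a model
#'
#' @param spec A [model_spec()].
#' @param params Per-layer parameter list consistent with `spec`.
#' @param stim A [spectrogram] or plain `F x T` matrix.
#' @param linear_output Skip the output nonlinearity (test hook; returns the
#'   linear drive of the output units).
#' @return `N x T` matrix of predicted rates.
#' @export
model_forward <- function(spec, params, stim, linear_output = FALSE) {
  if (length(params) != length(spec$layers))
    abort("params must have one entry per spec layer")
  sm <- as_stim_matrix(stim)
  if (nrow(sm$X) != spec$n_freq)
    abort("stimulus channel count does not match spec n_freq")
  out <- model_forward_layers(spec$layers, params, sm$X, sm$starts,
                              linear_output = linear_output)$out
  out
}

# Backward pass: returns per-layer parameter gradients (same shapes as
# params). `frozen` marks layer indices whose parameter gradients are not
# needed (input gradients still propagate through them).
model_backward_layers <- function(layers, params, caches, dY, starts,
                                  frozen = integer(0)) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (is.null(caches[[i]]) && layers[[i]]$type == "dexp") {
      grads[i] <- list(NULL) # linear-output hook skipped this layer
      next
    }
    need_dx <- i > 1
    bw <- layer_backward(layers[[i]], params[[i]], caches[[i]], dY, starts,
                         need_dx = need_dx)
    grads[i] <- list(if (i %in% frozen) NULL else bw$dpars)
    if (need_dx) dY <- bw$dX
  }
  grads
}

#' Rank-factorized LN model forward pass
#'
#' The linear stage convolves the spectrogram with a rank-D filter
#' `h = sum_d g_d (outer) taps_d`, where each spectral factor `g_d` is a
#' Gaussian over channel index; the output nonlinearity is the double
#' exponential. Convolution is causal with zero-padding before stimulus
#' (and snippet) onset.
#'
#' @param stim A [spectrogram] or `F x T` matrix.
#' @param spectral List with vectors `mu`, `sigma` (length D, 0-based
#'   channel-index units).
#' @param temporal `D x U` matrix of temporal filter taps.
#' @param out_nl List with scalars `b`, `a`, `s`, `k`, or `NULL` to return
#'   the linear drive `r_lin`.
#' @return Numeric vector of length T.
#' @export
ln_forward <- function(stim, spectral, temporal, out_nl = NULL) {
  sm <- as_stim_matrix(stim)
  D <- length(spectral$mu)
  if (nrow(temporal) != D) abort("temporal must have one row per rank component")
  W <- gauss_weights(spectral$mu, spectral$sigma, nrow(sm$X))
  Z <- cc_conv1d(W %*% sm$X, temporal, sm$starts)
  r_lin <- colSums(Z)
  if (is.null(out_nl)) return(r_lin)
  as.numeric(double_exponential(r_lin, out_nl$b, out_nl$a, out_nl$s, out_nl$k))
}

#' Population model forward pass
#'
#' Shared layers are computed once; each output unit applies a dense
#' weighting over the final hidden layer followed by its own double
#' exponential nonlinearity.
#'
#' @inheritParams model_forward
#' @return `N x T` matrix of predicted rates, rows named by output index.
#' @export
population_forward <- function(stim, spec, params) {
  model_forward(spec, params, stim)
}
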