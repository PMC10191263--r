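# Layer primitives: each has a forward pass returning (out, cache) and a
# backward pass mapping dL/dout to (dL/din, dL/dparams). Parameters are kept
# as named lists per layer; `starts` carries stimulus-snippet boundaries so
# temporal convolutions are causal within each snippet.

gauss_weights <- function(mu, sigma, n_freq) {
  j <- seq_len(n_freq) - 1 # 0-based channel indices
  W <- exp(-(outer(mu, j, "-"))^2 / (2 * sigma^2))
  W
}

layer_forward <- function(layer, pars, X, starts) {
  switch(layer$type,
    gauss = {
      W <- gauss_weights(pars$mu, pars$sigma, layer$n_freq)
      list(out = W %*% X, cache = list(X = X, W = W))
    },
    conv = {
      list(out = cc_conv1d(X, pars$taps, starts), cache = list(X = X))
    },
    relu = {
      Xs <- X - pars$offset # offset recycles over the unit (first) dimension
      mask <- Xs > 0
      list(out = Xs * mask, cache = list(mask = mask))
    },
    mix = {
      list(out = pars$W %*% X, cache = list(X = X))
    },
    scale = {
      list(out = X * pars$w, cache = list(X = X))
    },
    bias = {
      list(out = X + pars$b, cache = NULL)
    },
    sumgroups = {
      out <- rowsum(X, layer$groups, reorder = TRUE)
      list(out = out, cache = NULL)
    },
    expand2d = {
      list(out = array(X, c(1L, nrow(X), ncol(X))), cache = NULL)
    },
    conv2d = {
      list(out = cc_conv2d(X, pars$K, starts), cache = list(X = X))
    },
    flatten2d = {
      d <- dim(X)
      Y <- X
      dim(Y) <- c(d[1] * d[2], d[3])
      list(out = Y, cache = list(d = d))
    },
    dexp = {
      z <- pmin(pmax(pars$k * (X - pars$s), -30), 30)
      e1 <- exp(z)
      E <- exp(-e1)
      list(out = pars$b + pars$a * E,
           cache = list(X = X, e1 = e1, E = E))
    },
    abort(paste("unknown layer type:", layer$type))
  )
}

layer_backward <- function(layer, pars, cache, dY, starts, need_dx = TRUE) {
  switch(layer$type,
    gauss = {
      W <- cache$W
      X <- cache$X
      dW <- tcrossprod(dY, X)
      j <- seq_len(layer$n_freq) - 1
      dev <- -outer(pars$mu, j, "-") # (j - mu), rows = units
      gWd <- dW * W
      dmu <- rowSums(gWd * dev) / pars$sigma^2
      dsigma <- rowSums(gWd * dev^2) / pars$sigma^3
      list(dX = if (need_dx) crossprod(W, dY) else NULL,
           dpars = list(mu = dmu, sigma = dsigma))
    },
    conv = {
      list(dX = if (need_dx) cc_conv1d_grad_x(dY, pars$taps, starts) else NULL,
           dpars = list(taps = cc_conv1d_grad_taps(dY, cache$X, starts,
                                                   ncol(pars$taps))))
    },
    relu = {
      dM <- dY * cache$mask
      doff <- if (is.matrix(dM)) -rowSums(dM)
              else -rowSums(matrix(dM, dim(dM)[1]))
      list(dX = dM, dpars = list(offset = doff))
    },
    mix = {
      list(dX = if (need_dx) crossprod(pars$W, dY) else NULL,
           dpars = list(W = tcrossprod(dY, cache$X)))
    },
    scale = {
      list(dX = dY * pars$w, dpars = list(w = rowSums(dY * cache$X)))
    },
    bias = {
      list(dX = dY, dpars = list(b = rowSums(dY)))
    },
    sumgroups = {
      list(dX = if (need_dx) dY[layer$groups, , drop = FALSE] else NULL,
           dpars = NULL)
    },
    expand2d = {
      d <- dim(dY)
      dX <- dY
      dim(dX) <- c(d[2], d[3])
      list(dX = dX, dpars = NULL)
    },
    conv2d = {
      d <- dim(cache$X)
      list(dX = if (need_dx)
             cc_conv2d_grad_a(dY, pars$K, starts, d[1], d[2], d[3]) else NULL,
           dpars = list(K = cc_conv2d_grad_k(dY, cache$X, starts,
                                             dim(pars$K)[1], dim(pars$K)[2],
                                             dim(pars$K)[3], dim(pars$K)[4])))
    },
    flatten2d = {
      dX <- dY
      dim(dX) <- cache$d
      list(dX = dX, dpars = NULL)
    },
    dexp = {
      e1E <- cache$e1 * cache$E
      ak <- pars$a * pars$k
      list(dX = -dY * ak * e1E,
           dpars = list(b = rowSums(dY),
                        a = rowSums(dY * cache$E),
                        s = rowSums(dY * ak * e1E),
                        k = rowSums(-dY * pars$a * e1E * (cache$X - pars$s))))
    },
    abort(paste("unknown layer type:", layer$type))
  )
}

#' Double exponential output nonlinearity
#'
#' The saturating output nonlinearity applied per neuron:
#' `r = b + a * exp(-exp(k * (y - s)))`, with baseline rate `b`, saturation
#' amplitude `a`, firing threshold `s` and gain `k`. The inner exponent is
#' clipped to avoid numeric overflow; the function is otherwise exact.
#'
#' @param y Numeric vector or matrix of linear drive values.
#' @param b,a,s,k Nonlinearity parameters (scalars, or one per row of a
#'   matrix `y`).
#' @return Values of the same shape as `y`.
#' @export
double_exponential <- function(y, b, a, s, k) {
  z <- pmin(pmax(k * (y - s), -30), 30)
  b + a * exp(-exp(z))
}

#' One-dimensional convolutional layer
#'
#' Applies, per unit: a weighted sum over input channels, a causal temporal
#' FIR convolution, and (optionally) an offset rectified linearity. The
#' channel weighting is either an explicit weight matrix (deeper layers) or a
#' Gaussian over channel index parameterized by center and width (the
#' spectrogram-facing layer).
#'
#' @param inputs Channels x time numeric matrix.
#' @param weights Either a `units x channels` weight matrix, or a list with
#'   numeric vectors `mu` and `sigma` (Gaussian channel weighting, 0-based
#'   channel index units).
#' @param taps `units x n_taps` matrix of causal FIR coefficients.
#' @param offsets Per-unit ReLU offsets, or `NULL` for no activation (as in
#'   the population-LN convolutional layer).
#' @param starts 1-based start columns of independent stimulus snippets.
#' @return `units x time` matrix of layer outputs.
#' @export
conv1d_layer_forward <- function(inputs, weights, taps, offsets = NULL,
                                 starts = 1L) {
  if (is.list(weights)) {
    W <- gauss_weights(weights$mu, weights$sigma, nrow(inputs))
  } else {
    W <- weights
    if (ncol(W) != nrow(inputs)) abort("weight columns must match input channels")
  }
  if (nrow(taps) != nrow(W)) abort("taps rows must match unit count")
  Y <- cc_conv1d(W %*% inputs, taps, as.integer(starts))
  if (!is.null(offsets)) Y <- pmax(Y - offsets, 0)
  Y
}

#' Two-dimensional convolutional layer
#'
#' Joint spectro-temporal convolution: causal in time, centered and
#' zero-padded in frequency (the output keeps all frequency rows), summing
#' over all input channels, followed by an offset ReLU.
#'
#' @param inputs `channels x freq x time` numeric array (use a `1 x F x T`
#'   array for the spectrogram input).
#' @param kernels `units x channels x kf x kt` array of kernels (`kf` odd
#'   spectral span, `kt` causal temporal taps).
#' @param offsets Per-unit ReLU offsets, or `NULL` for no activation.
#' @param starts 1-based start columns of independent snippets.
#' @return `units x freq x time` array.
#' @export
conv2d_layer_forward <- function(inputs, kernels, offsets = NULL, starts = 1L) {
  if (length(dim(inputs)) != 3) abort("inputs must be a channels x freq x time array")
  if (dim(inputs)[2] < dim(kernels)[3])
    abort("input must have at least as many frequency rows as the kernel")
  Y <- cc_conv2d(inputs, kernels, as.integer(starts))
  if (!is.null(offsets)) Y <- pmax(Y - offsets, 0)
  Y
}
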