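#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model's parameters
#'
#' One row per trainable value, labelled by layer, layer type, unit and
#' role -- the flat parameter vector with its provenance.
#'
#' @param x An `strf_fit` (stage 1) from [fit_stage1()].
#' @param ... Unused.
#' @return Tibble with columns `layer`, `type`, `role`, `unit`, `estimate`.
#' @export
tidy.strf_fit <- function(x, ...) {
  if (x$stage != 1L)
    abort("tidy() is defined for stage-1 fits (stage-2 readouts are per neuron)")
  rows <- list()
  for (i in seq_along(x$spec$layers)) {
    ly <- x$spec$layers[[i]]
    tpl <- param_template(ly)
    for (nm in names(tpl)) {
      vals <- as.numeric(x$params[[i]][[nm]])
      n_units <- if (length(tpl[[nm]]) > 1) tpl[[nm]][1] else tpl[[nm]]
      unit <- if (length(tpl[[nm]]) > 1)
        rep(seq_len(n_units), times = prod(tpl[[nm]]) / n_units)
      else seq_len(n_units)
      rows[[length(rows) + 1]] <- tibble::tibble(
        layer = i, type = ly$type, role = nm, unit = unit, estimate = vals)
    }
  }
  dplyr::bind_rows(rows)
}

#' One-row fit summary
#'
#' @param x An `strf_fit`.
#' @param ... Unused.
#' @return Tibble with architecture, neuron and parameter counts, the
#'   chosen initialization, early-stop loss and epochs run.
#' @export
glance.strf_fit <- function(x, ...) {
  if (x$stage == 2L) {
    return(tibble::tibble(
      architecture = x$spec$architecture, stage = 2L,
      n_neurons = length(x$neuron_ids),
      es_loss = median(x$neurons$es_loss),
      epochs = sum(x$neurons$epochs)))
  }
  cp <- count_parameters(x$spec)
  tibble::tibble(
    architecture = x$spec$architecture, stage = 1L,
    n_neurons = x$spec$n_neurons,
    n_params = cp$total, n_params_all = cp$total_all,
    chosen_init = x$chosen_init, n_failed_inits = length(x$failed_inits),
    es_loss = x$es_loss, epochs = nrow(x$traces$stepC))
}

#' Reconstruct the effective spectro-temporal filter of an LN model
#'
#' The outer-product filter `h = sum_d g_d (outer) taps_d` implied by a
#' rank-factorized parameterization.
#'
#' @param spectral List with `mu`, `sigma` vectors (length D).
#' @param temporal `D x U` taps matrix.
#' @param n_freq Channel count.
#' @return `n_freq x U` filter matrix.
#' @export
ln_filter <- function(spectral, temporal, n_freq = 18) {
  W <- gauss_weights(spectral$mu, spectral$sigma, n_freq)
  t(W) %*% temporal
}
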