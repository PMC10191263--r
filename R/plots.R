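#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_abline geom_boxplot scale_fill_viridis_c labs facet_wrap
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a spectrogram
#'
#' @param object A [spectrogram].
#' @param ... Unused.
#' @return A ggplot heat map (time vs log-spaced channel, fill = level).
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tibble::tibble(
    time = rep((seq_len(ncol(object$values)) - 1) * object$bin_size,
               each = nrow(object$values)),
    channel = rep(seq_len(nrow(object$values)), ncol(object$values)),
    level = as.numeric(object$values))
  ggplot(df, aes(x = .data$time, y = .data$channel, fill = .data$level)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "frequency channel", fill = "level") +
    theme_minimal()
}

#' Plot per-neuron scores for one or more models
#'
#' @param object Score tibble from [score_models()].
#' @param ... Unused.
#' @return A ggplot: noise-corrected prediction correlation per model.
#' @export
autoplot.tbl_scores <- function(object, ...) {
  ggplot(object, aes(x = .data$model_id, y = .data$r_norm)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(position = ggplot2::position_jitter(width = 0.15), alpha = 0.5) +
    labs(x = NULL, y = "prediction correlation (noise-corrected)") +
    theme_minimal()
}

#' Scatter comparison of two models' per-neuron scores
#'
#' @param scores Score tibble covering both models.
#' @param model_x,model_y Model ids to compare.
#' @param value Score column (default `"r_norm"`).
#' @return A ggplot with the identity line.
#' @export
plot_score_comparison <- function(scores, model_x, model_y, value = "r_norm") {
  wide <- dplyr::inner_join(
    scores[scores$model_id == model_x, c("neuron_id", value)],
    scores[scores$model_id == model_y, c("neuron_id", value)],
    by = "neuron_id", suffix = c("_x", "_y"))
  ggplot(wide, aes(x = .data[[paste0(value, "_x")]],
                   y = .data[[paste0(value, "_y")]])) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = model_x, y = model_y) +
    theme_minimal()
}

#' Plot an LN spectro-temporal filter
#'
#' @param filter `F x U` filter matrix (see [ln_filter()]).
#' @param bin_size Time-bin width in seconds.
#' @return A ggplot heat map (lag vs channel).
#' @export
plot_strf <- function(filter, bin_size = 0.010) {
  df <- tibble::tibble(
    lag = rep((seq_len(ncol(filter)) - 1) * bin_size, each = nrow(filter)),
    channel = rep(seq_len(nrow(filter)), ncol(filter)),
    weight = as.numeric(filter))
  ggplot(df, aes(x = .data$lag, y = .data$channel, fill = .data$weight)) +
    geom_raster() +
    ggplot2::scale_fill_gradient2() +
    labs(x = "lag (s)", y = "frequency channel", fill = "weight") +
    theme_minimal()
}

#' Plot subsampling performance curves
#'
#' @param object A `subsample_result` from [run_subsample()].
#' @param ... Unused.
#' @return A ggplot of median normalized performance vs data fraction.
#' @export
autoplot.subsample_result <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$fraction, y = .data$median_r_norm,
             colour = .data$arm)) +
    geom_line() + geom_point() +
    labs(x = "fraction of estimation data", y = "median prediction correlation",
         colour = NULL) +
    theme_minimal()
}
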