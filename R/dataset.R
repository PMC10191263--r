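#' Paired stimulus/response dataset
#'
#' Bundles an estimation set (typically single-repeat responses to many
#' stimulus snippets) and a validation set (many repeats of a disjoint
#' snippet set) with aligned time axes.
#'
#' @param est_stim,val_stim [spectrogram] objects (concatenated snippets).
#' @param est_raster,val_raster [trial_raster] objects whose time axes
#'   match the corresponding stimulus and whose neurons agree.
#' @param truth Optional ground-truth population (synthetic data).
#' @param meta Optional named list of provenance (seeds, generator
#'   settings).
#' @return An object of class `strf_dataset`.
#' @export
strf_dataset <- function(est_stim, est_raster, val_stim, val_raster,
                         truth = NULL, meta = list()) {
  stopifnot(inherits(est_stim, "spectrogram"), inherits(val_stim, "spectrogram"),
            inherits(est_raster, "trial_raster"), inherits(val_raster, "trial_raster"))
  if (ncol(est_stim$values) != dim(est_raster)[2])
    abort("estimation stimulus and response time axes do not align")
  if (ncol(val_stim$values) != dim(val_raster)[2])
    abort("validation stimulus and response time axes do not align")
  if (!identical(est_raster$neuron_ids, val_raster$neuron_ids))
    abort("estimation and validation rasters must contain the same neurons")
  structure(list(est_stim = est_stim, est_raster = est_raster,
                 val_stim = val_stim, val_raster = val_raster,
                 truth = truth, meta = meta),
            class = "strf_dataset")
}

#' @export
print.strf_dataset <- function(x, ...) {
  cat(sprintf(
    "<strf_dataset> %d neurons (%d sites); est: %d snippets x %d bins (M=%d); val: %d snippets x %d bins (M=%d)%s\n",
    dim(x$est_raster)[1], length(unique(x$est_raster$site_ids)),
    length(x$est_stim$snippet_starts), dim(x$est_raster)[2], dim(x$est_raster)[3],
    length(x$val_stim$snippet_starts), dim(x$val_raster)[2], dim(x$val_raster)[3],
    if (!is.null(x$truth)) "; ground truth attached" else ""))
  invisible(x)
}

#' Keep a subset of neurons
#'
#' @param dataset An [strf_dataset()].
#' @param ids Neuron ids to keep (order preserved as given).
#' @return A new `strf_dataset` physically lacking the other neurons.
#' @export
dataset_subset_neurons <- function(dataset, ids) {
  ix <- match(ids, dataset$est_raster$neuron_ids)
  if (anyNA(ix)) abort("unknown neuron ids")
  sub <- function(r) trial_raster(r$rates[ix, , , drop = FALSE], r$bin_size,
                                  r$neuron_ids[ix], r$site_ids[ix])
  strf_dataset(dataset$est_stim, sub(dataset$est_raster),
               dataset$val_stim, sub(dataset$val_raster),
               truth = dataset$truth, meta = dataset$meta)
}

#' Keep a subset of estimation snippets
#'
#' Used by the data-subsampling protocol: retains the selected estimation
#' snippets (stimulus columns and response bins) and leaves the validation
#' set untouched.
#'
#' @param dataset An [strf_dataset()].
#' @param idx Estimation snippet indices to keep.
#' @return A new `strf_dataset`.
#' @export
dataset_subset_est_snippets <- function(dataset, idx) {
  st <- dataset$est_stim
  n <- length(st$snippet_starts)
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1 | idx > n)) abort("snippet index out of range")
  sc <- snippet_columns(st$snippet_starts, ncol(st$values), idx)
  new_stim <- spectrogram(st$values[, sc$cols, drop = FALSE], st$center_freqs,
                          st$bin_size, sc$starts)
  r <- dataset$est_raster
  new_raster <- trial_raster(r$rates[, sc$cols, , drop = FALSE], r$bin_size,
                             r$neuron_ids, r$site_ids)
  strf_dataset(new_stim, new_raster, dataset$val_stim, dataset$val_raster,
               truth = dataset$truth, meta = dataset$meta)
}
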