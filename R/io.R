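# On-disk containers. A dataset is stored as a directory: `meta.json` holds
# the schema version, shapes and identifiers; numeric arrays are raw
# little-endian float64 `.bin` files (endianness forced, so containers are
# portable across platforms and round-trip bitwise).

DATASET_SCHEMA <- "popstrf-dataset-1"
MODEL_SCHEMA <- "popstrf-model-1"

write_array_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_array_bin <- function(path, dims) {
  n <- prod(dims)
  info <- file.info(path)
  if (is.na(info$size) || info$size != n * 8)
    abort(sprintf("array file %s has %s bytes, expected %d (truncated or corrupt container)",
                  basename(path), format(info$size), n * 8))
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(dims) > 1) dim(x) <- dims
  x
}

#' Write a dataset container
#'
#' Serializes an [strf_dataset()] to a directory: `meta.json` (schema
#' version, shapes, bin sizes, neuron/site ids, snippet starts, provenance)
#' plus little-endian float64 arrays. Round-trips are bitwise lossless.
#'
#' @param dataset An [strf_dataset()].
#' @param path Directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "strf_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema = DATASET_SCHEMA,
    est_stim = list(dim = dim(dataset$est_stim$values),
                    bin_size = dataset$est_stim$bin_size,
                    snippet_starts = dataset$est_stim$snippet_starts,
                    center_freqs = dataset$est_stim$center_freqs),
    val_stim = list(dim = dim(dataset$val_stim$values),
                    bin_size = dataset$val_stim$bin_size,
                    snippet_starts = dataset$val_stim$snippet_starts,
                    center_freqs = dataset$val_stim$center_freqs),
    est_raster = list(dim = dim(dataset$est_raster),
                      bin_size = dataset$est_raster$bin_size),
    val_raster = list(dim = dim(dataset$val_raster),
                      bin_size = dataset$val_raster$bin_size),
    neuron_ids = dataset$est_raster$neuron_ids,
    site_ids = dataset$est_raster$site_ids,
    meta = dataset$meta
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_array_bin(dataset$est_stim$values, file.path(path, "est_stim.bin"))
  write_array_bin(dataset$val_stim$values, file.path(path, "val_stim.bin"))
  write_array_bin(dataset$est_raster$rates, file.path(path, "est_raster.bin"))
  write_array_bin(dataset$val_raster$rates, file.path(path, "val_raster.bin"))
  invisible(path)
}

#' Read a dataset container
#'
#' @param path Directory written by [write_dataset()].
#' @return An [strf_dataset()] (bitwise equal to the one written). The
#'   ground-truth attachment, if any, is not serialized.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) abort(paste("not a dataset container (no meta.json):", path))
  meta <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE),
                   error = function(e) abort(paste("corrupt meta.json:", conditionMessage(e))))
  if (!identical(meta$schema, DATASET_SCHEMA))
    abort(sprintf("dataset schema mismatch: found '%s', expected '%s'",
                  meta$schema, DATASET_SCHEMA))
  stim <- function(group, file) {
    spectrogram(read_array_bin(file.path(path, file), group$dim),
                center_freqs = group$center_freqs, bin_size = group$bin_size,
                snippet_starts = group$snippet_starts)
  }
  est_stim <- stim(meta$est_stim, "est_stim.bin")
  val_stim <- stim(meta$val_stim, "val_stim.bin")
  est_raster <- trial_raster(read_array_bin(file.path(path, "est_raster.bin"),
                                            meta$est_raster$dim),
                             meta$est_raster$bin_size, meta$neuron_ids, meta$site_ids)
  val_raster <- trial_raster(read_array_bin(file.path(path, "val_raster.bin"),
                                            meta$val_raster$dim),
                             meta$val_raster$bin_size, meta$neuron_ids, meta$site_ids)
  strf_dataset(est_stim, est_raster, val_stim, val_raster,
               meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Save a model (spec + parameters)
#'
#' Writes the architecture description as JSON and the flat parameter
#' vector as little-endian float64, so a reload reproduces predictions
#' bitwise.
#'
#' @param spec A [model_spec()].
#' @param params Per-layer parameter list.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
save_model <- function(spec, params, path) {
  vec <- pack_params(spec, params)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema = MODEL_SCHEMA,
               architecture = spec$architecture, n_neurons = spec$n_neurons,
               n_freq = spec$n_freq, rank = spec$rank,
               layers = spec$layers, n_params = length(vec))
  jsonlite::write_json(meta, file.path(path, "spec.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_array_bin(vec, file.path(path, "params.bin"))
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path Model directory.
#' @return List with `spec` and `params`; an integrity error is raised if
#'   the parameter vector does not match the spec.
#' @export
load_model <- function(path) {
  mf <- file.path(path, "spec.json")
  if (!file.exists(mf)) abort(paste("not a model container:", path))
  # no vector simplification: the layer list must stay a list of records
  meta <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(meta$schema, MODEL_SCHEMA))
    abort(sprintf("model schema mismatch: found '%s'", meta$schema))
  args <- list(architecture = meta$architecture, n_neurons = meta$n_neurons,
               n_freq = meta$n_freq)
  if (!is.null(meta$rank)) args$rank <- meta$rank
  # rebuild the spec from the serialized layer list to preserve exact sizes
  spec <- do.call(model_spec, c(args, spec_size_args(meta)))
  expected <- count_parameters(spec, count_offsets = TRUE)$total
  vec <- read_array_bin(file.path(path, "params.bin"), as.integer(meta$n_params))
  if (length(vec) != expected)
    abort(sprintf("model integrity error: %d parameters on disk, spec implies %d",
                  length(vec), expected))
  list(spec = spec, params = unpack_params(spec, vec))
}

# Recover model_spec size arguments from serialized layer metadata.
spec_size_args <- function(meta) {
  ly <- meta$layers
  types <- vapply(ly, function(l) l$type, character(1))
  get <- function(i, f) ly[[i]][[f]]
  switch(meta$architecture,
    "LN" = list(n_taps = get(which(types == "conv")[1], "n_taps")),
    "single-CNN" = ,
    "pop-LN" = list(n_units = get(1, "n_units"), n_taps = get(2, "n_taps")),
    "1D-CNN" = list(n_units = get(1, "n_units"), n_taps = get(2, "n_taps"),
                    hidden = get(4, "n_out")),
    "1Dx2-CNN" = list(n_units1 = get(1, "n_units"), n_taps1 = get(2, "n_taps"),
                      n_units2 = get(4, "n_out"), n_taps2 = get(5, "n_taps"),
                      hidden = get(7, "n_out")),
    "2D-CNN" = list(n_conv_units = get(2, "n_units"), kf = get(2, "kf"),
                    kt = get(2, "kt"), hidden = get(9, "n_out")),
    list()
  )
}
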