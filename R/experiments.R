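# Generalization protocols: pre-train shared layers on one population, then
# refit only per-neuron readouts, under several exclusion schemes.

#' Plan a held-out-site protocol
#'
#' All K neurons of one recording site are excluded from the stage-1
#' population fit; stage 2 then fits each excluded neuron's readout with
#' every earlier layer frozen.
#'
#' @param dataset An [strf_dataset()].
#' @param site Site label to hold out.
#' @return A `protocol_plan` (protocol, site, excluded neuron ids,
#'   stage-1 neuron ids).
#' @export
plan_heldout <- function(dataset, site) {
  sites <- dataset$est_raster$site_ids
  if (!site %in% sites) abort(paste("unknown site:", site))
  excluded <- dataset$est_raster$neuron_ids[sites == site]
  stage1 <- setdiff(dataset$est_raster$neuron_ids, excluded)
  if (length(stage1) == 0)
    abort("held-out protocol needs neurons outside the held-out site")
  structure(list(protocol = "heldout", site = site, excluded = excluded,
                 stage1 = stage1),
            class = "protocol_plan")
}

#' Plan a matched-exclusion control
#'
#' Excludes K off-site neurons whose baseline single-neuron LN prediction
#' scores are most similar to the K neurons of site S (greedy nearest-score
#' matching without replacement, site-S neurons visited in descending
#' score). The stage-1 population is the same size as in the held-out
#' protocol, but the site-S neurons themselves stay in it.
#'
#' @param dataset An [strf_dataset()].
#' @param site Site whose neurons define the score profile.
#' @param baseline_scores Named numeric vector of per-neuron baseline LN
#'   scores covering all neurons.
#' @return A `protocol_plan` with the matched excluded set.
#' @export
plan_matched <- function(dataset, site, baseline_scores) {
  sites <- dataset$est_raster$site_ids
  ids <- dataset$est_raster$neuron_ids
  if (!site %in% sites) abort(paste("unknown site:", site))
  if (!all(ids %in% names(baseline_scores)))
    abort("baseline_scores must cover every neuron")
  s_ids <- ids[sites == site]
  pool <- setdiff(ids, s_ids)
  if (length(pool) < length(s_ids))
    abort("fewer off-site neurons than site neurons to match")
  s_scores <- sort(baseline_scores[s_ids], decreasing = TRUE)
  excluded <- character(0)
  for (id in names(s_scores)) {
    cand <- setdiff(pool, excluded)
    pick <- cand[which.min(abs(baseline_scores[cand] - s_scores[[id]]))]
    excluded <- c(excluded, pick)
  }
  structure(list(protocol = "matched", site = site, excluded = excluded,
                 stage1 = setdiff(ids, excluded)),
            class = "protocol_plan")
}

#' @export
print.protocol_plan <- function(x, ...) {
  cat(sprintf("<protocol_plan> %s, site %s: %d excluded, %d in stage 1\n",
              x$protocol, x$site, length(x$excluded), length(x$stage1)))
  invisible(x)
}

# Resize a population spec to a new neuron count.
respec_n <- function(spec, n) {
  args <- list(architecture = spec$architecture, n_neurons = n,
               n_freq = spec$n_freq)
  ly <- spec$layers
  types <- vapply(ly, `[[`, character(1), "type")
  if (spec$architecture == "LN") {
    args$rank <- spec$rank
    args$n_taps <- ly[[which(types == "conv")[1]]]$n_taps
  } else if (spec$architecture == "pop-LN" || spec$architecture == "single-CNN") {
    args$n_units <- ly[[1]]$n_units
    args$n_taps <- ly[[2]]$n_taps
  } else if (spec$architecture == "1D-CNN") {
    args$n_units <- ly[[1]]$n_units
    args$n_taps <- ly[[2]]$n_taps
    args$hidden <- ly[[4]]$n_out
  } else if (spec$architecture == "1Dx2-CNN") {
    args$n_units1 <- ly[[1]]$n_units; args$n_taps1 <- ly[[2]]$n_taps
    args$n_units2 <- ly[[4]]$n_out; args$n_taps2 <- ly[[5]]$n_taps
    args$hidden <- ly[[7]]$n_out
  } else if (spec$architecture == "2D-CNN") {
    args$n_conv_units <- ly[[2]]$n_units; args$kf <- ly[[2]]$kf
    args$kt <- ly[[2]]$kt; args$hidden <- ly[[9]]$n_out
  }
  do.call(model_spec, args)
}

# Stage-2 readout fits are low-dimensional and cheap, so protocols give
# them a larger epoch budget than the shared-core fit.
readout_config <- function(config) {
  config$max_epochs <- max(config$max_epochs * 3L, 500L)
  config$patience <- max(config$patience * 2L, 30L)
  config
}

# One protocol arm: stage 1 on the plan's stage-1 population, stage 2 for
# the plan's target neurons, scored on validation data.
run_protocol_arm <- function(dataset, spec, config, plan, target_neurons) {
  ds1 <- dataset_subset_neurons(dataset, plan$stage1)
  spec1 <- respec_n(spec, length(plan$stage1))
  f1 <- fit_stage1(spec1, ds1, config)
  f2 <- fit_stage2(f1, dataset, readout_config(config), neurons = target_neurons)
  score_models(setNames(list(f2), paste0(plan$protocol, "-", plan$site)),
               dataset)
}

#' Held-out versus matched generalization protocol
#'
#' For every site: fit the shared layers once with that site's neurons
#' excluded (held-out) and once with a score-matched off-site set excluded
#' (matched control, same stage-1 population size), then refit only the
#' per-neuron readouts of the site's neurons and score them on validation
#' data. Equal held-out and matched performance indicates the shared
#' layers capture a population-general stimulus subspace rather than
#' neuron-specific tuning.
#'
#' @param dataset An [strf_dataset()].
#' @param spec Population [model_spec()] (neuron count is re-sized per
#'   protocol arm).
#' @param config A [fit_config()].
#' @param baseline_scores Named per-neuron baseline LN scores for matching
#'   (see [baseline_ln_scores()]).
#' @param sites Sites to iterate (default: all).
#' @return List of class `generalization_result`: `scores` (per neuron and
#'   arm) and `comparison` (paired signed-rank test of held-out vs matched
#'   r_norm).
#' @export
run_generalization <- function(dataset, spec, config, baseline_scores,
                               sites = NULL) {
  all_sites <- unique(dataset$est_raster$site_ids)
  if (is.null(sites)) sites <- all_sites
  rows <- list()
  for (s in sites) {
    for (arm in c("heldout", "matched")) {
      plan <- if (arm == "heldout") plan_heldout(dataset, s)
              else plan_matched(dataset, s, baseline_scores)
      target <- dataset$est_raster$neuron_ids[dataset$est_raster$site_ids == s]
      sc <- tryCatch(
        run_protocol_arm(dataset, spec, config, plan, target),
        error = function(e) {
          warn(sprintf("site %s %s arm failed: %s", s, arm, conditionMessage(e)))
          NULL
        })
      if (is.null(sc)) next
      sc$arm <- arm; sc$site <- s
      rows[[length(rows) + 1]] <- sc
    }
  }
  scores <- dplyr::bind_rows(rows)
  held <- scores[scores$arm == "heldout", ]
  mat <- scores[scores$arm == "matched", ]
  comparison <- compare_populations(held, mat, paired = TRUE)
  structure(list(scores = scores, comparison = comparison),
            class = "generalization_result")
}

#' Baseline per-neuron LN scores
#'
#' Fits independent rank-D LN models to every neuron (batched as one
#' population spec) and returns each neuron's noise-corrected prediction
#' correlation, used as the similarity key for matched exclusion.
#'
#' @param dataset An [strf_dataset()].
#' @param config A [fit_config()].
#' @param rank LN factorization rank (default 1).
#' @return Named numeric vector of per-neuron scores.
#' @export
baseline_ln_scores <- function(dataset, config, rank = 1) {
  n <- dim(dataset$est_raster)[1]
  spec <- model_spec("LN", n_neurons = n, rank = rank,
                     n_freq = nrow(dataset$est_stim$values))
  # no stage 2: batched LN models share no parameters, so the population
  # MSE decomposes exactly into the per-neuron losses stage 2 would optimize
  f1 <- fit_stage1(spec, dataset, config)
  sc <- score_models(list(ln = f1), dataset)
  # fall back to raw correlation where the ceiling is unstable
  v <- ifelse(is.na(sc$r_norm), sc$raw_r, sc$r_norm)
  setNames(ifelse(is.na(v), 0, v), sc$neuron_id)
}

#' Cross-population transfer protocol
#'
#' Pre-trains the shared layers on a source population (stage 1), then fits
#' only per-neuron readouts for the target population's neurons (stage 2)
#' and scores them on the target validation data. Both datasets must share
#' the same stimulus. With `source == target` this reduces exactly to the
#' held-out protocol.
#'
#' @param source_dataset,target_dataset [strf_dataset()] objects with
#'   identical stimuli.
#' @param spec Population [model_spec()].
#' @param config A [fit_config()].
#' @return Score tibble for the target neurons (arm `"cross"`).
#' @export
run_cross_population <- function(source_dataset, target_dataset, spec, config) {
  if (!isTRUE(all.equal(source_dataset$est_stim$values,
                        target_dataset$est_stim$values)))
    abort("source and target datasets must share the estimation stimulus")
  if (!isTRUE(all.equal(source_dataset$val_stim$values,
                        target_dataset$val_stim$values)))
    abort("source and target datasets must share the validation stimulus")
  src_ids <- source_dataset$est_raster$neuron_ids
  tgt_ids <- target_dataset$est_raster$neuron_ids
  overlap <- intersect(src_ids, tgt_ids)
  src_use <- setdiff(src_ids, overlap) # held-out reduction when source == target
  if (length(src_use) == 0 && length(overlap) > 0) {
    # full overlap: iterate sites as in the held-out protocol
    abort("source equals target; use run_generalization for the held-out protocol")
  }
  ds1 <- dataset_subset_neurons(source_dataset, src_use)
  spec1 <- respec_n(spec, length(src_use))
  f1 <- fit_stage1(spec1, ds1, config)
  f2 <- fit_stage2(f1, target_dataset, readout_config(config), neurons = tgt_ids)
  sc <- score_models(list(cross = f2), target_dataset)
  sc$arm <- "cross"
  sc
}

#' SNR-matched neuron subsets
#'
#' Selects the largest subsets of two populations whose binned SNR
#' distributions are identical: SNR values are histogrammed into shared
#' equal-width bins over the pooled range, and each side keeps the
#' `min(count_a, count_b)` highest-SNR neurons per bin (deterministic).
#'
#' @param snr_a,snr_b Named numeric vectors (neuron id -> SNR), or score
#'   tibbles with `neuron_id` and `snr` columns.
#' @param n_bins Number of shared histogram bins (default 20).
#' @return List with character vectors `a` and `b` of kept neuron ids.
#' @export
snr_matched_subsets <- function(snr_a, snr_b, n_bins = 20) {
  as_vec <- function(s) {
    if (is.numeric(s)) return(s)
    x <- s[!duplicated(s$neuron_id), ]
    setNames(x$snr, x$neuron_id)
  }
  a <- as_vec(snr_a); b <- as_vec(snr_b)
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  ba <- bin(a); bb <- bin(b)
  keep_a <- character(0); keep_b <- character(0)
  for (k in seq_len(n_bins)) {
    ia <- names(a)[ba == k]; ib <- names(b)[bb == k]
    m <- min(length(ia), length(ib))
    if (m == 0) next
    keep_a <- c(keep_a, ia[order(a[ia], decreasing = TRUE)][seq_len(m)])
    keep_b <- c(keep_b, ib[order(b[ib], decreasing = TRUE)][seq_len(m)])
  }
  if (length(keep_a) == 0) warn("no SNR overlap between populations; empty subsets")
  list(a = keep_a, b = keep_b)
}

#' Data-subsampling protocol: pre-trained versus standard fits
#'
#' For each fraction of the estimation data: the pre-trained arm fits the
#' shared layers on the full data with one site's neurons excluded, then
#' refits that site's readouts on the subsample only; the standard arm
#' fits both stages on the subsample alone. Subsamples are whole stimulus
#' snippets drawn uniformly (the same membership in both arms), nested so
#' smaller fractions are subsets of larger ones. Scores are reported for
#' the held-out site's neurons, with medians normalized to the standard
#' arm's full-data median.
#'
#' @param dataset An [strf_dataset()].
#' @param spec Population [model_spec()].
#' @param config A [fit_config()].
#' @param site Held-out site whose neurons are scored.
#' @param fractions Estimation-data fractions in (0, 1] (default
#'   `c(0.1, 0.25, 0.5, 1)`).
#' @param seed Seed for the subsample draw.
#' @return List of class `subsample_result`: `scores` (per neuron, arm and
#'   fraction) and `summary` (median r_norm per arm and fraction, raw and
#'   normalized).
#' @export
run_subsample <- function(dataset, spec, config, site,
                          fractions = c(0.1, 0.25, 0.5, 1), seed = 1) {
  if (any(fractions <= 0 | fractions > 1)) abort("fractions must be in (0, 1]")
  plan <- plan_heldout(dataset, site)
  target <- plan$excluded
  n_snip <- length(dataset$est_stim$snippet_starts)
  min_snip <- 5L
  perm <- with_seed(seed, sample.int(n_snip))
  # pre-trained shared layers: full estimation data, held-out site excluded
  ds1 <- dataset_subset_neurons(dataset, plan$stage1)
  spec1 <- respec_n(spec, length(plan$stage1))
  f_pre <- fit_stage1(spec1, ds1, config)
  rows <- list()
  for (fr in sort(fractions)) {
    n_keep <- floor(fr * n_snip)
    if (n_keep < min_snip) {
      warn(sprintf("fraction %.2f leaves %d snippets (< %d); skipped",
                   fr, n_keep, min_snip))
      next
    }
    sub <- dataset_subset_est_snippets(dataset, sort(perm[seq_len(n_keep)]))
    # pre-trained arm: stage 2 on the subsample only
    sc_pre <- tryCatch({
      f2 <- fit_stage2(f_pre, sub, readout_config(config), neurons = target)
      s <- score_models(list(pretrained = f2), dataset)
      s$arm <- "pretrained"; s$fraction <- fr; s
    }, error = function(e) { warn(conditionMessage(e)); NULL })
    # standard arm: both stages on the subsample
    sc_std <- tryCatch({
      g1 <- fit_stage1(respec_n(spec, dim(sub$est_raster)[1]), sub, config)
      g2 <- fit_stage2(g1, sub, readout_config(config), neurons = target)
      s <- score_models(list(standard = g2), dataset)
      s$arm <- "standard"; s$fraction <- fr; s
    }, error = function(e) { warn(conditionMessage(e)); NULL })
    rows <- c(rows, list(sc_pre), list(sc_std))
  }
  scores <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  summary <- dplyr::summarise(
    dplyr::group_by(scores, .data$arm, .data$fraction),
    median_r_norm = median(.data$r_norm, na.rm = TRUE), .groups = "drop")
  ref <- summary$median_r_norm[summary$arm == "standard" &
                               summary$fraction == max(summary$fraction)]
  if (length(ref) == 1 && is.finite(ref) && ref != 0)
    summary$normalized <- summary$median_r_norm / ref
  structure(list(scores = scores, summary = summary, site = site),
            class = "subsample_result")
}
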