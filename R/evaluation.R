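#' Trial-to-trial response correlation (TTRC)
#'
#' Mean Pearson correlation over all unordered pairs of distinct trials of
#' one neuron's response. TTRC estimates the reliability ceiling on raw
#' prediction correlation: for a signal with independent additive noise of
#' signal-variance fraction q, its expectation is q.
#'
#' Pairs involving a zero-variance trial are excluded (their correlation is
#' undefined) and counted in the `n_excluded` attribute; if every pair is
#' excluded the result is `NA`.
#'
#' @param raster_row `T x M` matrix: one neuron's response across `M >= 2`
#'   repeats.
#' @return Mean pairwise correlation (attribute `n_excluded` counts dropped
#'   pairs), or `NA` if undefined.
#' @export
ttrc <- function(raster_row) {
  x <- as.matrix(raster_row)
  M <- ncol(x)
  if (M < 2) abort("TTRC requires at least 2 repeats")
  sds <- apply(x, 2, sd)
  ok <- which(sds > 0)
  n_pairs <- M * (M - 1) / 2
  if (length(ok) < 2) {
    return(structure(NA_real_, n_excluded = n_pairs))
  }
  C <- cor(x[, ok, drop = FALSE])
  vals <- C[upper.tri(C)]
  n_used <- length(vals)
  structure(mean(vals), n_excluded = n_pairs - n_used)
}

#' Noise-corrected prediction correlation (R_norm)
#'
#' Mean correlation between the model prediction and each single-trial
#' response, normalized by the square root of the TTRC -- the reliability
#' ceiling of a single-trial correlation (for signal-variance fraction q,
#' a perfect prediction correlates with single trials at sqrt(q) while
#' TTRC estimates q). On noise-free data (identical trials) this equals
#' the raw Pearson correlation with the PSTH exactly; a prediction equal
#' to the true signal scores 1 in expectation at any noise level. Sampling
#' noise can push values slightly above 1; they are reported unclamped.
#'
#' @param raster_row `T x M` matrix of one neuron's repeats.
#' @param prediction Length-`T` predicted rate.
#' @param ttrc_floor Below this TTRC the normalization is unstable and `NA`
#'   is returned (default 0.05).
#' @return R_norm, or `NA` when undefined (constant prediction, undefined
#'   or too-small TTRC).
#' @export
noise_corrected_correlation <- function(raster_row, prediction,
                                        ttrc_floor = 0.05) {
  x <- as.matrix(raster_row)
  if (sd(prediction) == 0) return(NA_real_)
  tt <- ttrc(x)
  if (is.na(tt) || tt <= ttrc_floor) return(NA_real_)
  sds <- apply(x, 2, sd)
  ok <- which(sds > 0)
  rr <- vapply(ok, function(j) cor(x[, j], prediction), numeric(1))
  mean(rr) / sqrt(as.numeric(tt))
}

#' Model equivalence
#'
#' Pearson correlation between two models' predicted PSTHs for the same
#' neuron on validation data: a relative measure of how similarly two
#' models transform the stimulus.
#'
#' @param pred_a,pred_b Equal-length predicted rate vectors.
#' @return Correlation coefficient, or `NA` if either input is constant.
#' @export
equivalence <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) abort("predictions must have equal length")
  if (sd(pred_a) == 0 || sd(pred_b) == 0) return(NA_real_)
  cor(pred_a, pred_b)
}

#' Per-neuron signal-to-noise ratio (signal-variance fraction)
#'
#' Estimates the fraction of a neuron's response variance that is stimulus
#' signal rather than trial-to-trial noise, from the repeat-wise variance
#' decomposition: the PSTH variance is corrected for residual noise
#' (var_noise / M) and divided by the estimated total (signal + noise)
#' variance. Identical trials give 1; pure noise gives approximately 0.
#'
#' @param raster_row `T x M` matrix of one neuron's repeats (`M >= 2`).
#' @return SNR in `[0, 1]` (0 if the response has no variance).
#' @export
snr_fraction <- function(raster_row) {
  x <- as.matrix(raster_row)
  M <- ncol(x)
  if (M < 2) abort("SNR requires at least 2 repeats")
  m <- rowMeans(x)
  if (var(m) == 0 && all(apply(x, 2, var) == 0)) return(0)
  # unbiased per-bin noise variance from deviations around the PSTH
  noise_var <- sum((x - m)^2) / (nrow(x) * (M - 1))
  sig_var <- max(0, var(m) - noise_var / M)
  total <- sig_var + noise_var
  if (total <= 0) return(0)
  sig_var / total
}

# Contiguous time folds, reducing the fold count if any fold would be
# degenerate (shorter than 3 bins).
make_folds <- function(T, n_folds) {
  n_folds <- min(n_folds, floor(T / 3))
  if (n_folds < 2) abort("too few time bins for jackknife folds")
  split(seq_len(T), cut(seq_len(T), n_folds, labels = FALSE))
}

jackknife_t <- function(est) {
  K <- length(est)
  mb <- mean(est)
  se <- sqrt((K - 1) / K * sum((est - mb)^2))
  if (se == 0) return(list(t = NA_real_, p = 1))
  t <- mb / se
  list(t = t, p = 2 * pt(-abs(t), df = K - 1))
}

#' Jackknifed t-test for above-chance prediction
#'
#' Splits the validation PSTH into contiguous time folds, computes the
#' prediction correlation leaving each fold out, and tests the mean of the
#' leave-one-out estimates against zero with a jackknife t-statistic
#' (two-sided, `n_folds - 1` degrees of freedom). With `prediction_b`, the
#' paired version tests the per-fold difference in correlation between two
#' models.
#'
#' @param raster_row `T x M` matrix (or length-`T` PSTH vector) of the
#'   validation response.
#' @param prediction Length-`T` predicted rate.
#' @param n_folds Number of contiguous folds (default 20; reduced with a
#'   warning when `T` is too short).
#' @param prediction_b Optional second model's prediction for a paired
#'   comparison.
#' @return List with `t`, `p`, `estimate` (mean leave-one-out correlation
#'   or correlation difference) and `n_folds`.
#' @export
jackknife_above_chance <- function(raster_row, prediction, n_folds = 20,
                                   prediction_b = NULL) {
  m <- if (is.matrix(raster_row)) rowMeans(raster_row) else as.numeric(raster_row)
  T <- length(m)
  if (length(prediction) != T) abort("prediction length must match response")
  folds <- make_folds(T, n_folds)
  if (length(folds) < n_folds)
    warn(sprintf("reduced jackknife folds from %d to %d", n_folds, length(folds)))
  est <- vapply(folds, function(ix) {
    keep <- setdiff(seq_len(T), ix)
    r1 <- suppressWarnings(cor(m[keep], prediction[keep]))
    if (is.null(prediction_b)) {
      if (is.na(r1)) 0 else r1
    } else {
      r2 <- suppressWarnings(cor(m[keep], prediction_b[keep]))
      (if (is.na(r1)) 0 else r1) - (if (is.na(r2)) 0 else r2)
    }
  }, numeric(1))
  jt <- jackknife_t(est)
  list(t = jt$t, p = jt$p, estimate = mean(est), n_folds = length(folds))
}

#' Score fitted models on validation data
#'
#' Computes the per-neuron evaluation record for one or more fitted models:
#' raw prediction correlation against the validation PSTH, TTRC, the
#' noise-corrected prediction correlation, SNR, and the jackknifed
#' above-chance p-value.
#'
#' @param fits A named list of `strf_fit` objects (names become
#'   `model_id`), or a single fit.
#' @param dataset An [strf_dataset()] providing validation stimulus and
#'   raster.
#' @param ttrc_floor Stability floor for the R_norm normalization.
#' @param n_folds Jackknife fold count.
#' @param alpha Significance level for the per-model `responsive` flag
#'   (default 0.05); the population-level auditory-responsive criterion
#'   intersects these flags across models via [responsive_subset()].
#' @return A tibble with columns `neuron_id`, `site_id`, `model_id`,
#'   `raw_r`, `ttrc`, `r_norm`, `snr`, `p_above_chance`, `responsive`.
#' @export
score_models <- function(fits, dataset, ttrc_floor = 0.05, n_folds = 20,
                         alpha = 0.05) {
  if (inherits(fits, "strf_fit")) fits <- list(model = fits)
  stopifnot(length(names(fits)) == length(fits))
  vr <- dataset$val_raster
  ids <- vr$neuron_ids
  P <- psth(dataset$val_raster)
  rows <- list()
  for (mod in names(fits)) {
    pred <- predict_rates(fits[[mod]], dataset$val_stim)
    for (id in fits[[mod]]$neuron_ids) {
      i <- match(id, ids)
      if (is.na(i)) next
      x <- vr$rates[i, , ] # T x M
      p_i <- pred[match(id, rownames(pred)), ]
      raw_r <- if (sd(p_i) == 0 || sd(P[i, ]) == 0) NA_real_ else cor(P[i, ], p_i)
      tt <- as.numeric(ttrc(x))
      rows[[length(rows) + 1]] <- tibble::tibble(
        neuron_id = id, site_id = vr$site_ids[i], model_id = mod,
        raw_r = raw_r, ttrc = tt,
        r_norm = noise_corrected_correlation(x, p_i, ttrc_floor),
        snr = snr_fraction(x),
        p_above_chance = jackknife_above_chance(x, p_i, n_folds)$p)
      rows[[length(rows)]]$responsive <-
        !is.na(rows[[length(rows)]]$p_above_chance) &&
        rows[[length(rows)]]$p_above_chance < alpha
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tbl_scores", class(out))
  out
}

#' Auditory-responsive neuron subset
#'
#' Neurons whose activity is predicted above chance (jackknifed t-test,
#' `p < alpha`) by every one of the given models; neurons failing the
#' criterion for any model are treated as non-auditory and excluded from
#' population summaries.
#'
#' @param scores Score tibble from [score_models()] covering all models in
#'   `models`.
#' @param models Model ids that must all be above chance (default: every
#'   model present in `scores`).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of responsive neuron ids.
#' @export
responsive_subset <- function(scores, models = NULL, alpha = 0.05) {
  if (is.null(models)) models <- unique(scores$model_id)
  if (!all(models %in% scores$model_id)) abort("scores missing a requested model")
  sets <- lapply(models, function(m) {
    s <- scores[scores$model_id == m & !is.na(scores$p_above_chance) &
                scores$p_above_chance < alpha, ]
    unique(s$neuron_id)
  })
  Reduce(intersect, sets)
}

#' Rank-based comparison of two score distributions
#'
#' Two-sided Wilcoxon signed-rank test for paired scores (the same neurons
#' under two models or protocols, matched by `neuron_id`) or Mann-Whitney U
#' test for independent populations. Small samples (n < 5) trigger a
#' warning and use the exact distribution.
#'
#' @param scores_a,scores_b Tibbles with `neuron_id` and a score column, or
#'   bare numeric vectors (named by neuron for paired use).
#' @param paired Use the signed-rank test on matched neurons.
#' @param value Score column name (default `"r_norm"`).
#' @param alternative Test sidedness passed to [stats::wilcox.test()].
#' @return One-row tibble: medians, difference of medians, statistic,
#'   p-value, n, method.
#' @export
compare_populations <- function(scores_a, scores_b, paired = FALSE,
                                value = "r_norm", alternative = "two.sided") {
  get_vals <- function(s) {
    if (is.numeric(s)) return(s)
    setNames(s[[value]], s$neuron_id)
  }
  a <- get_vals(scores_a); b <- get_vals(scores_b)
  if (paired) {
    if (!is.null(names(a)) && !is.null(names(b))) {
      common <- intersect(names(a), names(b))
      if (length(common) == 0) abort("paired comparison requires matched neuron ids")
      a <- a[common]; b <- b[common]
    } else if (length(a) != length(b)) {
      abort("paired comparison requires equal-length samples")
    }
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  n <- if (paired) length(a) else length(a) + length(b)
  if (min(length(a), length(b)) < 5)
    warn("fewer than 5 observations; using exact small-sample test")
  # wilcox.test uses the exact rank distribution for small untied samples;
  # identical paired samples carry no signal and score p = 1
  wt <- tryCatch(
    suppressWarnings(wilcox.test(a, b, paired = paired,
                                 alternative = alternative)),
    error = function(e) list(statistic = NA_real_, p.value = 1))
  tibble::tibble(
    median_a = median(a), median_b = median(b),
    median_diff = if (paired) median(a - b) else median(a) - median(b),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n = n, method = if (paired) "wilcoxon-signed-rank" else "mann-whitney-u",
    alternative = alternative)
}
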