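test_that("estimation split: sizes, determinism, rounding rule", {
  s <- split_estimation(10, 0.2, seed = 1)
  expect_length(s$earlystop, 2)
  expect_length(s$fit, 8)
  expect_length(intersect(s$fit, s$earlystop), 0)
  expect_identical(split_estimation(10, 0.2, seed = 1), s)
  expect_false(identical(split_estimation(10, 0.2, seed = 2)$earlystop,
                         s$earlystop))
  # rounding rule floor(n * fraction), clamped to >= 1
  for (fr in c(0.1, 0.2, 0.5)) {
    got <- length(split_estimation(20, fr, seed = 3)$earlystop)
    expect_equal(got, max(1, floor(20 * fr)))
  }
  expect_equal(length(split_estimation(6, 0.05, seed = 1)$earlystop), 1)
  expect_error(split_estimation(4, 0.2), "at least 5")
  expect_error(split_estimation(10, 1.2), "in \\(0, 1\\)")
})

test_that("initialization: one mean entry, reproducible draws", {
  spec <- model_spec("pop-LN", n_neurons = 4, n_units = 6)
  ini <- initialize_params(spec, n_init = 10, seed = 5, rate_scale = 2)
  expect_length(ini, 10)
  # the final entry is the deterministic mean of each distribution
  mean_entry <- ini[[10]]
  expect_equal(mean_entry[[1]]$mu, rep((18 - 1) / 2, 6))
  expect_equal(mean_entry[[1]]$sigma, rep(2, 6))
  expect_true(all(mean_entry[[2]]$taps == 0))
  expect_true(all(mean_entry[[3]]$W == 0))
  expect_equal(mean_entry[[4]]$b, rep(1, 4))     # rate_scale / 2
  expect_equal(mean_entry[[4]]$a, rep(4, 4))     # 2 * rate_scale
  expect_equal(mean_entry[[4]]$k, rep(1, 4))
  # n_init = 1: only the mean initialization
  solo <- initialize_params(spec, n_init = 1, seed = 5, rate_scale = 2)
  expect_length(solo, 1)
  expect_equal(solo[[1]], mean_entry)
  # different seeds change random entries but never the mean entry
  ini2 <- initialize_params(spec, n_init = 10, seed = 6, rate_scale = 2)
  expect_false(identical(ini[[1]], ini2[[1]]))
  expect_equal(ini[[10]], ini2[[10]])
  # random draws have the documented distributions (loose moment check)
  mus <- unlist(lapply(1:9, function(i) ini[[i]][[1]]$mu))
  expect_true(all(mus >= 0 & mus <= 17))
})

test_that("optimizer restores the best early-stop epoch and never regresses", {
  # quadratic toy problem where the early-stop loss is optimized at w = 1
  grad_fn <- function(w) list(loss = sum((w - 1)^2), grad = 2 * (w - 1))
  es_fn <- function(w) sum((w - 1)^2)
  cfg <- fit_config(learning_rate = 0.05, max_epochs = 400, patience = 20,
                    n_init = 1, seed = 1)
  res <- popstrf:::adam_fit(c(5, -3), grad_fn, es_fn, cfg)
  expect_lt(res$es_loss, 1e-3)
  expect_equal(res$es_loss, min(res$trace$es_loss))
  # starting at the optimum: the epoch-0 candidate is kept, loss cannot rise
  res0 <- popstrf:::adam_fit(c(1, 1), grad_fn, es_fn, cfg)
  expect_lte(res0$es_loss, es_fn(c(1, 1)) + 1e-12)
})

test_that("a linear readout fit recovers the least-squares solution", {
  # noise-free linear data: y = W h + b on a fixed design; fitting the
  # step-A readout layers must approach the closed-form OLS predictions
  set.seed(41)
  H <- matrix(rnorm(5 * 400), 5, 400)
  W_true <- matrix(rnorm(3 * 5), 3, 5)
  b_true <- c(1, -2, 0.5)
  Y <- W_true %*% H + b_true
  layers <- list(list(type = "mix", n_out = 3L, n_in = 5L),
                 list(type = "bias", n_units = 3L))
  spec_like <- list(layers = layers)
  p0 <- list(list(W = matrix(0, 3, 5)), list(b = rep(0, 3)))
  cfg <- fit_config(learning_rate = 0.05, max_epochs = 2000, patience = 100,
                    n_init = 1, seed = 1, tolerance = 1e-9)
  res <- popstrf:::adam_fit(
    pack_params(spec_like, p0),
    popstrf:::make_loss(layers, H, 1L, Y),
    popstrf:::make_es_loss(layers, H, 1L, Y), cfg)
  pars <- unpack_params(spec_like, res$par)
  pred <- pars[[1]]$W %*% H + pars[[2]]$b
  # OLS oracle via lm on the induced design matrix
  ols <- lm(t(Y) ~ t(H))
  pred_ols <- t(fitted(ols))
  expect_equal(pred, pred_ols, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("stage-1 fitting improves over initialization and is deterministic", {
  ds <- small_dataset()
  spec <- model_spec("pop-LN", n_neurons = 12, n_units = 5)
  cfg <- fast_config(seed = 9)
  f1 <- fit_stage1(spec, ds, cfg)
  expect_s3_class(f1, "strf_fit")
  expect_equal(f1$stage, 1L)
  # loss decreased through step C
  expect_lt(f1$es_loss, f1$traces$stepC$es_loss[1] + 1e-9)
  # early stopping: reported loss is the minimum of the trace
  expect_lte(f1$es_loss, min(f1$traces$stepC$es_loss))
  # full determinism from (seed, config, data)
  f1b <- fit_stage1(spec, ds, cfg)
  expect_equal(f1$params, f1b$params)
  expect_equal(f1$chosen_init, f1b$chosen_init)
  # prediction shape and names
  pr <- predict_rates(f1, ds$val_stim)
  expect_equal(dim(pr), c(12, ncol(ds$val_stim$values)))
  expect_equal(rownames(pr), ds$val_raster$neuron_ids)
  # neuron-count mismatch is rejected
  expect_error(fit_stage1(model_spec("pop-LN", n_neurons = 5, n_units = 4), ds,
                          cfg), "neuron count")
})

test_that("stage 2 never worsens a neuron and isolates neurons", {
  ds <- small_dataset()
  spec <- model_spec("pop-LN", n_neurons = 12, n_units = 5)
  cfg <- fast_config(seed = 9)
  f1 <- fit_stage1(spec, ds, cfg)
  f2 <- fit_stage2(f1, ds)
  expect_equal(f2$stage, 2L)
  expect_equal(nrow(f2$neurons), 12)
  # per-neuron early-stop loss after stage 2 <= stage-1 value + tolerance:
  # compute stage-1 per-neuron losses on the same early-stop columns
  split <- f1$es_split
  st <- ds$est_stim$snippet_starts
  es_ix <- popstrf:::snippet_columns(st, ncol(ds$est_stim$values), split$earlystop)
  R <- psth(ds$est_raster)
  pred1 <- predict_rates(f1, ds$est_stim)
  for (i in seq_len(12)) {
    l1 <- mean((pred1[i, es_ix$cols] - R[i, es_ix$cols])^2) / f1$resp_scale^2
    expect_lte(f2$neurons$es_loss[i], l1 + 1e-6)
  }
  # isolation: changing neuron j's responses changes only neuron j's readout
  ds2 <- ds
  ds2$est_raster$rates[3, , ] <- rev(ds2$est_raster$rates[3, , ])
  f2b <- fit_stage2(f1, ds2)
  pr_a <- predict_rates(f2, ds$val_stim)
  pr_b <- predict_rates(f2b, ds$val_stim)
  expect_equal(pr_a[-3, ], pr_b[-3, ])
  expect_false(isTRUE(all.equal(pr_a[3, ], pr_b[3, ])))
})

test_that("stage 2 helps a neuron whose firing scale the population loss underweights", {
  # construct a population where one neuron fires at double scale: the
  # unweighted stage-1 loss underfits the others relative to a per-neuron fit
  ds <- small_dataset()
  spec <- model_spec("pop-LN", n_neurons = 12, n_units = 5)
  cfg <- fast_config(seed = 9)
  ds_scaled <- ds
  ds_scaled$est_raster$rates[5, , ] <- ds_scaled$est_raster$rates[5, , ] * 3
  ds_scaled$val_raster$rates[5, , ] <- ds_scaled$val_raster$rates[5, , ] * 3
  f1 <- fit_stage1(spec, ds_scaled, cfg)
  f2 <- fit_stage2(f1, ds_scaled)
  split <- f1$es_split
  es_ix <- popstrf:::snippet_columns(ds_scaled$est_stim$snippet_starts,
                                     ncol(ds_scaled$est_stim$values),
                                     split$earlystop)
  R <- psth(ds_scaled$est_raster)
  pred1 <- predict_rates(f1, ds_scaled$est_stim)
  # median per-neuron improvement is nonnegative, and no neuron regresses
  impr <- vapply(seq_len(12), function(i) {
    l1 <- mean((pred1[i, es_ix$cols] - R[i, es_ix$cols])^2) / f1$resp_scale^2
    l1 - f2$neurons$es_loss[i]
  }, numeric(1))
  expect_true(all(impr > -1e-6))
  expect_gt(median(impr), 0)
})

test_that("rank-1 LN parameter recovery from rank-1 LN data", {
  # simulate a single neuron from a known rank-1 LN model (200 snippets,
  # high SNR) and refit the same architecture: the recovered outer-product
  # filter must align with the true one
  rec <- ln_recovery()
  expect_gt(rec$correlation, 0.95)
  expect_equal(rec$fit$spec$architecture, "LN")
})
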