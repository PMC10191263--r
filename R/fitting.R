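#' Fitting configuration
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs Maximum full-batch epochs per optimization step
#'   (default 5000).
#' @param patience Epochs without early-stop-set improvement before
#'   stopping (default 30).
#' @param es_fraction Fraction of estimation snippets held out as the
#'   early-stopping set (default 0.2).
#' @param n_init Number of stage-1 initializations: `n_init - 1` random plus
#'   one mean initialization (default 10).
#' @param n_init_readout Initializations for output-layer fits of neurons
#'   absent from the stage-1 population (default 3).
#' @param seed RNG seed governing the snippet split and initializations.
#' @param tolerance Relative improvement in early-stop loss counted as
#'   progress (default 1e-6).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(learning_rate = 1e-3, max_epochs = 5000, patience = 30,
                       es_fraction = 0.2, n_init = 10, n_init_readout = 3,
                       seed = 1, tolerance = 1e-6) {
  if (es_fraction <= 0 || es_fraction >= 1) abort("es_fraction must be in (0, 1)")
  if (n_init < 1) abort("n_init must be at least 1")
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), es_fraction = es_fraction,
                 n_init = as.integer(n_init),
                 n_init_readout = as.integer(n_init_readout),
                 seed = as.integer(seed), tolerance = tolerance),
            class = "fit_config")
}

# Columns belonging to the selected snippets, plus rebuilt snippet starts.
snippet_columns <- function(starts, T, idx) {
  ends <- c(starts[-1] - 1L, T)
  cols <- integer(0); new_starts <- integer(0); pos <- 1L
  for (i in idx) {
    seg <- starts[i]:ends[i]
    new_starts <- c(new_starts, pos)
    pos <- pos + length(seg)
    cols <- c(cols, seg)
  }
  list(cols = cols, starts = new_starts)
}

#' Split estimation snippets into fit and early-stop sets
#'
#' Splits by whole stimulus snippets (never within a snippet), holding out
#' `floor(n * es_fraction)` snippets (at least 1) for early stopping.
#' Validation data never enters either set.
#'
#' @param n_snippets Number of estimation snippets (or a [spectrogram],
#'   whose snippet count is used).
#' @param es_fraction Early-stop fraction in (0, 1).
#' @param seed RNG seed; the same seed always yields the same split.
#' @return List with integer snippet indices `fit` and `earlystop`.
#' @export
split_estimation <- function(n_snippets, es_fraction = 0.2, seed = 1) {
  if (inherits(n_snippets, "spectrogram"))
    n_snippets <- length(n_snippets$snippet_starts)
  n <- as.integer(n_snippets)
  if (n < 5) abort("need at least 5 estimation snippets to split")
  if (es_fraction <= 0 || es_fraction >= 1) abort("es_fraction must be in (0, 1)")
  n_es <- max(1L, as.integer(floor(n * es_fraction)))
  es <- with_seed(seed, sort(sample.int(n, n_es)))
  list(fit = setdiff(seq_len(n), es), earlystop = es)
}

# Full-batch Adam with early stopping and best-weights restoration. grad_fn
# returns list(loss, grad); es_fn returns the early-stop loss. The initial
# parameters count as the epoch-0 candidate, so the result is never worse
# than the start on the early-stop set.
adam_fit <- function(par, grad_fn, es_fn, config, lower = NULL, upper = NULL) {
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- v <- numeric(length(par))
  best_par <- par
  best_es <- es_fn(par)
  best_epoch <- 0L
  waited <- 0L
  trace_fit <- numeric(0); trace_es <- numeric(0)
  diverged <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    g <- grad_fn(par)
    if (!is.finite(g$loss) || anyNA(g$grad) || any(!is.finite(g$grad))) {
      diverged <- TRUE
      break
    }
    m <- b1 * m + (1 - b1) * g$grad
    v <- b2 * v + (1 - b2) * g$grad^2
    mh <- m / (1 - b1^epoch)
    vh <- v / (1 - b2^epoch)
    par <- par - lr * mh / (sqrt(vh) + eps)
    if (!is.null(lower)) par <- pmax(par, lower)
    if (!is.null(upper)) par <- pmin(par, upper)
    es <- es_fn(par)
    trace_fit <- c(trace_fit, g$loss); trace_es <- c(trace_es, es)
    if (is.finite(es) && es < best_es - config$tolerance * max(abs(best_es), 1e-12)) {
      best_es <- es; best_par <- par; best_epoch <- epoch; waited <- 0L
    } else {
      waited <- waited + 1L
      if (waited >= config$patience) break
    }
  }
  list(par = best_par, es_loss = best_es, best_epoch = best_epoch,
       trace = tibble::tibble(epoch = seq_along(trace_fit),
                              fit_loss = trace_fit, es_loss = trace_es),
       diverged = diverged)
}

# Loss/gradient closure for a layer sequence on fixed data.
make_loss <- function(layers, X, starts, R, frozen = integer(0)) {
  n_resp <- length(R)
  spec_like <- list(layers = layers)
  function(vec) {
    params <- unpack_params(spec_like, vec)
    fw <- model_forward_layers(layers, params, X, starts, keep_cache = TRUE)
    resid <- fw$out - R
    loss <- mean(resid^2)
    dY <- 2 * resid / n_resp
    grads <- model_backward_layers(layers, params, fw$caches, dY, starts, frozen)
    # frozen layers contribute zero gradient but keep vector alignment
    for (i in frozen) grads[[i]] <- lapply(params[[i]], function(p) p * 0)
    list(loss = loss, grad = pack_params(spec_like, grads))
  }
}

make_es_loss <- function(layers, X, starts, R) {
  spec_like <- list(layers = layers)
  function(vec) {
    params <- unpack_params(spec_like, vec)
    out <- model_forward_layers(layers, params, X, starts)$out
    mean((out - R)^2)
  }
}

# Spec-like object for the step-A submodel: shared core plus a temporary
# linear per-neuron readout (no output nonlinearity). For the batched LN the
# readout is per-neuron scale + offset on the neuron's own channel.
stepA_layers <- function(spec) {
  k_out <- output_layer_start(spec)
  core <- spec$layers[seq_len(k_out - 1L)]
  n <- spec$n_neurons
  if (spec$architecture == "LN") {
    c(core, list(list(type = "scale", n_units = n),
                 list(type = "bias", n_units = n)))
  } else {
    c_last <- spec$layers[[k_out]]$n_in
    c(core, list(list(type = "mix", n_out = n, n_in = c_last),
                 list(type = "bias", n_units = n)))
  }
}

layers_bounds <- function(layers) param_bounds(list(layers = layers))

standardize_stim <- function(X, preproc = NULL) {
  if (is.null(preproc)) {
    mu <- rowMeans(X)
    sdv <- apply(X, 1, sd)
    sdv[sdv < 1e-12] <- 1
    preproc <- list(mean = mu, sd = sdv)
  }
  list(X = (X - preproc$mean) / preproc$sd, preproc = preproc)
}

#' Stage 1: population fit with multiple initializations
#'
#' Fits a model to all neurons of the estimation set simultaneously
#' (mean-squared-error loss averaged over neurons and time), using a
#' three-step heuristic per initialization: (A) fit the shared core with
#' the output layer replaced by a temporary linear per-neuron readout;
#' (B) freeze the core and fit the true output layer (dense readout plus
#' double exponential) from its initialization values; then the best
#' initialization by early-stop loss seeds (C) a joint fit of all
#' parameters. Each step uses full-batch Adam with early stopping on a
#' held-out fraction of estimation snippets and best-weights restoration.
#' Initializations whose loss diverges are restarted once with a halved
#' learning rate, then marked failed; at least one must succeed.
#'
#' @param spec A [model_spec()] with `n_neurons` matching the dataset.
#' @param dataset An [strf_dataset()].
#' @param config A [fit_config()].
#' @return An object of class `strf_fit`: fitted per-layer parameters,
#'   stimulus preprocessing, per-step loss traces, the chosen
#'   initialization, and the snippet split.
#' @export
fit_stage1 <- function(spec, dataset, config = fit_config()) {
  stim <- dataset$est_stim
  R <- psth(dataset$est_raster)
  if (nrow(R) != spec$n_neurons)
    abort("dataset neuron count does not match spec n_neurons")
  std <- standardize_stim(stim$values)
  starts <- stim$snippet_starts
  T_all <- ncol(std$X)
  split <- split_estimation(length(starts), config$es_fraction, config$seed)
  fit_ix <- snippet_columns(starts, T_all, split$fit)
  es_ix <- snippet_columns(starts, T_all, split$earlystop)
  # responses are scaled by one population-wide factor so parameters live at
  # order 1; this leaves the relative weighting of neurons in the population
  # loss untouched and is inverted at prediction time
  resp_scale <- max(sd(R), 1e-6)
  R <- R / resp_scale
  Xf <- std$X[, fit_ix$cols, drop = FALSE]; Rf <- R[, fit_ix$cols, drop = FALSE]
  Xe <- std$X[, es_ix$cols, drop = FALSE]; Re <- R[, es_ix$cols, drop = FALSE]
  rate_scale <- max(mean(Rf), 1e-3)

  inits <- initialize_params(spec, config$n_init, config$seed, rate_scale)
  layersA <- stepA_layers(spec)
  tmp_inits <- initialize_params(list(layers = layersA), config$n_init,
                                 child_seed(config$seed, "stepA"), rate_scale)
  k_out <- output_layer_start(spec)
  core_idx <- seq_len(k_out - 1L)
  out_idx <- seq(k_out, length(spec$layers))

  run_steps_AB <- function(i, lr_scale = 1) {
    cfg <- config; cfg$learning_rate <- config$learning_rate * lr_scale
    # step A: core + temporary linear readout, offsets seeded at each
    # neuron's mean rate
    parsA <- c(inits[[i]][core_idx],
               tmp_inits[[i]][seq(k_out, length(layersA))])
    parsA[[length(parsA)]]$b <- rowMeans(Rf)
    bA <- layers_bounds(layersA)
    resA <- adam_fit(pack_params(list(layers = layersA), parsA),
                     make_loss(layersA, Xf, fit_ix$starts, Rf),
                     make_es_loss(layersA, Xe, es_ix$starts, Re),
                     cfg, bA$lower, bA$upper)
    if (resA$diverged) return(list(diverged = TRUE))
    parsA_fit <- unpack_params(list(layers = layersA), resA$par)
    core_pars <- parsA_fit[core_idx]
    # step B: freeze core, fit true output layer from initialization values
    H_fit <- model_forward_layers(spec$layers[core_idx], core_pars, Xf,
                                  fit_ix$starts)$out
    H_es <- model_forward_layers(spec$layers[core_idx], core_pars, Xe,
                                 es_ix$starts)$out
    out_layers <- spec$layers[out_idx]
    out_pars <- inits[[i]][out_idx]
    bB <- layers_bounds(out_layers)
    resB <- adam_fit(pack_params(list(layers = out_layers), out_pars),
                     make_loss(out_layers, H_fit, fit_ix$starts, Rf),
                     make_es_loss(out_layers, H_es, es_ix$starts, Re),
                     cfg, bB$lower, bB$upper)
    if (resB$diverged) return(list(diverged = TRUE))
    list(diverged = FALSE, core = core_pars,
         out = unpack_params(list(layers = out_layers), resB$par),
         es_loss = resB$es_loss,
         traceA = resA$trace, traceB = resB$trace)
  }

  results <- vector("list", config$n_init)
  for (i in seq_len(config$n_init)) {
    res <- run_steps_AB(i)
    if (isTRUE(res$diverged)) res <- run_steps_AB(i, lr_scale = 0.5)
    results[[i]] <- res
  }
  ok <- which(!vapply(results, function(r) isTRUE(r$diverged), logical(1)))
  if (length(ok) == 0) abort("all initializations diverged")
  es_losses <- vapply(results[ok], `[[`, numeric(1), "es_loss")
  best_i <- ok[which.min(es_losses)]

  # step C: joint fit of all parameters from the best initialization
  parsC <- c(results[[best_i]]$core, results[[best_i]]$out)
  bC <- param_bounds(spec)
  resC <- adam_fit(pack_params(spec, parsC),
                   make_loss(spec$layers, Xf, fit_ix$starts, Rf),
                   make_es_loss(spec$layers, Xe, es_ix$starts, Re),
                   config, bC$lower, bC$upper)
  params <- unpack_params(spec, resC$par)

  structure(
    list(spec = spec, params = params, preproc = std$preproc,
         resp_scale = resp_scale,
         config = config, chosen_init = best_i,
         failed_inits = setdiff(seq_len(config$n_init), ok),
         es_split = split, es_loss = resC$es_loss,
         init_es_losses = setNames(es_losses, ok),
         traces = list(stepA = results[[best_i]]$traceA,
                       stepB = results[[best_i]]$traceB,
                       stepC = resC$trace),
         neuron_ids = dataset$est_raster$neuron_ids,
         site_ids = dataset$est_raster$site_ids,
         stage = 1L, seed = config$seed),
    class = "strf_fit"
  )
}

#' @export
print.strf_fit <- function(x, ...) {
  cat(sprintf("<strf_fit> stage %d, %s, %d neuron(s); init %d/%d, es loss %.4g\n",
              x$stage, x$spec$architecture, x$spec$n_neurons,
              x$chosen_init, x$config$n_init, x$es_loss))
  invisible(x)
}

#' Predict firing rates from a fitted model
#'
#' @param fit An `strf_fit` from [fit_stage1()] or [fit_stage2()].
#' @param stim A [spectrogram] (raw frontend output; the fit's stored
#'   stimulus standardization is applied internally).
#' @param linear_output Return the pre-nonlinearity drive (test hook).
#' @return `N x T` matrix of predicted rates, rows named by neuron id.
#' @export
predict_rates <- function(fit, stim, linear_output = FALSE) {
  std <- standardize_stim(stim$values, fit$preproc)
  rs <- if (is.null(fit$resp_scale)) 1 else fit$resp_scale
  if (fit$stage == 2L) {
    core_layers <- fit$core_layers
    H <- model_forward_layers(core_layers, fit$core_params, std$X,
                              stim$snippet_starts)$out
    out <- matrix(0, length(fit$neuron_ids), ncol(H),
                  dimnames = list(fit$neuron_ids, NULL))
    for (i in seq_along(fit$neuron_ids)) {
      ro <- fit$readout[[i]]
      y <- if (is.null(ro$w)) H[ro$row, ] else as.numeric(ro$w %*% H)
      out[i, ] <- if (linear_output) y
                  else double_exponential(y, ro$b, ro$a, ro$s, ro$k)
    }
    return(out * rs)
  }
  out <- model_forward_layers(fit$spec$layers, fit$params, std$X,
                              stim$snippet_starts,
                              linear_output = linear_output)$out
  rownames(out) <- fit$neuron_ids
  out * rs
}

# Optimize every neuron's readout (dense weights over the core output plus
# double exponential, or the double exponential alone for the batched LN)
# against its own MSE, jointly in one vectorized Adam loop. The per-neuron
# problems have block-independent gradients, so the joint trajectory equals
# independent per-neuron fits; early stopping, patience and best-weights
# restoration are tracked per neuron. `inits` is a list of candidate
# starting points, each with W (N x C, or NULL) and b/a/s/k vectors;
# every neuron keeps its best candidate by early-stop loss.
fit_readouts_vectorized <- function(H_fit, H_es, R_fit, R_es, inits, config,
                                    with_w = TRUE) {
  N <- nrow(R_fit); Tf <- ncol(R_fit); Te <- ncol(R_es)
  C <- nrow(H_fit)
  best_es <- rep(Inf, N)
  best <- list(W = if (with_w) matrix(0, N, C), b = numeric(N), a = numeric(N),
               s = numeric(N), k = numeric(N), epochs = integer(N))
  for (cand in inits) {
    p <- list(W = cand$W, b = cand$b, a = cand$a, s = cand$s, k = cand$k)
    n_par_per <- (if (with_w) C else 0) + 4L
    m <- v <- matrix(0, N, n_par_per)
    cb_es <- rep(Inf, N); cb <- p; cb_epoch <- integer(N)
    waited <- integer(N)
    lr <- config$learning_rate
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    # epoch-0 candidate
    drive0 <- if (with_w) p$W %*% H_es else H_es
    cb_es <- cc_dexp_rowmse(drive0, R_es, p$b, p$a, p$s, p$k)
    for (epoch in seq_len(config$max_epochs)) {
      active <- waited < config$patience
      if (!any(active)) break
      drive <- if (with_w) p$W %*% H_fit else H_fit
      gr <- cc_dexp_grad(drive, R_fit, p$b, p$a, p$s, p$k)
      if (with_w) {
        g <- cbind(tcrossprod(gr$ddrive, H_fit),
                   gr$g_b, gr$g_a, gr$g_s, gr$g_k)
      } else {
        g <- cbind(gr$g_b, gr$g_a, gr$g_s, gr$g_k)
      }
      bad <- !is.finite(rowSums(g))
      if (any(bad)) g[bad, ] <- 0 # freeze diverged neurons at their best
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      step <- lr * (m / (1 - b1^epoch)) / (sqrt(v / (1 - b2^epoch)) + eps)
      step[!active | bad, ] <- 0
      if (with_w) {
        p$W <- p$W - step[, seq_len(C), drop = FALSE]
        off <- C
      } else off <- 0L
      p$b <- p$b - step[, off + 1]; p$a <- p$a - step[, off + 2]
      p$s <- p$s - step[, off + 3]; p$k <- p$k - step[, off + 4]
      drive_e <- if (with_w) p$W %*% H_es else H_es
      es <- cc_dexp_rowmse(drive_e, R_es, p$b, p$a, p$s, p$k)
      impr <- is.finite(es) & (es < cb_es - config$tolerance * pmax(abs(cb_es), 1e-12))
      waited <- ifelse(impr, 0L, waited + 1L)
      upd <- which(impr & active)
      if (length(upd) > 0) {
        cb_es[upd] <- es[upd]
        if (with_w) cb$W[upd, ] <- p$W[upd, , drop = FALSE]
        cb$b[upd] <- p$b[upd]; cb$a[upd] <- p$a[upd]
        cb$s[upd] <- p$s[upd]; cb$k[upd] <- p$k[upd]
        cb_epoch[upd] <- epoch
      }
    }
    take <- which(cb_es < best_es)
    if (length(take) > 0) {
      best_es[take] <- cb_es[take]
      if (with_w) best$W[take, ] <- cb$W[take, , drop = FALSE]
      best$b[take] <- cb$b[take]; best$a[take] <- cb$a[take]
      best$s[take] <- cb$s[take]; best$k[take] <- cb$k[take]
      best$epochs[take] <- cb_epoch[take]
    }
  }
  if (any(!is.finite(best_es))) abort("readout fit diverged for all initializations")
  list(best = best, es_loss = best_es)
}

#' Stage 2: per-neuron output-layer refits
#'
#' Re-fits the output layer (readout weights and output nonlinearity) one
#' neuron at a time with all earlier layers frozen, each neuron under its
#' own MSE loss. Neurons present in the stage-1 population start from their
#' stage-1 output parameters (whose early-stop loss is the epoch-0
#' candidate, so a neuron's loss never ends worse than stage 1). Neurons
#' absent from stage 1 (held-out protocols) start from
#' `config$n_init_readout` fresh initializations.
#'
#' @param fit A stage-1 `strf_fit`.
#' @param dataset An [strf_dataset()]; may contain neurons that were not in
#'   the stage-1 population.
#' @param config A [fit_config()]; defaults to the stage-1 config.
#' @param neurons Neuron ids to refit (default: all in `dataset`).
#' @return A stage-2 `strf_fit` with per-neuron readouts and a `neurons`
#'   tibble (id, site, early-stop losses, epochs).
#' @export
fit_stage2 <- function(fit, dataset, config = NULL, neurons = NULL) {
  if (is.null(config)) config <- fit$config
  spec <- fit$spec
  stim <- dataset$est_stim
  R <- psth(dataset$est_raster)
  rs <- if (is.null(fit$resp_scale)) 1 else fit$resp_scale
  R <- R / rs
  ids <- dataset$est_raster$neuron_ids
  if (is.null(neurons)) neurons <- ids
  if (!all(neurons %in% ids)) abort("unknown neuron ids requested")
  std <- standardize_stim(stim$values, fit$preproc)
  starts <- stim$snippet_starts
  T_all <- ncol(std$X)
  split <- split_estimation(length(starts), config$es_fraction, config$seed)
  fit_ix <- snippet_columns(starts, T_all, split$fit)
  es_ix <- snippet_columns(starts, T_all, split$earlystop)

  k_out <- output_layer_start(spec)
  core_idx <- seq_len(k_out - 1L)
  core_layers <- spec$layers[core_idx]
  core_params <- fit$params[core_idx]
  H_fit <- model_forward_layers(core_layers, core_params,
                                std$X[, fit_ix$cols, drop = FALSE], fit_ix$starts)$out
  H_es <- model_forward_layers(core_layers, core_params,
                               std$X[, es_ix$cols, drop = FALSE], es_ix$starts)$out
  with_w <- spec$layers[[k_out]]$type == "mix"
  i_dat <- match(neurons, ids)
  i_fit <- match(neurons, fit$neuron_ids)
  if (!with_w && anyNA(i_fit))
    abort("cannot stage-2 fit a new neuron for an architecture without a dense readout")
  N <- length(neurons)
  Rf <- R[i_dat, fit_ix$cols, drop = FALSE]
  Re <- R[i_dat, es_ix$cols, drop = FALSE]
  if (!with_w) {
    # batched LN: each neuron's readout is its own core channel
    H_fit <- H_fit[i_fit, , drop = FALSE]
    H_es <- H_es[i_fit, , drop = FALSE]
  }
  C <- nrow(H_fit)
  # fresh initialization candidates for every neuron (identical fitting
  # process for in-population and held-out neurons); the stage-1 output
  # parameters, when available, join as one extra candidate
  # per-neuron rate scales (not a population scalar), so a neuron's
  # initialization depends on no other neuron's data
  rate_i <- pmax(rowMeans(Rf), 1e-3)
  cands <- with_seed(child_seed(config$seed, "stage2"), {
    lapply(seq_len(config$n_init_readout), function(ci) {
      mean_init <- ci == config$n_init_readout
      list(
        W = if (!with_w) NULL
            else if (mean_init) matrix(0, N, C)
            else matrix(rnorm(N * C, 0, 1 / sqrt(C)), N, C),
        b = if (mean_init) rate_i / 2 else runif(N) * rate_i,
        a = if (mean_init) 2 * rate_i else runif(N) * 4 * rate_i,
        s = if (mean_init) rep(0, N) else rnorm(N),
        k = if (mean_init) rep(1, N) else runif(N, 0.5, 1.5))
    })
  })
  if (any(!is.na(i_fit))) {
    dxp <- fit$params[[length(fit$params)]]
    warm <- cands[[1]] # neurons without stage-1 parameters keep a fresh draw
    ok <- which(!is.na(i_fit))
    if (with_w) warm$W[ok, ] <- fit$params[[k_out]]$W[i_fit[ok], , drop = FALSE]
    warm$b[ok] <- dxp$b[i_fit[ok]]; warm$a[ok] <- dxp$a[i_fit[ok]]
    warm$s[ok] <- dxp$s[i_fit[ok]]; warm$k[ok] <- dxp$k[i_fit[ok]]
    cands <- c(list(warm), cands)
  }
  res <- fit_readouts_vectorized(H_fit, H_es, Rf, Re, cands, config,
                                 with_w = with_w)
  readouts <- lapply(seq_len(N), function(j) {
    if (with_w)
      list(w = res$best$W[j, ], b = res$best$b[j], a = res$best$a[j],
           s = res$best$s[j], k = res$best$k[j])
    else
      list(w = NULL, row = i_fit[j], b = res$best$b[j], a = res$best$a[j],
           s = res$best$s[j], k = res$best$k[j])
  })
  neuron_tbl <- tibble::tibble(
    neuron_id = neurons, site_id = dataset$est_raster$site_ids[i_dat],
    in_stage1 = !is.na(i_fit), es_loss = res$es_loss,
    epochs = res$best$epochs)
  structure(
    list(spec = spec, core_layers = core_layers, core_params = core_params,
         readout = readouts, preproc = fit$preproc, resp_scale = rs,
         config = config,
         neurons = neuron_tbl, neuron_ids = neurons,
         site_ids = dataset$est_raster$site_ids[i_dat],
         es_split = split, stage = 2L, seed = config$seed),
    class = "strf_fit"
  )
}
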