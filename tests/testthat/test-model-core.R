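test_that("double exponential matches its closed form", {
  # threshold point: y = s gives b + a/e
  expect_equal(double_exponential(2, b = 1, a = 3, s = 2, k = 0.7),
               1 + 3 * exp(-1))
  # a = 0 collapses to the baseline for every input
  expect_equal(double_exponential(seq(-5, 5), b = 0.4, a = 0, s = 1, k = 2),
               rep(0.4, 11))
  # scalar evaluations of the formula, frozen from independent computation
  got <- double_exponential(c(-4, 0, 4), b = 0, a = 1, s = 0, k = 1)
  expect_equal(got, exp(-exp(c(-4, 0, 4))), tolerance = 1e-12)
  expect_equal(got[2], 0.367879441171442, tolerance = 1e-12)
  # vectorizes over matrices with per-row parameters
  y <- matrix(rnorm(6), 2, 3)
  out <- double_exponential(y, b = c(1, 2), a = c(1, 1), s = c(0, 0), k = c(1, 1))
  expect_equal(out[2, ], 2 + exp(-exp(y[2, ])))
})

test_that("ln_forward matches brute-force evaluation of the convolution sum", {
  set.seed(11)
  stim <- tiny_stim(T = 200, seed = 11)
  spectral <- list(mu = runif(3, 2, 15), sigma = runif(3, 0.5, 3))
  temporal <- matrix(rnorm(3 * 25), 3, 25)
  # the rank-3 filter as an explicit F x U outer-product sum
  W <- popstrf:::gauss_weights(spectral$mu, spectral$sigma, 18)
  h <- t(W) %*% temporal
  r_direct <- brute_force_rlin(stim$values, h, stim$snippet_starts)
  r_lin <- ln_forward(stim, spectral, temporal)
  expect_equal(r_lin, r_direct, tolerance = 1e-6)
  # with the output nonlinearity applied
  nl <- list(b = 1, a = 10, s = 0.5, k = 1.2)
  expect_equal(ln_forward(stim, spectral, temporal, nl),
               double_exponential(r_direct, nl$b, nl$a, nl$s, nl$k),
               tolerance = 1e-6)
})

test_that("delta filter passes the stimulus channel through; zero filter is flat", {
  stim <- tiny_stim(T = 100, seed = 12)
  spectral <- list(mu = 4, sigma = 0.25) # channel index 4 (0-based)
  # make the Gaussian a near-one-hot on channel 5 (1-based); use the exact
  # weight at the peak, which is 1 by construction
  temporal <- matrix(c(1, rep(0, 24)), 1, 25)
  r <- ln_forward(stim, spectral, temporal)
  w <- popstrf:::gauss_weights(4, 0.25, 18)
  expect_equal(r, as.numeric(w %*% stim$values), tolerance = 1e-12)
  expect_equal(max(w), 1) # peak weight at mu
  # all-zero filter: constant double_exponential(0) everywhere
  r0 <- ln_forward(stim, list(mu = 4, sigma = 1), matrix(0, 1, 25),
                   list(b = 2, a = 5, s = 0.3, k = 1))
  expect_equal(r0, rep(double_exponential(0, 2, 5, 0.3, 1), 100))
})

test_that("conv1d layer equals the composition of its primitive operations", {
  set.seed(13)
  stim <- tiny_stim(T = 150, seed = 13)
  W <- matrix(rnorm(4 * 18), 4, 18)
  taps <- matrix(rnorm(4 * 10), 4, 10)
  off <- rnorm(4)
  got <- conv1d_layer_forward(stim$values, W, taps, off, stim$snippet_starts)
  mixed <- W %*% stim$values
  conved <- popstrf:::cc_conv1d(mixed, taps, stim$snippet_starts)
  expect_equal(got, pmax(conved - off, 0))
  # one-hot weighting + identity tap + disabled rectification passes a row
  W1 <- matrix(0, 1, 18); W1[1, 3] <- 1
  t1 <- matrix(c(1, rep(0, 9)), 1, 10)
  out <- conv1d_layer_forward(stim$values, W1, t1, offsets = NULL,
                              starts = stim$snippet_starts)
  expect_equal(out[1, ], stim$values[3, ])
  # offset above the max pre-activation rectifies everything to zero
  big <- max(conved) + 1
  expect_true(all(conv1d_layer_forward(stim$values, W, taps,
                                       rep(big, 4), stim$snippet_starts) == 0))
})

test_that("conv2d layer: identity kernel, impulse support, zero kernels", {
  set.seed(14)
  F <- 12; T <- 80
  X <- array(abs(rnorm(F * T)), c(1, F, T))
  # identity kernel: single 1 at spectral center, lag 0
  K <- array(0, c(1, 1, 3, 8)); K[1, 1, 2, 1] <- 1
  expect_equal(conv2d_layer_forward(X, K), X)
  # impulse at t0: three stacked 8-tap causal layers support t0..t0+21
  t0 <- 30
  imp <- array(0, c(1, F, T)); imp[1, 6, t0] <- 1
  set.seed(15)
  K1 <- array(rnorm(2 * 1 * 3 * 8), c(2, 1, 3, 8))
  K2 <- array(rnorm(2 * 2 * 3 * 8), c(2, 2, 3, 8))
  K3 <- array(rnorm(1 * 2 * 3 * 8), c(1, 2, 3, 8))
  y <- conv2d_layer_forward(conv2d_layer_forward(
    conv2d_layer_forward(imp, K1), K2), K3)
  nz <- which(apply(abs(y[1, , ]) > 1e-12, 2, any))
  expect_true(all(nz >= t0 & nz <= t0 + 21))
  expect_true((t0 + 21) %in% nz) # full cumulative memory is reachable
  # all-zero kernels with zero offsets
  expect_true(all(conv2d_layer_forward(X, array(0, c(3, 1, 3, 8)),
                                       offsets = rep(0, 3)) == 0))
  # fewer frequency rows than the kernel span is rejected
  expect_error(conv2d_layer_forward(array(1, c(1, 2, 10)), K), "frequency rows")
})

test_that("conv2d forward matches a direct convolution oracle", {
  set.seed(16)
  Cin <- 2; Cout <- 3; F <- 7; T <- 40; KF <- 3; KT <- 8
  A <- array(rnorm(Cin * F * T), c(Cin, F, T))
  K <- array(rnorm(Cout * Cin * KF * KT), c(Cout, Cin, KF, KT))
  starts <- c(1L, 21L)
  got <- conv2d_layer_forward(A, K, starts = starts)
  h <- (KF - 1) / 2
  want <- array(0, c(Cout, F, T))
  for (o in seq_len(Cout)) for (f in seq_len(F)) for (t in seq_len(T)) {
    s0 <- if (t < 21) 1 else 21
    acc <- 0
    for (ci in seq_len(Cin)) for (df in seq_len(KF)) for (dt in seq_len(KT)) {
      fa <- f + df - 1 - h; ta <- t - dt + 1
      if (fa >= 1 && fa <= F && ta >= s0)
        acc <- acc + K[o, ci, df, dt] * A[ci, fa, ta]
    }
    want[o, f, t] <- acc
  }
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("parameter counting follows the declared convention", {
  # first layer of the two-conv-layer population exemplar: 70 Gaussian units
  # (center + width) and 70 15-tap filters
  spec <- exemplar_spec("1Dx2-CNN", n_neurons = 100)
  cp <- count_parameters(spec)
  first_layer <- cp$breakdown[cp$breakdown$layer <= 3, ]
  expect_equal(sum(first_layer$n_params), 70 * 2 + 70 * 15)
  expect_equal(sum(first_layer$n_params), 1190)
  # the temporal component alone is 1050 coefficients
  expect_equal(cp$breakdown$n_params[cp$breakdown$type == "conv"][1], 1050)
  # a full-rank 18 x 25 filter has 450 coefficients
  expect_equal(18 * 25, 450)
  ln18 <- model_spec("LN", rank = 18)
  conv_row <- ln18$layers[[2]]
  expect_equal(conv_row$n_units * conv_row$n_taps, 450)
  # rank-1 LN: 2 (Gaussian) + 25 (taps) + 4 (output nonlinearity)
  expect_equal(count_parameters(model_spec("LN", rank = 1))$total, 31)
  # counting with offsets equals the instantiated parameter vector length
  for (spec_i in list(model_spec("LN", n_neurons = 3, rank = 2),
                      exemplar_spec("single-CNN"),
                      exemplar_spec("pop-LN", 10),
                      exemplar_spec("1D-CNN", 10),
                      exemplar_spec("1Dx2-CNN", 10),
                      exemplar_spec("2D-CNN", 10))) {
    p <- initialize_params(spec_i, n_init = 1, seed = 1)[[1]]
    expect_equal(length(pack_params(spec_i, p)),
                 count_parameters(spec_i, count_offsets = TRUE)$total)
  }
})

test_that("forward passes are deterministic and causal", {
  stim <- tiny_stim(T = 120, seed = 17)
  for (spec in list(model_spec("pop-LN", n_neurons = 3, n_units = 4),
                    model_spec("1Dx2-CNN", n_neurons = 2, n_units1 = 3,
                               n_units2 = 3, hidden = 3),
                    model_spec("2D-CNN", n_neurons = 2, n_conv_units = 2,
                               hidden = 3))) {
    p <- initialize_params(spec, n_init = 2, seed = 19)[[1]]
    y1 <- model_forward(spec, p, stim)
    y2 <- model_forward(spec, p, stim)
    expect_identical(y1, y2)
    # perturb the stimulus at bin t: predictions strictly before t unchanged
    t_hit <- 60
    stim2 <- stim
    stim2$values[5, t_hit] <- stim2$values[5, t_hit] + 10
    y3 <- model_forward(spec, p, stim2)
    expect_equal(y3[, seq_len(t_hit - 1)], y1[, seq_len(t_hit - 1)])
    expect_false(isTRUE(all.equal(y3, y1)))
  }
})

test_that("architecture reductions: single-CNN(1) and pop-LN(N=1) equal rank-1 LN", {
  stim <- tiny_stim(T = 150, seed = 21)
  spectral <- list(mu = 7.3, sigma = 1.8)
  taps <- matrix(rnorm(25), 1, 25)
  nl <- list(b = 1.5, a = 20, s = 0.2, k = 0.9)
  r_ln <- ln_forward(stim, spectral, taps, nl)
  # pop-LN with one unit, N = 1, readout weight 1
  spec_pl <- model_spec("pop-LN", n_neurons = 1, n_units = 1)
  p_pl <- list(list(mu = spectral$mu, sigma = spectral$sigma),
               list(taps = taps),
               list(W = matrix(1, 1, 1)),
               list(b = nl$b, a = nl$a, s = nl$s, k = nl$k))
  expect_equal(as.numeric(population_forward(stim, spec_pl, p_pl)), r_ln,
               tolerance = 1e-12)
  # single-CNN with one unit: pick a rectification offset below the minimum
  # pre-activation and absorb it in the output threshold
  pre <- popstrf:::cc_conv1d(
    popstrf:::gauss_weights(spectral$mu, spectral$sigma, 18) %*% stim$values,
    taps, stim$snippet_starts)
  off <- min(pre) - 1
  spec_sc <- model_spec("single-CNN", n_units = 1)
  p_sc <- list(list(mu = spectral$mu, sigma = spectral$sigma),
               list(taps = taps),
               list(offset = off),
               list(W = matrix(1, 1, 1)),
               list(b = nl$b, a = nl$a, s = nl$s - off, k = nl$k))
  expect_equal(as.numeric(model_forward(spec_sc, p_sc, stim)), r_ln,
               tolerance = 1e-9)
})

test_that("LN spec with N > 1 batches independent per-neuron models", {
  stim <- tiny_stim(T = 100, seed = 22)
  spec2 <- model_spec("LN", n_neurons = 2, rank = 2)
  p <- initialize_params(spec2, n_init = 2, seed = 23, rate_scale = 5)[[1]]
  y <- model_forward(spec2, p, stim)
  # neuron 1 alone, using its own slice of parameters
  spec1 <- model_spec("LN", n_neurons = 1, rank = 2)
  p1 <- list(list(mu = p[[1]]$mu[1:2], sigma = p[[1]]$sigma[1:2]),
             list(taps = p[[2]]$taps[1:2, , drop = FALSE]),
             list(),
             list(b = p[[4]]$b[1], a = p[[4]]$a[1], s = p[[4]]$s[1],
                  k = p[[4]]$k[1]))
  expect_equal(as.numeric(model_forward(spec1, p1, stim)), y[1, ])
})

test_that("a rank-F stage with free spectral weights reproduces any full filter", {
  set.seed(24)
  stim <- tiny_stim(T = 120, seed = 24)
  h <- matrix(rnorm(18 * 25), 18, 25)
  # free (identity) channel weights, one unit per channel, taps = filter rows
  out <- conv1d_layer_forward(stim$values, diag(18), h, offsets = NULL,
                              starts = stim$snippet_starts)
  r_rank <- colSums(out)
  r_full <- brute_force_rlin(stim$values, h, stim$snippet_starts)
  expect_equal(r_rank, r_full, tolerance = 1e-8)
})

test_that("population forward matches manual layer-by-layer composition", {
  stim <- tiny_stim(T = 130, seed = 25)
  spec <- model_spec("1Dx2-CNN", n_neurons = 4, n_units1 = 5, n_units2 = 4,
                     hidden = 3)
  p <- initialize_params(spec, n_init = 2, seed = 26, rate_scale = 3)[[1]]
  y <- population_forward(stim, spec, p)
  st <- stim$snippet_starts
  h1 <- conv1d_layer_forward(stim$values, list(mu = p[[1]]$mu, sigma = p[[1]]$sigma),
                             p[[2]]$taps, p[[3]]$offset, st)
  h2 <- conv1d_layer_forward(h1, p[[4]]$W, p[[5]]$taps, p[[6]]$offset, st)
  h3 <- pmax(p[[7]]$W %*% h2 - p[[8]]$offset, 0)
  y_manual <- double_exponential(p[[9]]$W %*% h3, p[[10]]$b, p[[10]]$a,
                                 p[[10]]$s, p[[10]]$k)
  expect_equal(y, y_manual, tolerance = 1e-12)
  # duplicating a readout row duplicates the predicted row
  p2 <- p
  p2[[9]]$W[2, ] <- p2[[9]]$W[1, ]
  p2[[10]]$b[2] <- p2[[10]]$b[1]; p2[[10]]$a[2] <- p2[[10]]$a[1]
  p2[[10]]$s[2] <- p2[[10]]$s[1]; p2[[10]]$k[2] <- p2[[10]]$k[1]
  y2 <- population_forward(stim, spec, p2)
  expect_equal(y2[1, ], y2[2, ])
})

test_that("parameter vectors round-trip through pack/unpack", {
  spec <- model_spec("2D-CNN", n_neurons = 3, n_conv_units = 2, hidden = 4)
  p <- initialize_params(spec, n_init = 3, seed = 31)[[2]]
  v <- pack_params(spec, p)
  p2 <- unpack_params(spec, v)
  expect_equal(p, p2)
  expect_error(unpack_params(spec, v[-1]), "length")
})
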