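test_that("TTRC: identical trials, two-trial case, pair exclusion", {
  set.seed(71)
  s <- abs(rnorm(100))
  # M identical nonconstant trials
  expect_equal(as.numeric(ttrc(cbind(s, s, s))), 1.0)
  # M = 2 equals the single pair correlation exactly
  x2 <- cbind(s + rnorm(100), s + rnorm(100))
  expect_equal(as.numeric(ttrc(x2)), cor(x2[, 1], x2[, 2]))
  # symmetry in trial order
  expect_equal(as.numeric(ttrc(x2[, 2:1])), as.numeric(ttrc(x2)))
  # zero-variance trials: pairs excluded and counted
  x3 <- cbind(s, rep(1, 100), s + rnorm(100))
  t3 <- ttrc(x3)
  expect_equal(attr(t3, "n_excluded"), 2)
  expect_equal(as.numeric(t3), cor(x3[, 1], x3[, 3]))
  # all pairs excluded
  expect_true(is.na(ttrc(cbind(rep(1, 10), rep(2, 10)))))
  expect_error(ttrc(matrix(1, 5, 1)), "2 repeats")
})

test_that("TTRC estimates the signal-variance fraction", {
  set.seed(72)
  for (q in c(0.3, 0.6)) {
    est <- replicate(120, {
      s <- rnorm(400)
      x <- s + matrix(rnorm(400 * 20), 400, 20) * sqrt((1 - q) / q)
      as.numeric(ttrc(x))
    })
    expect_equal(mean(est), q, tolerance = 0.02)
  }
})

test_that("R_norm: noise-free equality, chance level, affine invariance", {
  set.seed(73)
  s <- abs(rnorm(300))
  pred <- s + rnorm(300, 0, 0.3)
  # identical trials: equals raw Pearson correlation exactly
  x <- cbind(s, s, s, s)
  expect_equal(noise_corrected_correlation(x, pred), cor(s, pred))
  # prediction equal to the trials' common signal scores exactly 1
  expect_equal(noise_corrected_correlation(x, s), 1.0)
  # invariant to positive affine rescaling of the prediction
  xn <- s + matrix(rnorm(300 * 10), 300, 10)
  expect_equal(noise_corrected_correlation(xn, pred),
               noise_corrected_correlation(xn, 3.2 * pred + 7))
  # independent prediction: expectation zero
  est <- replicate(200, noise_corrected_correlation(xn, rnorm(300)))
  expect_equal(mean(est), 0, tolerance = 0.02)
  # degenerate inputs flagged as NA
  expect_true(is.na(noise_corrected_correlation(xn, rep(1, 300))))
  low <- matrix(rnorm(300 * 4), 300, 4) # TTRC near zero
  expect_true(is.na(noise_corrected_correlation(low, pred)))
})

test_that("R_norm approaches 1 for the true signal at any noise level", {
  set.seed(74)
  for (q in c(0.25, 0.7)) {
    est <- replicate(100, {
      s <- rnorm(600)
      x <- s + matrix(rnorm(600 * 20), 600, 20) * sqrt((1 - q) / q)
      noise_corrected_correlation(x, s)
    })
    expect_equal(mean(est), 1, tolerance = 0.02)
  }
})

test_that("equivalence is a plain symmetric correlation", {
  set.seed(75)
  a <- rnorm(200); b <- a + rnorm(200)
  expect_equal(equivalence(a, a), 1.0)
  expect_equal(equivalence(a, -a), -1.0)
  expect_equal(equivalence(a, b), equivalence(b, a))
  # arithmetic oracle from summary sums
  n <- length(a)
  r_manual <- (sum(a * b) - n * mean(a) * mean(b)) /
    ((n - 1) * sd(a) * sd(b))
  expect_equal(equivalence(a, b), r_manual)
  expect_true(is.na(equivalence(rep(1, 10), rnorm(10))))
  expect_error(equivalence(a, b[-1]), "equal length")
})

test_that("SNR estimates the signal-variance fraction", {
  set.seed(76)
  s <- abs(rnorm(400)) * 10
  expect_equal(snr_fraction(cbind(s, s, s)), 1.0)
  # pure noise around a constant signal
  null_est <- replicate(150, snr_fraction(matrix(rnorm(200 * 20), 200, 20)))
  expect_equal(mean(null_est), 0, tolerance = 0.02)
  expect_equal(snr_fraction(matrix(5, 100, 4)), 0)
  # recovery of q across the range
  for (q in c(0.1, 0.3, 0.7)) {
    est <- replicate(200, {
      sig <- rnorm(300)
      snr_fraction(sig + matrix(rnorm(300 * 20), 300, 20) * sqrt((1 - q) / q))
    })
    expect_equal(mean(est), q, tolerance = 0.05)
  }
})

test_that("jackknifed above-chance test: power, null p, paired self-comparison", {
  set.seed(77)
  s <- sin(seq_len(400) / 10) * 20 + 25
  x <- s + matrix(rnorm(400 * 10), 400, 10)
  # self-prediction on a strongly modulated neuron is significant
  jt <- jackknife_above_chance(x, s)
  expect_lt(jt$p, 0.05)
  expect_equal(jt$n_folds, 20)
  # paired comparison of a model with itself is never significant
  jp <- jackknife_above_chance(x, s, prediction_b = s)
  expect_equal(jp$p, 1)
  # short series reduce the fold count with a warning
  expect_warning(jackknife_above_chance(rnorm(30), rnorm(30)), "reduced")
})

test_that("jackknifed test is calibrated under the null", {
  set.seed(78)
  p <- replicate(400, {
    jackknife_above_chance(rnorm(300), rnorm(300))$p
  })
  rate <- mean(p < 0.05)
  # 95% binomial interval around 0.05 at 400 draws
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})

test_that("responsive subset is the intersection of above-chance sets", {
  sc <- tibble::tibble(
    neuron_id = rep(c("a", "b", "c", "d"), 3),
    site_id = "s1",
    model_id = rep(c("m1", "m2", "m3"), each = 4),
    p_above_chance = c(0.01, 0.2, 0.01, 0.04,   # m1
                       0.02, 0.01, 0.03, 0.2,   # m2
                       0.01, 0.01, 0.04, 0.01)) # m3
  got <- responsive_subset(sc, c("m1", "m2", "m3"))
  # brute-force set intersection oracle
  want <- Reduce(intersect, lapply(c("m1", "m2", "m3"), function(m) {
    sc$neuron_id[sc$model_id == m & sc$p_above_chance < 0.05]
  }))
  expect_setequal(got, want)
  expect_setequal(got, c("a", "c"))
  # one model never significant: empty set
  sc2 <- sc; sc2$p_above_chance[sc2$model_id == "m2"] <- 0.5
  expect_length(responsive_subset(sc2), 0)
  # all significant: full set
  sc3 <- sc; sc3$p_above_chance <- 0.001
  expect_setequal(responsive_subset(sc3), c("a", "b", "c", "d"))
  expect_error(responsive_subset(sc, c("m1", "m9")), "missing")
})

test_that("rank tests agree with closed-form rank-statistic distributions", {
  set.seed(79)
  # signed-rank statistic and exact p from psignrank; U statistic from pwilcox
  for (rep_i in 1:25) {
    n <- 12
    a <- rnorm(n); b <- rnorm(n)
    names(a) <- names(b) <- paste0("n", seq_len(n))
    res <- suppressWarnings(compare_populations(a, b, paired = TRUE))
    d <- a - b
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    p_exact <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
    expect_equal(res$statistic, W)
    expect_equal(res$p_value, p_exact, tolerance = 1e-10)
    res_u <- compare_populations(a, b, paired = FALSE)
    U <- sum(rank(c(a, b))[seq_len(n)]) - n * (n + 1) / 2
    p_u <- min(1, 2 * min(pwilcox(U, n, n), 1 - pwilcox(U - 1, n, n)))
    expect_equal(res_u$statistic, U)
    expect_equal(res_u$p_value, p_u, tolerance = 1e-10)
  }
  # identical paired samples carry no signal
  x <- rnorm(20); names(x) <- paste0("n", 1:20)
  res_id <- suppressWarnings(compare_populations(x, x, paired = TRUE))
  expect_true(is.na(res_id$p_value) || res_id$p_value > 0.9)
  # shifted distributions are detected with high power
  set.seed(80)
  y1 <- rnorm(200); y2 <- rnorm(200) + 1
  expect_lt(compare_populations(y1, y2, paired = FALSE)$p_value, 0.01)
})
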