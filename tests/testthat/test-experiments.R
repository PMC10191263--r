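test_that("held-out plans partition neurons across sites", {
  ds <- small_dataset()
  sites <- unique(ds$est_raster$site_ids)
  plans <- lapply(sites, function(s) plan_heldout(ds, s))
  # every neuron is excluded in exactly one plan
  all_excluded <- unlist(lapply(plans, `[[`, "excluded"))
  expect_setequal(all_excluded, ds$est_raster$neuron_ids)
  expect_equal(anyDuplicated(all_excluded), 0)
  for (p in plans) {
    expect_length(intersect(p$excluded, p$stage1), 0)
    expect_setequal(c(p$excluded, p$stage1), ds$est_raster$neuron_ids)
  }
  expect_error(plan_heldout(ds, "nowhere"), "unknown site")
  # single-site dataset: empty stage-1 population is rejected
  one_site <- dataset_subset_neurons(
    ds, ds$est_raster$neuron_ids[ds$est_raster$site_ids == sites[1]])
  expect_error(plan_heldout(one_site, sites[1]), "outside")
})

test_that("matched plans greedily pair baseline scores", {
  ds <- small_dataset()
  ids <- ds$est_raster$neuron_ids
  sites <- ds$est_raster$site_ids
  s1_ids <- ids[sites == "site1"]
  off_ids <- ids[sites != "site1"]
  # off-site scores identical to site scores: matched multiset equals the
  # site's score multiset
  scores <- setNames(numeric(length(ids)), ids)
  scores[s1_ids] <- seq(0.1, 0.6, length.out = length(s1_ids))
  scores[off_ids] <- c(seq(0.1, 0.6, length.out = length(s1_ids)),
                       rep(99, length(off_ids) - length(s1_ids)))
  plan <- plan_matched(ds, "site1", scores)
  expect_length(plan$excluded, length(s1_ids))
  expect_true(all(plan$excluded %in% off_ids))
  expect_equal(sort(scores[plan$excluded]), sort(scores[s1_ids]),
               ignore_attr = TRUE)
  # greedy matching beats random exclusion on mean absolute score gap
  set.seed(91)
  wins <- replicate(60, {
    sc <- setNames(runif(length(ids)), ids)
    pl <- plan_matched(ds, "site1", sc)
    gap_greedy <- mean(abs(sort(sc[pl$excluded]) - sort(sc[s1_ids])))
    rnd <- sample(off_ids, length(s1_ids))
    gap_rand <- mean(abs(sort(sc[rnd]) - sort(sc[s1_ids])))
    gap_greedy <= gap_rand + 1e-12
  })
  expect_gt(mean(wins), 0.9)
  # more site neurons than the off-site pool is an error
  big_site <- dataset_subset_neurons(ds, ids[c(which(sites == "site1"),
                                               which(sites != "site1")[1:2])])
  expect_error(plan_matched(big_site, "site1", scores), "fewer off-site")
  expect_error(plan_matched(ds, "site1", scores[-1]), "cover every neuron")
})

test_that("held-out and matched protocols exclude equally many neurons", {
  ds <- small_dataset()
  ids <- ds$est_raster$neuron_ids
  scores <- setNames(seq_along(ids) / length(ids), ids)
  for (s in unique(ds$est_raster$site_ids)) {
    ph <- plan_heldout(ds, s)
    pm <- plan_matched(ds, s, scores)
    expect_equal(length(ph$excluded), length(pm$excluded))
    # matched never excludes site-S neurons
    expect_length(intersect(pm$excluded, ph$excluded), 0)
    expect_length(ph$stage1, length(pm$stage1))
  }
})

test_that("SNR-matched subsets equalize binned distributions", {
  # identical populations: full subsets
  a <- setNames(seq(0.1, 0.9, length.out = 20), paste0("a", 1:20))
  b <- setNames(seq(0.1, 0.9, length.out = 20), paste0("b", 1:20))
  got <- snr_matched_subsets(a, b)
  expect_length(got$a, 20)
  expect_length(got$b, 20)
  # disjoint ranges: empty subsets with a warning
  hi <- setNames(seq(0.8, 0.9, length.out = 10), paste0("h", 1:10))
  lo <- setNames(seq(0.05, 0.12, length.out = 10), paste0("l", 1:10))
  expect_warning(got2 <- snr_matched_subsets(hi, lo, n_bins = 5), "overlap")
  expect_length(got2$a, 0)
  # extra high-SNR mass on one side is excluded from its top bins
  set.seed(92)
  a3 <- setNames(c(runif(30, 0.1, 0.5), runif(30, 0.5, 0.95)), paste0("a", 1:60))
  b3 <- setNames(runif(40, 0.1, 0.5), paste0("b", 1:40))
  got3 <- snr_matched_subsets(a3, b3)
  dropped <- setdiff(names(a3), got3$a)
  expect_gt(mean(a3[dropped]), mean(a3))
  # binned distributions are identical by construction
  edges <- seq(min(c(a3, b3)), max(c(a3, b3)), length.out = 21)
  ha <- hist(a3[got3$a], breaks = edges, plot = FALSE)$counts
  hb <- hist(b3[got3$b], breaks = edges, plot = FALSE)$counts
  expect_equal(ha, hb)
})

test_that("estimation-snippet subsetting is exact and deterministic", {
  ds <- small_dataset()
  sub <- dataset_subset_est_snippets(ds, c(2, 5, 9, 10, 11))
  expect_length(sub$est_stim$snippet_starts, 5)
  expect_equal(ncol(sub$est_stim$values), 5 * 110)
  # columns of snippet 2 appear at the front
  expect_equal(sub$est_stim$values[, 1:110],
               ds$est_stim$values[, 111:220])
  expect_equal(sub$est_raster$rates[, 1:110, ],
               ds$est_raster$rates[, 111:220, ])
  # validation untouched
  expect_identical(sub$val_stim, ds$val_stim)
  expect_error(dataset_subset_est_snippets(ds, c(0, 1)), "out of range")
})

test_that("cross-population transfer validates stimulus identity", {
  ds <- small_dataset()
  other <- simulate_dataset(n_neurons = 6, subspace_dim = 2, n_sites = 1,
                            n_est_snippets = 30, n_val_snippets = 6, seed = 99)
  spec <- model_spec("pop-LN", n_neurons = 12, n_units = 4)
  expect_error(run_cross_population(ds, other, spec, fast_config()),
               "share the estimation stimulus")
})
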