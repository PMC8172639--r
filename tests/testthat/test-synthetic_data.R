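test_that("bursting counts follow the negative binomial implied by f, b and tau", {
  # f = 1/2.8, b = 1, tau = 2.8 -> r = 1, p = 1/2, mean r*b = 1
  set.seed(101)
  cts <- simulate_rna_counts(1 / 2.8, 1, 2.8, 1e5)
  se <- sd(cts) / sqrt(length(cts))
  expect_lt(abs(mean(cts) - 1), 3 * se)
  # vanishing burst size: essentially all-zero counts
  set.seed(102)
  expect_lt(mean(simulate_rna_counts(1, 1e-6, 2.8, 1e4)), 1e-3)
  # determinism under a fixed seed
  set.seed(7); a <- simulate_rna_counts(0.5, 3, 2.8, 100)
  set.seed(7); b <- simulate_rna_counts(0.5, 3, 2.8, 100)
  expect_identical(a, b)
  expect_error(simulate_rna_counts(0, 1), "> 0")
  expect_error(simulate_rna_counts(1, -1), "> 0")
})

test_that("binomial thinning matches its closed-form mean, variance and Fano factor", {
  expect_identical(thin_counts(c(0L, 3L, 7L), 1), c(0L, 3L, 7L))
  expect_identical(thin_counts(rep(0L, 10), 0.4), rep(0L, 10))
  expect_error(thin_counts(c(1L, 2L), 0), "efficiency")
  expect_error(thin_counts(c(1L, 2L), 1.2), "efficiency")
  expect_error(thin_counts(c(1.5, 2), 0.5), "integer")

  # NB(r = 5, p = 0.5): mu = 5, var = 10, Fano 2; thinned at 1/2 the
  # predictions are E = 2.5, Var = 5*0.5*0.5 + 0.25*10 = 3.75, Fano 1.5
  set.seed(103)
  lat <- rnbinom(1e5, size = 5, prob = 0.5)
  y <- thin_counts(lat, 0.5)
  pred <- thinning_predictions(5, 10, 0.5)
  expect_lt(abs(mean(y) - pred$mean), 3 * block_se(y, mean))
  expect_lt(abs(var(y) - pred$variance), 3 * block_se(y, var))
  expect_lt(abs(fano_factor(y) - pred$fano),
            3 * block_se(y, function(b) var(b) / mean(b)))
  expect_true(all(y <= lat))
})

test_that("mean and Fano-1 of thinned counts scale linearly with efficiency", {
  # ratio identity against a perfect-efficiency reference method
  set.seed(104)
  lat <- rnbinom(5e4, size = 2, mu = 12)
  fano_lat <- fano_factor(lat)
  for (eps in c(0.3, 0.6)) {
    y <- thin_counts(lat, eps)
    expect_equal(mean(y) / mean(lat), eps, tolerance = 0.03)
    expect_equal((fano_factor(y) - 1) / (fano_lat - 1), eps, tolerance = 0.08)
  }
})

test_that("simulated protein signals reduce to the Hill curve without noise", {
  hill <- list(offset = 0.1, A = 2, K_half = 20, n = 1.5)
  expect_equal(simulate_protein(40, hill, 5, cv = 0),
               rep(hill_function(40, 0.1, 2, 20, 1.5), 5))
  hill0 <- list(offset = 0, A = 2, K_half = 20, n = 1.5)
  expect_equal(simulate_protein(20, hill0, 3, cv = 0), rep(1, 3))  # A/2
  expect_equal(simulate_protein(0, hill, 3, cv = 0), rep(0.1, 3))  # offset
  expect_error(simulate_protein(10, list(offset = 0, A = -1, K_half = 2,
                                         n = 1), 3), "Hill")
})

test_that("a simulated experiment covers all methods, samples and replicates deterministically", {
  cfg <- small_sim(n_replicates = 2L)
  df <- simulate_experiment(cfg, seed = 11)
  key <- paste(df$preparation, df$detection, df$measurand, df$construct,
               df$iptg_umol_per_L, df$replicate)
  expect_equal(length(unique(key)), 12 * 10 * 2)
  # cell numbers per detection
  expect_true(all(table(key[df$detection == "flow"]) == 300))
  expect_true(all(table(key[df$detection == "microscopy"]) == 150))
  # microscopy rows carry DAPI, flow rows do not
  expect_true(all(!is.na(df$dapi[df$detection == "microscopy"])))
  expect_true(all(is.na(df$dapi[df$detection == "flow"])))
  # bit-identical on re-run with the same seed
  expect_identical(df, simulate_experiment(cfg, seed = 11))
  expect_false(identical(df, simulate_experiment(cfg, seed = 12)))
})

test_that("equal hybridization efficiencies make FISH and HCR counts exchangeable", {
  cfg <- small_sim(n_replicates = 1L, eff_fish = 0.8, eff_hcr = 0.8,
                   frac_poor_permeabilized = 0)
  df <- simulate_experiment(cfg, seed = 21)
  cts <- df[df$measurand == "rna_count" & df$construct == "inducible" &
            df$iptg_umol_per_L == 1000, ]
  a <- cts$signal[cts$preparation == "FISH"]
  b <- cts$signal[cts$preparation == "HCR"]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
})

test_that("measurands of one route observe the same cells and labeling outcome", {
  # with unit brightness and all noise layers off, whole-cell RNA
  # fluorescence must equal the RNA count table cell for cell
  cfg <- small_sim(n_replicates = 1L, brightness = 1, cv_brightness = 0,
                   cv_detection = list(flow = 0, microscopy = 0),
                   background = list(flow = c(mean = 0, sd = 0),
                                     microscopy = c(mean = 0, sd = 0)))
  df <- simulate_experiment(cfg, seed = 31)
  sub <- df[df$preparation == "FISH" & df$detection == "microscopy" &
            df$construct == "inducible" & df$iptg_umol_per_L == 100, ]
  expect_equal(sub$signal[sub$measurand == "rna_fluorescence"],
               sub$signal[sub$measurand == "rna_count"])
})

test_that("median simulated protein signal is non-decreasing in the stimulus", {
  # noise-free: medians equal the Hill curve exactly, hence monotone
  cfg0 <- small_sim(n_replicates = 1L, cv_protein = 0,
                    cv_detection = list(flow = 0, microscopy = 0),
                    background = list(flow = c(mean = 0, sd = 0),
                                      microscopy = c(mean = 0, sd = 0)))
  df0 <- simulate_experiment(cfg0, seed = 41)
  sub0 <- df0[df0$preparation == "Kn" & df0$measurand == "protein" &
              df0$construct == "inducible", ]
  med0 <- tapply(sub0$signal, sub0$iptg_umol_per_L, median)
  med0 <- med0[order(as.numeric(names(med0)))]
  expect_true(all(diff(med0) >= 0))
  # with cell-to-cell noise the trend still holds within sampling error
  df <- simulate_experiment(small_sim(n_replicates = 1L), seed = 41)
  sub <- df[df$preparation == "Kn" & df$measurand == "protein" &
            df$construct == "inducible", ]
  med <- tapply(sub$signal, sub$iptg_umol_per_L, median)
  med <- med[order(as.numeric(names(med)))]
  expect_true(all(diff(med) > -0.05 * med[-1]))
  expect_gt(med[[8]], med[[1]])
})
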