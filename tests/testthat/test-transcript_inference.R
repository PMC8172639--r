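test_that("the Fano factor uses the n-1 sample variance over the mean", {
  expect_equal(fano_factor(rep(7, 10)), 0)
  expect_equal(fano_factor(c(0, 0, 4, 4)), (16 / 3) / 2)  # 8/3
  set.seed(501)
  x <- rpois(1e5, 5)
  expect_lt(abs(fano_factor(x) - 1),
            3 * block_se(x, function(b) var(b) / mean(b)))
  expect_error(fano_factor(c(0, 0, 0)), "mean")
  expect_error(fano_factor(3), "2 observations")
})

test_that("thinning predictions implement the closed forms exactly", {
  p1 <- thinning_predictions(10, 30, 1)
  expect_equal(c(p1$mean, p1$variance, p1$fano), c(10, 30, 3))
  p2 <- thinning_predictions(10, 30, 0.5)
  expect_equal(c(p2$mean, p2$variance, p2$fano), c(5, 10, 2))
  # thinned Poisson stays Poisson: Fano 1 for every p
  for (p in c(0.2, 0.7, 1)) {
    expect_equal(thinning_predictions(6, 6, p)$fano, 1)
  }
  expect_error(thinning_predictions(0, 1, 0.5), "mu")
  expect_error(thinning_predictions(1, 1, 0), "p must")
})

test_that("negative-binomial maximum likelihood recovers known parameters", {
  set.seed(5)
  cts <- rnbinom(5000, size = 2, prob = 0.4)
  fit <- fit_negative_binomial(cts)
  expect_equal(fit$status, "ok")
  expect_true(fit$r > 1.7 && fit$r < 2.3)
  expect_true(fit$p_nb > 0.34 && fit$p_nb < 0.46)
  expect_true(fit$r_ci[1] < 2 && 2 < fit$r_ci[2])
  # MLE log-likelihood dominates the moments estimate
  m <- mean(cts); v <- var(cts)
  r0 <- m^2 / (v - m); p0 <- m / v
  expect_gte(fit$loglik, nb_loglik(cts, r0, p0))
  # underdispersed counts hit the Poisson-like boundary
  under <- rep(c(3L, 4L), each = 5)
  fb <- fit_negative_binomial(under)
  expect_equal(fb$status, "poisson_boundary")
  expect_equal(fb$r, 1e4)
  expect_error(fit_negative_binomial(rep(0L, 20)), "zero")
  expect_error(fit_negative_binomial(0:5), "10 counts")
})

test_that("the MLE beats a likelihood grid around the moments estimate", {
  for (seed in 1:3) {
    set.seed(seed)
    cts <- rnbinom(400, size = 1.5, mu = 8)
    fit <- fit_negative_binomial(cts)
    m <- mean(cts); v <- var(cts)
    r_grid <- exp(seq(log(m^2 / (v - m)) - 1.5, log(m^2 / (v - m)) + 1.5,
                      length.out = 120))
    best_grid <- max(vapply(r_grid, function(r) {
      nb_loglik(cts, r, r / (r + m))
    }, numeric(1)))
    expect_gte(fit$loglik, best_grid - 1e-6)
  }
})

test_that("burst parameters derive from the NB fit, with efficiency scaling size only", {
  bp <- burst_parameters(1, 0.5, 2.8, 1)
  expect_equal(bp$burst_frequency, 1 / 2.8)
  expect_equal(bp$burst_size, 1)
  expect_equal(bp$corrected_burst_size, 1)
  bp2 <- burst_parameters(1, 0.5, 2.8, 0.5)
  expect_equal(bp2$corrected_burst_size, 2)
  expect_equal(bp2$burst_frequency, bp$burst_frequency)  # never modified
  expect_lt(burst_parameters(1, 0.999)$burst_size, 0.002)
  expect_error(burst_parameters(-1, 0.5), "r must")
  expect_error(burst_parameters(1, 1), "p_nb")
  expect_error(burst_parameters(1, 0.5, efficiency = 0), "efficiency")
})

test_that("thinned fits keep the burst frequency and scale burst size with efficiency", {
  set.seed(502)
  lat <- simulate_rna_counts(0.5, 4, 2.8, 5000)  # r = 1.4
  f_lat <- fit_negative_binomial(lat)
  eps <- c(0.3, 0.6, 1.0)
  b_hat <- vapply(eps, function(e) {
    f <- fit_negative_binomial(thin_counts(lat, e))
    # same r within CI (the NB is closed under binomial thinning)
    expect_true(f$r_ci[1] <= f_lat$r_ci[2] && f_lat$r_ci[1] <= f$r_ci[2])
    (1 - f$p_nb) / f$p_nb
  }, numeric(1))
  expect_gt(summary(lm(b_hat ~ eps))$r.squared, 0.99)
})

test_that("the efficiency-ratio estimator pools mean and Fano-1 ratios correctly", {
  set.seed(503)
  tabs <- lapply(1:4, function(i) rnbinom(300, size = 2, mu = 4 * i))
  names(tabs) <- paste0("s", 1:4)
  est <- efficiency_ratio(tabs, tabs, n_boot = 50, seed = 1)
  expect_equal(est$overall_ratio, 1)
  expect_true(all(est$per_sample$ratio[!est$per_sample$excluded] == 1))
  expect_equal(est$absolute_efficiency, 0.95)

  # a sample with Fano < 1 loses its Fano ratio but keeps its mean ratio
  a <- tabs
  a$s1 <- rep(c(2L, 3L), 150)          # Fano well below 1
  est2 <- efficiency_ratio(a, tabs, n_boot = 50, seed = 2)
  ps <- est2$per_sample
  expect_true(ps$excluded[ps$sample == "s1" & ps$type == "fano"])
  expect_false(ps$excluded[ps$sample == "s1" & ps$type == "mean"])
  expect_error(efficiency_ratio(list(a = 1:3), list(b = 1:3)), "matched")
})

test_that("matched thinned tables recover the true efficiency ratio", {
  set.seed(504)
  fish <- list(); hcr <- list()
  for (i in 1:6) {
    lat <- rnbinom(400, size = 1.5, mu = 3 + 5 * i)
    fish[[paste0("s", i)]] <- thin_counts(lat, 0.95)
    hcr[[paste0("s", i)]] <- thin_counts(lat, 0.341)
  }
  est <- efficiency_ratio(hcr, fish, n_boot = 300, seed = 3)
  truth <- 0.341 / 0.95
  expect_true(est$overall_ci[1] <= truth && truth <= est$overall_ci[2])
  expect_equal(est$overall_ratio, truth, tolerance = 0.15)
})

test_that("the two-lognormal spot mixture separates specific from background spots", {
  set.seed(505)
  lower <- rlnorm(600, meanlog = 1, sdlog = 0.4)
  upper <- rlnorm(1400, meanlog = 4, sdlog = 0.4)
  mix <- sample(c(lower, upper))
  fit <- spot_intensity_mixture(mix, threshold = exp(2.5))
  expect_equal(fit$weight_upper, 0.7, tolerance = 0.05)
  expect_lt(fit$meanlog[1], 2.5)
  expect_gt(fit$meanlog[2], 2.5)
  expect_gt(fit$specific_fraction, 0.9)  # bright spots carry the intensity

  # mirrored mixture: weights swap
  mix2 <- sample(c(rlnorm(1400, 1, 0.4), rlnorm(600, 4, 0.4)))
  fit2 <- spot_intensity_mixture(mix2, threshold = exp(2.5))
  expect_equal(fit2$weight_upper, 0.3, tolerance = 0.05)

  # everything below the threshold: degenerate, no specific signal
  low_only <- rlnorm(500, 1, 0.3)
  fit3 <- spot_intensity_mixture(low_only, threshold = max(low_only) * 2)
  expect_equal(fit3$status, "degenerate")
  expect_equal(fit3$specific_fraction, 0)
  expect_error(spot_intensity_mixture(rlnorm(10, 1, 1), 2), "50 spots")
})
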