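#' Fano factor of a count distribution
#'
#' Sample variance (n - 1 denominator) divided by the sample mean.  Equals 1
#' for a Poisson distribution; under binomial thinning with efficiency `p`,
#' `Fano - 1` scales linearly with `p`.
#'
#' @param counts non-negative numeric vector (>= 2 values, positive mean).
#' @return the Fano factor.
#' @export
fano_factor <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 observations")
  m <- mean(counts)
  if (m <= 0) stop("Fano factor undefined: mean is zero")
  stats::var(counts) / m
}

#' Moments of binomially thinned counts
#'
#' If the latent per-cell molecule number has mean `mu` and variance
#' `sigma2`, and each molecule is detected independently with probability
#' `p`, the observed count Y satisfies `E(Y) = mu p`,
#' `Var(Y) = mu p (1 - p) + p^2 sigma2` and
#' `Fano(Y) = 1 + p (sigma2 / mu - 1)`.
#'
#' @param mu latent mean (> 0).
#' @param sigma2 latent variance (>= 0).
#' @param p detection probability in (0, 1].
#' @return list with `mean`, `variance`, `fano`.
#' @export
thinning_predictions <- function(mu, sigma2, p) {
  if (mu <= 0) stop("mu must be > 0")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  list(mean = mu * p,
       variance = mu * p * (1 - p) + p^2 * sigma2,
       fano = 1 + p * (sigma2 / mu - 1))
}

#' Maximum-likelihood negative-binomial fit to RNA counts
#'
#' Fits `P(n) = choose(n + r - 1, n) p^r (1 - p)^n` with continuous `r > 0`
#' by maximum likelihood (the MLE of the mean equals the sample mean for any
#' `r`, so the fit profiles the likelihood over `log r`).  Initialization is
#' by moments (`p0 = m / v`, `r0 = m^2 / (v - m)`).  Underdispersed samples
#' (variance <= mean) return a boundary result flagged `"poisson_boundary"`
#' with `r` capped at 1e4 and `p = r / (r + m)`.
#'
#' @param counts non-negative integer vector (n >= 10, not all zero).
#' @return object of class `"nb_fit"`: `r`, `p_nb`, `mu`, `loglik`,
#'   `status`, `r_ci` (95% Wald interval on the log scale), `se_log_r`, `n`.
#' @export
fit_negative_binomial <- function(counts) {
  if (!is_count_vector(counts)) stop("counts must be non-negative integers")
  n <- length(counts)
  if (n < 10L) stop("need at least 10 counts")
  m <- mean(counts)
  if (m == 0) stop("all counts are zero: no information on burst parameters")
  v <- stats::var(counts)
  if (v <= 0) stop("zero variance: no information on burst parameters")
  ll <- function(logr) sum(stats::dnbinom(counts, size = exp(logr),
                                          mu = m, log = TRUE))
  if (v <= m) {
    r <- 1e4
    return(structure(list(r = r, p_nb = r / (r + m), mu = m,
                          loglik = ll(log(r)), status = "poisson_boundary",
                          r_ci = c(NA_real_, NA_real_),
                          se_log_r = NA_real_, n = n),
                     class = "nb_fit"))
  }
  logr0 <- log(m^2 / (v - m))
  opt <- stats::optimize(ll, interval = logr0 + c(-8, 8), maximum = TRUE,
                         tol = 1e-10)
  logr <- opt$maximum
  r <- exp(logr)
  ## observed information on (log r, log mu); delta-method CI for r
  nll2 <- function(par) {
    -sum(stats::dnbinom(counts, size = exp(par[1]), mu = exp(par[2]),
                        log = TRUE))
  }
  H <- num_hessian(nll2, c(logr, log(m)))
  se_logr <- tryCatch({
    V <- solve(H)
    if (V[1, 1] > 0) sqrt(V[1, 1]) else NA_real_
  }, error = function(e) NA_real_)
  structure(list(r = r, p_nb = r / (r + m), mu = m, loglik = opt$objective,
                 status = "ok",
                 r_ci = if (is.na(se_logr)) c(NA_real_, NA_real_)
                        else exp(logr + c(-1.96, 1.96) * se_logr),
                 se_log_r = se_logr, n = n),
            class = "nb_fit")
}

#' @export
coef.nb_fit <- function(object, ...) c(r = object$r, p_nb = object$p_nb)

#' @export
logLik.nb_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<NB fit> r = %.4g, p = %.4g (mean %.4g, n = %d) [%s]\n",
              x$r, x$p_nb, x$mu, x$n, x$status))
  invisible(x)
}

#' Transcriptional burst parameters from a negative-binomial fit
#'
#' Under the two-state promoter model, burst frequency is `f = r / tau_rna`
#' and burst size `b = (1 - p) / p`.  Binomial thinning maps NB(r, p) to
#' NB(r, p') with `(1 - p') / p' = efficiency * (1 - p) / p`, so
#' hybridization efficiency biases the apparent burst size but not the burst
#' frequency; the corrected burst size is `b / efficiency`.
#'
#' @param r NB size parameter (> 0).
#' @param p_nb NB probability parameter in (0, 1).
#' @param tau_min RNA lifetime in minutes (default 2.8).
#' @param efficiency hybridization efficiency in (0, 1] applied to correct
#'   the burst size.
#' @return object of class `"burst_fit"`: `r`, `p_nb`, `burst_size`,
#'   `burst_frequency` (per minute), `tau_rna_min`, `efficiency`,
#'   `corrected_burst_size`.
#' @export
burst_parameters <- function(r, p_nb, tau_min = 2.8, efficiency = 1) {
  if (r <= 0) stop("r must be > 0")
  if (p_nb <= 0 || p_nb >= 1) stop("p_nb must lie in (0, 1)")
  if (tau_min <= 0) stop("tau_min must be > 0")
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must lie in (0, 1]")
  b <- (1 - p_nb) / p_nb
  structure(list(r = r, p_nb = p_nb,
                 burst_size = b,
                 burst_frequency = r / tau_min,
                 tau_rna_min = tau_min,
                 efficiency = efficiency,
                 corrected_burst_size = b / efficiency),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf(
    "<burst> f = %.4g /min, b = %.4g (corrected %.4g at efficiency %.3g)\n",
    x$burst_frequency, x$burst_size, x$corrected_burst_size, x$efficiency))
  invisible(x)
}

## point estimate of the pooled-median efficiency ratio (no bootstrap)
.overall_ratio_point <- function(tables_a, tables_b) {
  keys <- intersect(names(tables_a), names(tables_b))
  if (length(keys) == 0L) stop("no matched samples")
  lr <- unlist(lapply(keys, function(k) {
    a <- tables_a[[k]]; b <- tables_b[[k]]
    ma <- mean(a); mb <- mean(b)
    out <- c(NA_real_, NA_real_)
    if (ma > 0 && mb > 0) {
      out[1] <- log(ma / mb)
      fa <- stats::var(a) / ma
      fb <- stats::var(b) / mb
      if (fa > 1 && fb > 1) out[2] <- log((fa - 1) / (fb - 1))
    }
    out
  }))
  if (all(is.na(lr))) stop("no computable ratio")
  exp(stats::median(lr, na.rm = TRUE))
}

#' Relative hybridization efficiency from mean and Fano-factor ratios
#'
#' If two labeling methods differ only by their hybridization efficiencies
#' `p_A` and `p_B`, binomial thinning implies
#' `E(Y_A)/E(Y_B) = (Fano(Y_A) - 1)/(Fano(Y_B) - 1) = p_A/p_B` for every
#' sample.  For each matched sample this computes the mean ratio (whenever
#' the reference mean is positive) and the (Fano - 1) ratio (only when both
#' Fano factors exceed 1; others are excluded and flagged), each with a
#' bootstrap 95% confidence interval, and reports the overall median ratio
#' pooled across both statistic types, all samples and replicates.  Ratios
#' are computed in log space and exponentiated (the median is
#' monotone-invariant).  The absolute efficiency of method A is
#' `overall_ratio * reference_efficiency` of method B.
#'
#' @param tables_a,tables_b named lists of non-negative integer count
#'   vectors (method A and reference method B), matched by name
#'   (sample x replicate keys).
#' @param n_boot bootstrap iterations (default 1000).
#' @param reference_efficiency assumed absolute efficiency of method B.
#' @param seed optional seed for the bootstrap.
#' @param conf confidence level of the bootstrap intervals.
#' @return object of class `"efficiency_ratio"`: `per_sample` data.frame
#'   (sample, type, ratio, ci_low, ci_high, excluded), `overall_ratio` with
#'   `overall_ci`, `reference_efficiency`, `absolute_efficiency`, `n_boot`.
#' @export
efficiency_ratio <- function(tables_a, tables_b, n_boot = 1000L,
                             reference_efficiency = 0.95, seed = NULL,
                             conf = 0.95) {
  keys <- intersect(names(tables_a), names(tables_b))
  if (is.null(names(tables_a)) &&
      length(tables_a) == length(tables_b)) {
    keys <- as.character(seq_along(tables_a))
    names(tables_a) <- names(tables_b) <- keys
  }
  if (length(keys) == 0L) stop("no matched samples between the two methods")
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - conf) / 2
  log_ratios <- function(a, b) {
    ma <- mean(a); mb <- mean(b)
    out <- c(mean = NA_real_, fano = NA_real_)
    if (mb > 0 && ma > 0) out["mean"] <- log(ma / mb)
    if (ma > 0 && mb > 0) {
      fa <- stats::var(a) / ma
      fb <- stats::var(b) / mb
      if (fa > 1 && fb > 1) out["fano"] <- log((fa - 1) / (fb - 1))
    }
    out
  }
  point <- vapply(keys, function(k) log_ratios(tables_a[[k]], tables_b[[k]]),
                  numeric(2))
  if (all(is.na(point))) stop("no computable ratio in any matched sample")
  ## one bootstrap pass drives both the per-sample CIs and the CI of the
  ## pooled median (cells resampled with replacement within each table)
  boot_ratio <- array(NA_real_, dim = c(2L, length(keys), n_boot),
                      dimnames = list(c("mean", "fano"), keys, NULL))
  for (it in seq_len(n_boot)) {
    for (k in keys) {
      a <- tables_a[[k]]
      b <- tables_b[[k]]
      boot_ratio[, k, it] <- log_ratios(
        a[sample.int(length(a), replace = TRUE)],
        b[sample.int(length(b), replace = TRUE)])
    }
  }
  per_sample <- do.call(rbind, lapply(keys, function(k) {
    do.call(rbind, lapply(c("mean", "fano"), function(type) {
      est <- point[type, k]
      bs <- boot_ratio[type, k, ]
      data.frame(sample = k, type = type,
                 log_ratio = est,
                 ratio = exp(est),
                 ci_low = exp(unname(stats::quantile(bs, alpha, na.rm = TRUE))),
                 ci_high = exp(unname(stats::quantile(bs, 1 - alpha,
                                                      na.rm = TRUE))),
                 excluded = is.na(est))
    }))
  }))
  overall <- exp(stats::median(point, na.rm = TRUE))
  boot_overall <- exp(apply(boot_ratio, 3, stats::median, na.rm = TRUE))
  overall_ci <- unname(stats::quantile(boot_overall, c(alpha, 1 - alpha),
                                       na.rm = TRUE))
  structure(list(per_sample = per_sample,
                 overall_ratio = overall,
                 overall_ci = overall_ci,
                 reference_efficiency = reference_efficiency,
                 absolute_efficiency = overall * reference_efficiency,
                 n_boot = n_boot),
            class = "efficiency_ratio")
}

#' @export
print.efficiency_ratio <- function(x, ...) {
  cat(sprintf(
    "<efficiency ratio> overall median %.3f (95%% boot CI %.3f-%.3f)\n",
    x$overall_ratio, x$overall_ci[1], x$overall_ci[2]))
  cat(sprintf("absolute efficiency = %.3f x %.3f = %.3f (%.1f%%)\n",
              x$overall_ratio, x$reference_efficiency,
              x$absolute_efficiency, 100 * x$absolute_efficiency))
  invisible(x)
}

#' Two-lognormal mixture fit to spot intensities
#'
#' Separates specific from nonspecific fluorescent spots by fitting a
#' mixture of two lognormal components constrained to be centered on either
#' side of a threshold intensity (EM on the log scale, component log-medians
#' clamped below/above `log(threshold)`).  Reports the mixture weight of the
#' above-threshold component and the fraction of total spot intensity
#' attributed to it (the specific fraction).
#'
#' @param intensities positive spot intensities (n >= 50).
#' @param threshold positive threshold within the data range.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return object of class `"spot_mixture"`: `weight_upper`, `meanlog`,
#'   `sdlog` (length-2 each), `specific_fraction`, `loglik`, `status`.
#' @export
spot_intensity_mixture <- function(intensities, threshold,
                                   max_iter = 500L, tol = 1e-8) {
  if (any(intensities <= 0)) stop("intensities must be positive")
  if (length(intensities) < 50L) stop("need at least 50 spots")
  if (threshold <= min(intensities) || threshold >= max(intensities)) {
    ## all mass on one side: degenerate single-component result
    upper <- mean(intensities > threshold)
    z <- log(intensities)
    return(structure(list(weight_upper = upper,
                          meanlog = c(mean(z), mean(z)),
                          sdlog = c(stats::sd(z), stats::sd(z)),
                          specific_fraction = if (upper > 0.5) 1 else 0,
                          loglik = NA_real_, status = "degenerate"),
                     class = "spot_mixture"))
  }
  z <- log(intensities)
  zt <- log(threshold)
  lower <- z <= zt
  mu <- c(mean(z[lower]), mean(z[!lower]))
  sd0 <- stats::sd(z)
  s <- c(max(stats::sd(z[lower]), sd0 / 10, 1e-3),
         max(stats::sd(z[!lower]), sd0 / 10, 1e-3))
  w <- c(mean(lower), mean(!lower))
  ll_old <- -Inf
  status <- "not_converged"
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(z, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(z, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d2 / tot                      # responsibility of upper component
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { status <- "converged"; break }
    ll_old <- ll
    w <- c(mean(1 - g), mean(g))
    mu[1] <- min(sum((1 - g) * z) / max(sum(1 - g), 1e-12), zt)
    mu[2] <- max(sum(g * z) / max(sum(g), 1e-12), zt)
    s[1] <- sqrt(sum((1 - g) * (z - mu[1])^2) / max(sum(1 - g), 1e-12))
    s[2] <- sqrt(sum(g * (z - mu[2])^2) / max(sum(g), 1e-12))
    s <- pmax(s, 1e-4)
  }
  d1 <- w[1] * stats::dnorm(z, mu[1], s[1])
  d2 <- w[2] * stats::dnorm(z, mu[2], s[2])
  g <- d2 / pmax(d1 + d2, .Machine$double.xmin)
  structure(list(weight_upper = w[2], meanlog = mu, sdlog = s,
                 specific_fraction = sum(g * intensities) / sum(intensities),
                 loglik = ll_old, status = status),
            class = "spot_mixture")
}

#' @export
print.spot_mixture <- function(x, ...) {
  cat(sprintf(
    "<spot mixture> upper weight %.3f, specific intensity fraction %.3f [%s]\n",
    x$weight_upper, x$specific_fraction, x$status))
  invisible(x)
}
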