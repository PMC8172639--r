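#' Location estimate of a single-cell distribution with bootstrap uncertainty
#'
#' Mean, median and geometric mean of the per-cell signals; the median is the
#' location used downstream (robust to outliers and distribution tails).
#' Uncertainty on the median is its variance over bootstrap resamples.
#'
#' @param x numeric vector of per-cell signals (or a [cell_event_table()]).
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param seed optional seed making the resampling deterministic.
#' @return list of class `"location_estimate"`: `median`, `mean`,
#'   `geometric_mean` (`NA` if any value is non-positive),
#'   `bootstrap_variance_of_median`, `n_boot`, `n`.
#' @export
location_with_bootstrap <- function(x, n_boot = 1000L, seed = NULL) {
  if (inherits(x, "cell_event_table")) x <- x$signal
  n <- length(x)
  if (n < 2L) stop("need at least 2 cells for a location estimate")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  boots <- vapply(seq_len(n_boot),
                  function(i) stats::median(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  structure(list(
    median = stats::median(x),
    mean = mean(x),
    geometric_mean = if (all(x > 0)) exp(mean(log(x))) else NA_real_,
    bootstrap_variance_of_median = stats::var(boots),
    n_boot = n_boot,
    n = n), class = "location_estimate")
}

#' @export
print.location_estimate <- function(x, ...) {
  cat(sprintf("<location> median %.4g (boot var %.3g, n = %d)\n",
              x$median, x$bootstrap_variance_of_median, x$n))
  invisible(x)
}

#' Normalization to relative promoter units (RPU)
#'
#' `RPU = (Signal_test - Signal_neg) / (Signal_pos - Signal_neg)` where the
#' signals are medians of the test sample, the constitutive positive-control
#' reference and the negative control.  Uncertainty is propagated from the
#' bootstrap variances by the first-order delta method.
#'
#' @param signal_test,signal_pos,signal_neg location medians.
#' @param var_test,var_pos,var_neg bootstrap variances of the medians
#'   (default 0: no propagation).
#' @param rel_tol relative tolerance below which the denominator
#'   `signal_pos - signal_neg` is considered degenerate.
#' @return list with `rpu` and `variance`.
#' @export
rpu_normalize <- function(signal_test, signal_pos, signal_neg,
                          var_test = 0, var_pos = 0, var_neg = 0,
                          rel_tol = 1e-8) {
  denom <- signal_pos - signal_neg
  scale <- max(abs(signal_pos), abs(signal_neg), 1)
  if (abs(denom) <= rel_tol * scale) {
    stop("degenerate denominator: positive and negative control signals coincide")
  }
  rpu <- (signal_test - signal_neg) / denom
  g <- c(test = 1 / denom,
         pos = -(signal_test - signal_neg) / denom^2,
         neg = (signal_test - signal_pos) / denom^2)
  list(rpu = rpu,
       variance = g[["test"]]^2 * var_test + g[["pos"]]^2 * var_pos +
         g[["neg"]]^2 * var_neg)
}

#' Clamp inverse-variance weights to a factor of 10 around their geometric mean
#'
#' Bootstrapping tends to underestimate variability around the dose-response
#' fit, so raw inverse variances can span orders of magnitude.  Each weight
#' is constrained to lie within a factor of 10 below or above the geometric
#' mean of the available (finite, positive) inverse variances within a
#' replicate; infinite weights (zero bootstrap variance) are set to the upper
#' clamp.
#'
#' @param inverse_variances numeric vector of inverse bootstrap variances.
#' @return clamped weights, same length.
#' @export
clamp_weights <- function(inverse_variances) {
  w <- inverse_variances
  ok <- is.finite(w) & w > 0
  if (!any(ok)) stop("no finite positive inverse variance available")
  g <- exp(mean(log(w[ok])))
  out <- pmin(pmax(w, g / 10), 10 * g)
  out[!is.finite(w)] <- 10 * g
  if (any(!ok & is.finite(w))) {
    stop("non-positive inverse variances are not valid weights")
  }
  out
}

#' Fit the Hill equation by weighted nonlinear least squares
#'
#' Minimizes `sum(w * (y - offset - A x^n / (K_half^n + x^n))^2)` under the
#' bounds `A >= 0`, `K_half > 0`, `n` in (0, 10], offset unconstrained.
#' Initialization is multi-start over a small grid of `K_half` (around the
#' geometric mid-range of the positive stimuli) and `n` (0.5, 1, 2, 4), with
#' `offset0 = min(y)` and `A0 = max(y) - min(y)`; the best weighted RSS wins.
#' 95% confidence intervals are Gaussian (`estimate +/- 1.96 SE`) from the
#' linearized covariance at the solution.  Non-convergence from every start
#' yields a result flagged `status = "failed"`, not an error.
#'
#' @param x stimulus concentrations (>= 0; `x = 0` is used as-is).
#' @param y location estimates (e.g. medians), one per stimulus.
#' @param weights optional fit weights (e.g. from [clamp_weights()]);
#'   default: unit weights.
#' @param rpu_normalized flag recorded in the result.
#' @return object of class `"hill_fit"` with components `coefficients`
#'   (offset, A, K_half, n), `se`, `ci` (2-column matrix), `rss`, `status`,
#'   `rpu_normalized`, and the data.
#' @examples
#' x <- stimulus_series()
#' y <- hill_function(x, 0.1, 1, 20, 2)
#' fit <- fit_hill(x, y)
#' coef(fit)
#' @export
fit_hill <- function(x, y, weights = NULL, rpu_normalized = FALSE) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5L) stop("need at least 5 points to fit 4 parameters")
  if (any(x < 0)) stop("stimulus concentrations must be >= 0")
  if (is.null(weights)) weights <- rep(1, length(x))
  offset0 <- min(y)
  A0 <- max(max(y) - min(y), 1e-12)
  xp <- x[x > 0]
  K0mid <- exp(mean(log(range(xp))))
  starts <- expand.grid(K = K0mid * c(0.25, 1, 4), n = c(0.5, 1, 2, 4))
  lower <- c(offset = -Inf, A = 0, K_half = 1e-9, n = 1e-3)
  upper <- c(offset = Inf, A = Inf, K_half = Inf, n = 10)
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ offset + A * ifelse(x > 0, x^n, 0) / (K_half^n + ifelse(x > 0, x^n, 0)),
      data = dat,
      start = list(offset = offset0, A = A0,
                   K_half = starts$K[s], n = starts$n[s]),
      weights = weights, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (!is.null(best)) {
    est <- stats::coef(best$fit)
    names(est) <- c("offset", "A", "K_half", "n")
    se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) {
      rep(NA_real_, 4)
    })
  } else {
    ## degenerate responses (e.g. flat y) make the LM Jacobian singular at
    ## every start; fall back to bounded quasi-Newton on the same objective
    obj <- function(p) {
      sum(weights * (y - hill_function(x, p[1], p[2], p[3], p[4]))^2)
    }
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(
        c(offset0, A0, starts$K[s], starts$n[s]), obj,
        method = "L-BFGS-B",
        lower = unname(lower), upper = pmin(unname(upper), 1e12)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$rss) best <- list(par = o$par,
                                                            rss = o$value)
    }
    if (is.null(best)) {
      return(structure(list(coefficients = c(offset = NA, A = NA,
                                             K_half = NA, n = NA),
                            se = rep(NA_real_, 4), ci = NULL, rss = NA_real_,
                            status = "failed",
                            rpu_normalized = rpu_normalized,
                            x = x, y = y, weights = weights),
                       class = "hill_fit"))
    }
    est <- c(offset = best$par[1], A = best$par[2], K_half = best$par[3],
             n = best$par[4])
    ## linearized covariance at the solution; singular designs give NA SEs
    jac <- vapply(seq_along(est), function(j) {
      h <- pmax(abs(est[j]), 1e-6) * 1e-6
      ep <- est; ep[j] <- ep[j] + h
      em <- est; em[j] <- em[j] - h
      (hill_function(x, ep[1], ep[2], ep[3], ep[4]) -
         hill_function(x, em[1], em[2], em[3], em[4])) / (2 * h)
    }, numeric(length(x)))
    sigma2 <- best$rss / max(length(x) - 4, 1)
    se <- tryCatch(sqrt(diag(solve(crossprod(jac * sqrt(weights)))) * sigma2),
                   error = function(e) rep(NA_real_, 4))
  }
  names(se) <- names(est)
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(coefficients = est, se = se, ci = ci, rss = best$rss,
                 status = "converged", rpu_normalized = rpu_normalized,
                 x = x, y = y, weights = weights,
                 fitted = hill_function(x, est[["offset"]], est[["A"]],
                                        est[["K_half"]], est[["n"]])),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cat("<Hill fit>", if (x$rpu_normalized) "(RPU-normalized)" else "(raw)",
      "status:", x$status, "\n")
  if (x$status == "converged") {
    print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  }
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  cat("Hill dose-response fit (weighted nonlinear least squares)\n")
  cat("status:", object$status, "  weighted RSS:",
      format(object$rss, digits = 4), "\n\n")
  if (object$status == "converged") {
    tab <- cbind(estimate = object$coefficients, se = object$se, object$ci)
    print(round(tab, 5))
  }
  invisible(object)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  p <- object$coefficients
  hill_function(x, p[["offset"]], p[["A"]], p[["K_half"]], p[["n"]])
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  xx <- x$x
  pos <- xx[xx > 0]
  grid <- c(0, exp(seq(log(min(pos) / 2), log(max(pos) * 2), length.out = 200)))
  plot(pmax(xx, min(pos) / 4), x$y, log = "x",
       xlab = "stimulus (log scale; 0 plotted at left edge)",
       ylab = "signal", ...)
  graphics::lines(pmax(grid, min(pos) / 4), predict(x, grid))
  invisible(x)
}
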