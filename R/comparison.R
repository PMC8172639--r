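#' Enumerate method pairs differing in exactly one measurement step
#'
#' Attribution of performance differences rests on pairwise comparisons of
#' methods that share two of the three measurement steps and differ in the
#' third: sample preparation (`"P"`), signal detection (`"D"`), or measurand
#' (`"M"`).  By default the measurand comparison is restricted to protein
#' versus whole-cell RNA fluorescence (the two measurands available on both
#' detections); pass `values = NULL` to enumerate every measurand pair, or
#' e.g. `values = c("FISH", "HCR")` with `step = "P"` to restrict the
#' preparation comparison to the two RNA-labeling strategies.
#'
#' @param methods data.frame of methods (columns `preparation`, `detection`,
#'   `measurand`), e.g. [method_validity()].
#' @param step which step the pair must differ in: `"P"`, `"D"` or `"M"`.
#' @param values optional pair of step values the two methods must take;
#'   `NULL` (no restriction) except for `step = "M"`, whose default is
#'   `c("protein", "rna_fluorescence")`.
#' @return data.frame with one row per unordered pair: the two methods'
#'   step fields (suffixes `_a`, `_b`), `differing_step`, and labels.
#' @export
attribution_pairs <- function(methods, step = c("P", "D", "M"),
                              values = if (match.arg(step) == "M")
                                c("protein", "rna_fluorescence") else NULL) {
  step <- match.arg(step)
  col <- c(P = "preparation", D = "detection", M = "measurand")[[step]]
  other <- setdiff(c("preparation", "detection", "measurand"), col)
  methods <- unique(methods[c("preparation", "detection", "measurand")])
  rows <- list()
  n <- nrow(methods)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (n < 2L) break
      a <- methods[i, ]
      b <- methods[j, ]
      if (!all(a[other] == b[other]) || a[[col]] == b[[col]]) next
      if (!is.null(values) && !setequal(c(a[[col]], b[[col]]), values)) next
      ## orient so the pair is reported in a stable order
      if (a[[col]] > b[[col]]) { tmp <- a; a <- b; b <- tmp }
      rows[[length(rows) + 1L]] <- data.frame(
        preparation_a = a$preparation, detection_a = a$detection,
        measurand_a = a$measurand,
        preparation_b = b$preparation, detection_b = b$detection,
        measurand_b = b$measurand,
        differing_step = step,
        label_a = paste(a$preparation, a$detection, a$measurand),
        label_b = paste(b$preparation, b$detection, b$measurand))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(preparation_a = character(0), detection_a = character(0),
                      measurand_a = character(0), preparation_b = character(0),
                      detection_b = character(0), measurand_b = character(0),
                      differing_step = character(0), label_a = character(0),
                      label_b = character(0)))
  }
  do.call(rbind, rows)
}

#' Two-sided sign test
#'
#' Exact binomial test of the null that paired comparisons favor either side
#' equally, on the `N = n_pos + n_neg` non-tied cells (ties are excluded
#' before calling).  `p = min(1, 2 * min(P(X <= min), P(X >= max)))` with
#' `X ~ Binomial(N, 1/2)`; with no non-tied cells the p-value is 1.
#'
#' @param n_pos,n_neg counts of cells favoring each side.
#' @return two-sided p-value.
#' @examples
#' sign_test(12, 2)  # 212 / 2^14
#' @export
sign_test <- function(n_pos, n_neg) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be >= 0")
  n <- n_pos + n_neg
  if (n == 0) return(1)
  lo <- min(n_pos, n_neg)
  min(1, 2 * stats::pbinom(lo, n, 0.5))
}

## tie-corrected Friedman statistic; blocks in columns, treatments in rows
.friedman_statistic <- function(m) {
  k <- nrow(m)
  n <- ncol(m)
  r <- apply(m, 2, rank)               # midranks within each block
  tie_term <- sum(apply(r, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })) / (k - 1)
  num <- 12 * sum((rowSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - tie_term
  if (den <= 0) return(0)              # all values tied in every block
  num / den
}

## all permutations of seq_len(k), rows of a matrix
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Friedman test for consistent ordering across blocks
#'
#' Nonparametric test of whether the ordering of values across the primary
#' factor is more consistent across the blocking factor's instances than
#' expected under random within-block permutations.  Used with measurement
#' method as primary factor and biological replicate as block (method bias),
#' and transposed (replicate bias).  The statistic is the tie-corrected
#' Friedman chi-square; the p-value uses the chi-square approximation with
#' `k - 1` degrees of freedom, or, with `exact = TRUE` and a feasible
#' enumeration budget, the exact permutation null.
#'
#' @param values numeric `k x n` matrix: primary-factor levels in rows,
#'   blocks in columns (set `primary = "columns"` to transpose).  Blocks
#'   containing missing values are dropped with a warning.
#' @param primary which axis holds the primary factor.
#' @param exact if `TRUE`, also compute the exact permutation p-value
#'   (requires `factorial(k)^n <= 1e7`).
#' @return object of class `"friedman_result"`: `statistic`, `df`,
#'   `p_value`, `p_exact` (or `NA`), `k`, `n_blocks`.
#' @export
friedman_test <- function(values, primary = c("rows", "columns"),
                          exact = FALSE) {
  primary <- match.arg(primary)
  m <- as.matrix(values)
  if (primary == "columns") m <- t(m)
  drop <- apply(m, 2, anyNA)
  if (any(drop)) {
    warning(sum(drop), " block(s) with missing cells dropped")
    m <- m[, !drop, drop = FALSE]
  }
  k <- nrow(m)
  n <- ncol(m)
  if (k < 2L || n < 2L) stop("need k >= 2 treatments and n >= 2 blocks")
  stat <- .friedman_statistic(m)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  p_exact <- NA_real_
  if (exact) {
    if (factorial(k)^n > 1e7) stop("exact enumeration budget exceeded")
    perms <- .permutations(k)
    ranks <- apply(m, 2, rank)
    ## enumerate all k!^n within-block permutations of the observed midranks
    idx <- rep(1L, n)
    np <- nrow(perms)
    total <- np^n
    count <- 0L
    rcur <- matrix(0, k, n)
    for (code in 0:(total - 1L)) {
      c0 <- code
      for (j in seq_len(n)) {
        idx[j] <- (c0 %% np) + 1L
        c0 <- c0 %/% np
      }
      for (j in seq_len(n)) rcur[, j] <- ranks[perms[idx[j], ], j]
      tie_term <- sum(apply(rcur, 2, function(col) {
        tt <- table(col); sum(tt^3 - tt)
      })) / (k - 1)
      num <- 12 * sum((rowSums(rcur) - n * (k + 1) / 2)^2)
      den <- n * k * (k + 1) - tie_term
      s <- if (den <= 0) 0 else num / den
      if (s >= stat - 1e-12) count <- count + 1L
    }
    p_exact <- count / total
  }
  structure(list(statistic = stat, df = k - 1, p_value = p,
                 p_exact = p_exact, k = k, n_blocks = n),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("<Friedman> chi2 = %.4g (df %d), p = %.4g", x$statistic, x$df,
              x$p_value))
  if (!is.na(x$p_exact)) cat(sprintf(", exact p = %.4g", x$p_exact))
  cat(sprintf("  [k = %d, blocks = %d]\n", x$k, x$n_blocks))
  invisible(x)
}

#' Friedman bias report over Hill-fit parameters
#'
#' For each Hill parameter and normalization, tests the null of no
#' method-to-method bias (method as primary factor, replicate as block) and,
#' a second time, of no replicate-to-replicate bias (replicate as primary
#' factor, method as block).
#'
#' @param hill_fits long data.frame with columns `method`, `replicate`,
#'   `normalization`, `parameter`, `estimate`.
#' @param parameters parameters to test.
#' @return data.frame with one row per
#'   (parameter, normalization, primary factor): `k`, `n_blocks`,
#'   `statistic`, `p_value`, `note`.
#' @export
bias_report <- function(hill_fits,
                        parameters = c("offset", "A", "K_half", "n")) {
  need <- c("method", "replicate", "normalization", "parameter", "estimate")
  if (!all(need %in% names(hill_fits))) {
    stop("hill_fits must have columns ", paste(need, collapse = ", "))
  }
  rows <- list()
  for (param in parameters) {
    for (norm in unique(hill_fits$normalization)) {
      sub <- hill_fits[hill_fits$parameter == param &
                       hill_fits$normalization == norm, ]
      if (nrow(sub) == 0L) next
      m <- tapply(sub$estimate, list(sub$method, sub$replicate),
                  function(v) v[1])
      for (prim in c("method", "replicate")) {
        mat <- if (prim == "method") m else t(m)
        res <- tryCatch(suppressWarnings(friedman_test(mat)),
                        error = function(e) e)
        rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
          data.frame(parameter = param, normalization = norm,
                     primary_factor = prim, k = NA, n_blocks = NA,
                     statistic = NA_real_, p_value = NA_real_,
                     note = conditionMessage(res))
        } else {
          data.frame(parameter = param, normalization = norm,
                     primary_factor = prim, k = res$k,
                     n_blocks = res$n_blocks, statistic = res$statistic,
                     p_value = res$p_value, note = "")
        }
      }
    }
  }
  if (length(rows) == 0L) stop("no testable parameter in hill_fits")
  do.call(rbind, rows)
}
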