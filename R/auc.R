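#' Resolvability between two single-cell distributions (ROC AUC)
#'
#' The area under the receiver operating characteristic curve between the
#' distributions measured at two stimulus levels, computed via rank sums
#' (equivalently the Mann-Whitney U statistic normalized by
#' `n_high * n_low`).  Ties count one half (midrank convention), so the AUC
#' is the probability that a random cell from the higher-stimulus sample
#' exceeds one from the lower, plus half the probability of a tie.  0.5 means
#' no resolvability (complete overlap), 1 complete resolvability in the
#' expected direction, 0 complete resolvability in the unexpected direction.
#' Values below 0.5 are reported as-is, never folded.
#'
#' @param low signal values at the lower stimulus.
#' @param high signal values at the higher stimulus.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_auc(c(1, 2, 3), c(4, 5, 6))  # 1
#' compute_auc(1:10, 1:10)              # 0.5
#' @export
compute_auc <- function(low, high) {
  if (length(low) == 0L || length(high) == 0L) {
    stop("both samples must be non-empty")
  }
  r <- rank(c(low, high))
  n_l <- length(low)
  n_h <- length(high)
  u <- sum(r[n_l + seq_len(n_h)]) - n_h * (n_h + 1) / 2
  u / (n_h * n_l)
}

#' AUC profile across an ordered stimulus series
#'
#' Computes the AUC for every pair of adjacent stimulus levels of one method
#' and replicate, plus the average AUC (unweighted arithmetic mean of the
#' available adjacent-pair values) as a summary statistic.  A missing level
#' drops the adjacent pairs touching the gap (they are not bridged); dropped
#' pairs are excluded from the average with a warning.
#'
#' @param signals named list of numeric vectors, one per measured stimulus
#'   level; names are the levels.  Levels in `levels` absent from `signals`
#'   (or `NULL` entries) are treated as missing.
#' @param levels ordered (strictly increasing) stimulus series; default: the
#'   sorted numeric names of `signals`.
#' @param method,replicate optional provenance attached to the profile.
#' @return object of class `"auc_profile"`: list with `levels`,
#'   `auc_adjacent` (length `length(levels) - 1`, `NA` for dropped pairs),
#'   `average_auc`, `method`, `replicate`.
#' @export
auc_profile <- function(signals, levels = NULL, method = NULL,
                        replicate = NULL) {
  if (is.null(levels)) levels <- sort(as.numeric(names(signals)))
  if (length(levels) < 2L) stop("need at least 2 stimulus levels")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  get_level <- function(l) {
    v <- signals[[as.character(l)]]
    if (!is.null(v) && length(v) == 0L) v <- NULL
    v
  }
  k <- length(levels) - 1L
  auc <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    lo <- get_level(levels[i])
    hi <- get_level(levels[i + 1L])
    if (!is.null(lo) && !is.null(hi)) auc[i] <- compute_auc(lo, hi)
  }
  names(auc) <- paste(levels[-length(levels)], levels[-1L], sep = "-")
  if (anyNA(auc)) {
    warning(sum(is.na(auc)), " adjacent pair(s) dropped (missing level); ",
            "average over the remaining pairs")
  }
  if (all(is.na(auc))) stop("no adjacent pair could be computed")
  structure(list(levels = levels, auc_adjacent = auc,
                 average_auc = mean(auc, na.rm = TRUE),
                 method = method, replicate = replicate),
            class = "auc_profile")
}

#' @export
print.auc_profile <- function(x, ...) {
  cat("<AUC profile>",
      if (!is.null(x$method)) format(x$method) else "",
      if (!is.null(x$replicate)) sprintf("(rep %s)", x$replicate) else "",
      "\n")
  print(round(x$auc_adjacent, 3))
  cat("average AUC:", round(x$average_auc, 3), "\n")
  invisible(x)
}

#' Pairwise resolvability comparison between two methods
#'
#' Matches the adjacent-pair AUC values of two methods across replicates,
#' counts in how many matched cells each method's AUC is higher (ties
#' excluded and reported), and attaches the two-sided sign-test p-value.
#'
#' @param profiles_a,profiles_b lists of [auc_profile()] objects for the two
#'   methods, matched by position or by (identical) names; profiles must
#'   share the same stimulus levels.
#' @param label_a,label_b optional method labels.
#' @return object of class `"pairwise_auc"`: counts `n_a_higher`,
#'   `n_b_higher`, `n_ties`, sign-test `p_two_sided`, and the matched AUC
#'   table.
#' @export
pairwise_auc_table <- function(profiles_a, profiles_b,
                               label_a = "A", label_b = "B") {
  if (inherits(profiles_a, "auc_profile")) profiles_a <- list(profiles_a)
  if (inherits(profiles_b, "auc_profile")) profiles_b <- list(profiles_b)
  if (length(profiles_a) != length(profiles_b)) {
    stop("profiles must be matched across replicates")
  }
  if (!is.null(names(profiles_a)) && !is.null(names(profiles_b))) {
    profiles_b <- profiles_b[names(profiles_a)]
  }
  rows <- list()
  for (i in seq_along(profiles_a)) {
    pa <- profiles_a[[i]]
    pb <- profiles_b[[i]]
    stopifnot(length(pa$auc_adjacent) == length(pb$auc_adjacent))
    rows[[i]] <- data.frame(
      replicate = pa$replicate %||% i,
      pair = names(pa$auc_adjacent),
      auc_a = unname(pa$auc_adjacent),
      auc_b = unname(pb$auc_adjacent))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$auc_a) & !is.na(tab$auc_b), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no matched (replicate, pair) cells")
  n_a <- sum(tab$auc_a > tab$auc_b)
  n_b <- sum(tab$auc_b > tab$auc_a)
  structure(list(label_a = label_a, label_b = label_b,
                 n_a_higher = n_a, n_b_higher = n_b,
                 n_ties = nrow(tab) - n_a - n_b,
                 p_two_sided = sign_test(n_a, n_b),
                 matched = tab),
            class = "pairwise_auc")
}

#' @export
print.pairwise_auc <- function(x, ...) {
  cat(sprintf("<pairwise AUC> %s vs %s: %d vs %d higher (%d ties), sign test p = %.4g\n",
              x$label_a, x$label_b, x$n_a_higher, x$n_b_higher, x$n_ties,
              x$p_two_sided))
  invisible(x)
}
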