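#' Measurement-method and sample identity
#'
#' A measurement method is a route through the split-sample design: a sample
#' preparation (live-cell antibiotic treatment with kanamycin `Kn` or
#' chloramphenicol `Cm`, or RNA labeling by `FISH` or `HCR`), a signal
#' detection (`flow` cytometry or `microscopy`), and a measurand (whole-cell
#' `protein` fluorescence, whole-cell `rna_fluorescence` from labeled RNA, or
#' estimated `rna_count` per cell).  Which combinations are meaningful is
#' data, not code: a validity table enumerates them, and the default table
#' ships with the package (the twelve-method benchmark design).
#'
#' @param preparation one of `"Kn"`, `"Cm"`, `"FISH"`, `"HCR"`.
#' @param detection one of `"flow"`, `"microscopy"`.
#' @param measurand one of `"protein"`, `"rna_fluorescence"`, `"rna_count"`.
#' @param validity a validity table as returned by [method_validity()].
#' @return `method_id()` returns an object of class `"method_id"`; a named
#'   list with the three step fields.
#' @examples
#' method_id("HCR", "flow", "protein")
#' @export
method_id <- function(preparation, detection, measurand,
                      validity = method_validity()) {
  preparation <- match.arg(preparation, c("Kn", "Cm", "FISH", "HCR"))
  detection   <- match.arg(detection, c("flow", "microscopy"))
  measurand   <- match.arg(measurand,
                           c("protein", "rna_fluorescence", "rna_count"))
  if (measurand == "rna_count" &&
      (detection != "microscopy" || !preparation %in% c("FISH", "HCR"))) {
    stop("rna_count requires microscopy detection and FISH or HCR preparation")
  }
  if (measurand %in% c("rna_fluorescence", "rna_count") &&
      !preparation %in% c("FISH", "HCR")) {
    stop("RNA measurands require an RNA-labeling preparation (FISH or HCR)")
  }
  if (!is.null(validity)) {
    ok <- any(validity$preparation == preparation &
              validity$detection == detection &
              validity$measurand == measurand)
    if (!ok) {
      stop(sprintf("method %s %s %s is not in the validity table",
                   preparation, detection, measurand))
    }
  }
  structure(list(preparation = preparation, detection = detection,
                 measurand = measurand), class = "method_id")
}

#' @rdname method_id
#' @param x a `method_id`.
#' @param ... ignored.
#' @export
format.method_id <- function(x, ...) {
  paste(x$preparation, x$detection,
        c(protein = "protein", rna_fluorescence = "RNA",
          rna_count = "RNA #")[x$measurand])
}

#' @export
print.method_id <- function(x, ...) {
  cat("<method>", format(x), "\n")
  invisible(x)
}

#' Table of valid method combinations
#'
#' Reads the validity table enumerating allowed
#' (preparation, detection, measurand) combinations.  The packaged default is
#' the twelve-method benchmark design; supply `file` to use a different
#' design.
#'
#' @param file path to a CSV with columns `preparation`, `detection`,
#'   `measurand`; `NULL` for the packaged default.
#' @return a data.frame with one row per valid method.
#' @export
method_validity <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "method_validity.csv", package = "brass")
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("preparation", "detection", "measurand")
  if (!all(need %in% names(tab))) {
    stop("validity table must have columns preparation, detection, measurand")
  }
  tab[need]
}

#' Culture (sample) identity
#'
#' A sample is one culture: either the inducible construct at a given IPTG
#' concentration, or the constitutive positive control used as the living
#' reference for RPU normalization, or the negative control carrying no
#' reporter.  Controls are grown without inducer.
#'
#' @param construct `"inducible"`, `"positive_control"` or
#'   `"negative_control"`.
#' @param iptg_umol_per_L inducer concentration in micromol/L; must be 0 for
#'   controls.
#' @param replicate positive integer biological-replicate index.
#' @return an object of class `"sample_id"`.
#' @export
sample_id <- function(construct, iptg_umol_per_L = 0, replicate = 1L) {
  construct <- match.arg(construct,
                         c("inducible", "positive_control", "negative_control"))
  if (!is.numeric(iptg_umol_per_L) || iptg_umol_per_L < 0) {
    stop("iptg_umol_per_L must be a non-negative concentration")
  }
  if (construct != "inducible" && iptg_umol_per_L != 0) {
    stop("control constructs carry iptg_umol_per_L = 0")
  }
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate must be >= 1")
  structure(list(construct = construct,
                 iptg_umol_per_L = as.numeric(iptg_umol_per_L),
                 replicate = replicate),
            class = "sample_id")
}

#' @export
format.sample_id <- function(x, ...) {
  if (x$construct == "inducible") {
    sprintf("inducible %g umol/L (rep %d)", x$iptg_umol_per_L, x$replicate)
  } else {
    sprintf("%s (rep %d)", x$construct, x$replicate)
  }
}

#' @export
print.sample_id <- function(x, ...) {
  cat("<sample>", format(x), "\n")
  invisible(x)
}

#' Canonical stimulus series
#'
#' The default induction series for the inducible construct, in micromol/L
#' IPTG.
#'
#' @return numeric vector of 8 concentrations.
#' @export
stimulus_series <- function() c(0, 5, 10, 20, 40, 100, 400, 1000)

#' Per-cell event table
#'
#' The atomic measured distribution: per-cell signals for one
#' (method, sample, replicate) combination, optionally with a per-cell DAPI
#' stain used for permeabilization QC.
#'
#' @param signal numeric vector, one value per cell (fluorescence a.u., or a
#'   non-negative integer RNA count when the measurand is `rna_count`).
#' @param method a [method_id()].
#' @param sample a [sample_id()].
#' @param dapi optional numeric vector of per-cell DAPI signals (>= 0).
#' @return object of class `"cell_event_table"`.
#' @export
cell_event_table <- function(signal, method, sample, dapi = NULL) {
  stopifnot(inherits(method, "method_id"), inherits(sample, "sample_id"))
  if (length(signal) < 1L) stop("a cell event table needs n_cells >= 1")
  if (anyNA(signal) || !all(is.finite(signal))) {
    stop("signal contains missing or non-finite values")
  }
  if (method$measurand == "rna_count" && !is_count_vector(signal)) {
    stop("rna_count signals must be non-negative integers")
  }
  if (!is.null(dapi)) {
    if (length(dapi) != length(signal)) stop("dapi length must match signal")
    if (anyNA(dapi) || any(dapi < 0)) stop("dapi must be non-negative")
  }
  structure(list(method = method, sample = sample,
                 signal = as.numeric(signal), dapi = dapi,
                 n_cells = length(signal)),
            class = "cell_event_table")
}

#' @export
print.cell_event_table <- function(x, ...) {
  cat(sprintf("<cell event table> %s | %s | %d cells%s\n",
              format(x$method), format(x$sample), x$n_cells,
              if (is.null(x$dapi)) "" else " (+dapi)"))
  invisible(x)
}
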