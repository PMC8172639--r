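## canonical long-format columns for event tables
.EVENT_COLS <- c("preparation", "detection", "measurand", "construct",
                 "iptg_umol_per_L", "replicate", "signal")

#' Read per-cell event tables from CSV
#'
#' Reads one CSV file, or every `*.csv` in a directory, in the canonical
#' long format (one row per cell) and partitions the rows into one
#' [cell_event_table()] per distinct (method, sample, replicate).  A schema
#' file can map user column names onto the canonical ones.
#'
#' @param path a CSV file or a directory of CSV files.
#' @param schema optional column-name map: a named list/vector
#'   (canonical name -> column name in the file) or the path of a YAML file
#'   containing one.
#' @param validity method validity table passed to [method_id()].
#' @return a named list of `cell_event_table` objects; names are
#'   `preparation.detection.measurand|construct|iptg|replicate` keys.
#' @export
read_event_tables <- function(path, schema = NULL, validity = method_validity()) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else path
  if (length(files) == 0L) stop("no CSV files found at ", path)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- yaml::read_yaml(schema)
  }
  df <- do.call(rbind, lapply(files, utils::read.csv,
                              stringsAsFactors = FALSE))
  if (!is.null(schema)) {
    schema <- unlist(schema)
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df)) {
        stop("schema error: column '", schema[[canon]], "' not in file")
      }
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(.EVENT_COLS, names(df))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  split_events(df, validity = validity)
}

#' Partition a long event data frame into cell event tables
#'
#' @param df data.frame in the canonical long format (see
#'   [read_event_tables()]); a `dapi` column is optional and used where
#'   non-missing.
#' @inheritParams read_event_tables
#' @return named list of [cell_event_table()] objects.
#' @export
split_events <- function(df, validity = method_validity()) {
  bad <- which(df$measurand == "rna_count" &
               (df$signal < 0 | df$signal != round(df$signal)))
  if (length(bad)) {
    stop("validation error: negative or non-integer rna_count in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- paste(paste(df$preparation, df$detection, df$measurand, sep = "."),
               df$construct, df$iptg_umol_per_L, df$replicate, sep = "|")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    r <- df[idx, , drop = FALSE]
    dapi <- if ("dapi" %in% names(r) && !anyNA(r$dapi)) r$dapi else NULL
    cell_event_table(
      signal = r$signal,
      method = method_id(r$preparation[1], r$detection[1], r$measurand[1],
                         validity = validity),
      sample = sample_id(r$construct[1], r$iptg_umol_per_L[1],
                         r$replicate[1]),
      dapi = dapi)
  })
  out
}

#' Flatten cell event tables back to the long format
#'
#' @param tables a list of [cell_event_table()] objects.
#' @return data.frame in the canonical long format.
#' @export
events_df <- function(tables) {
  if (inherits(tables, "cell_event_table")) tables <- list(tables)
  do.call(rbind, lapply(tables, function(t) {
    data.frame(preparation = t$method$preparation,
               detection = t$method$detection,
               measurand = t$method$measurand,
               construct = t$sample$construct,
               iptg_umol_per_L = t$sample$iptg_umol_per_L,
               replicate = t$sample$replicate,
               signal = t$signal,
               dapi = if (is.null(t$dapi)) NA_real_ else t$dapi)
  }))
}

#' DAPI stainability filter
#'
#' Quality control for cell-to-cell variability in fixation and
#' permeabilization: cells whose DAPI signal is less than half the sample
#' mean are excluded.  The threshold uses the arithmetic mean of all cells in
#' the table *before* any exclusion (single-pass rule); cells at exactly half
#' the mean are retained.
#'
#' @param table a [cell_event_table()] with a `dapi` column.
#' @return list with `table` (the filtered table) and `n_excluded`.
#' @export
dapi_stainability_filter <- function(table) {
  stopifnot(inherits(table, "cell_event_table"))
  if (is.null(table$dapi)) stop("dapi column absent: cannot apply QC filter")
  thr <- 0.5 * mean(table$dapi)
  keep <- table$dapi >= thr
  if (!any(keep)) {
    stop("degenerate sample: all cells below half the mean DAPI signal")
  }
  out <- cell_event_table(table$signal[keep], table$method, table$sample,
                          dapi = table$dapi[keep])
  list(table = out, n_excluded = sum(!keep))
}

#' Write an analysis result set to disk
#'
#' Writes each result table as CSV plus a JSON manifest recording the files,
#' their checksums, the configuration and the seed.  Re-reading the CSVs
#' reproduces integer columns exactly and real columns to the full printed
#' precision (17 significant digits).
#'
#' @param results a named list of data.frames (typical components:
#'   `auc_profiles`, `auc_summary`, `hill_fits`, `friedman`, `pairwise`,
#'   `burst_fits`, `efficiency`), as produced by [run_pipeline()].
#' @param path output directory (created if needed).
#' @param config optional configuration list stored in the manifest.
#' @param seed optional seed stored in the manifest.
#' @return invisibly, the manifest list.
#' @export
write_results <- function(results, path, config = NULL, seed = NULL) {
  tabs <- Filter(function(x) is.data.frame(x) && nrow(x) > 0, results)
  if (length(tabs) == 0L) stop("result set is empty: nothing to write")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(path, paste0(nm, ".csv"))
    df <- tabs[[nm]]
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    }
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    files <- c(files, f)
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    config = config,
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Read back result tables written by [write_results()]
#'
#' @param path directory containing the CSVs and `manifest.json`.
#' @return named list of data.frames plus a `manifest` element.
#' @export
read_results <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf)
  out <- list()
  for (f in manifest$files) {
    nm <- sub("\\.csv$", "", f$name)
    out[[nm]] <- utils::read.csv(file.path(path, f$name),
                                 stringsAsFactors = FALSE)
  }
  out$manifest <- manifest
  out
}
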