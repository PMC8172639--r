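#' Pipeline configuration
#'
#' Bundles the inputs and stage parameters for [run_pipeline()].
#'
#' @param input event data: a long data.frame in the canonical format, a
#'   path readable by [read_event_tables()], or `NULL` to simulate from
#'   `simulation`.
#' @param simulation a [sim_config()] used when `input` is `NULL`.
#' @param stages stages to run, a subset of
#'   `c("qc", "resolvability", "dose_response", "bias", "burst",
#'   "efficiency")`.  QC always runs first; `bias` needs `dose_response`.
#' @param n_boot bootstrap iterations for medians and efficiency ratios.
#' @param tau_rna_min RNA lifetime (minutes) for burst-frequency estimates.
#' @param reference_efficiency assumed absolute hybridization efficiency of
#'   the FISH reference.
#' @param seed integer seed driving simulation and all bootstraps.
#' @param out_dir optional output directory for [write_results()].
#' @param verbose log stage progress and timing to stderr.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL,
                            simulation = sim_config(),
                            stages = c("qc", "resolvability", "dose_response",
                                       "bias", "burst", "efficiency"),
                            n_boot = 1000L,
                            tau_rna_min = 2.8,
                            reference_efficiency = 0.95,
                            seed = 1L,
                            out_dir = NULL,
                            verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(input = input, simulation = simulation, stages = stages,
              n_boot = as.integer(n_boot), tau_rna_min = tau_rna_min,
              reference_efficiency = reference_efficiency,
              seed = as.integer(seed), out_dir = out_dir, verbose = verbose)
  class(cfg) <- "pipeline_config"
  cfg
}

.log_stage <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(paste0("[brass] ", fmt), ...))
}

## stable hash of the configuration for provenance stamping
.config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("input", "out_dir", "verbose"))]
  sprintf("%08x", .string_hash(paste(deparse(keep), collapse = "")))
}

#' Run the split-sample analysis pipeline
#'
#' Executes the analysis stages in dependency order on measured or simulated
#' event tables: DAPI stainability QC (microscopy tables with a DAPI
#' column), AUC resolvability profiles, Hill dose-response fits (raw and
#' RPU-normalized) from bootstrapped medians with clamped inverse-variance
#' weights, Friedman bias report and pairwise sign-test attribution,
#' negative-binomial burst fits of RNA-count tables, and the relative
#' hybridization-efficiency estimate (HCR:FISH).  A stage that fails is
#' recorded in the manifest and its dependents are skipped; independent
#' stages still run.  Identical configuration and seed give bit-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"analysis_result_set"` with data.frame components
#'   (`auc_profiles`, `auc_summary`, `hill_fits`, `friedman`, `pairwise`,
#'   `burst_fits`, `efficiency`, `qc`) plus `manifest` (config hash, seed,
#'   warnings, per-stage status/timing).  If `out_dir` is set the tables and
#'   manifest are also written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  manifest <- list(seed = cfg$seed, config_hash = .config_hash(cfg),
                   stages = list(), warnings = list())
  t_all <- proc.time()[["elapsed"]]

  events <- if (is.null(cfg$input)) {
    .log_stage(cfg, "simulating experiment (seed %d)", cfg$seed)
    simulate_experiment(cfg$simulation, seed = cfg$seed)
  } else if (is.character(cfg$input)) {
    events_df(read_event_tables(cfg$input))
  } else {
    cfg$input
  }

  results <- list()
  ran <- character(0)
  run_stage <- function(name, deps, fun) {
    if (!name %in% cfg$stages && name != "qc") {
      return(list(status = "skipped", reason = "not selected"))
    }
    if (!all(deps %in% ran)) {
      return(list(status = "skipped",
                  reason = paste("missing dependency:",
                                 paste(setdiff(deps, ran), collapse = ","))))
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(list(status = "ok", value = fun()),
                    error = function(e) list(status = "failed",
                                             reason = conditionMessage(e)))
    out$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
    .log_stage(cfg, "stage %-13s %s (%.2fs)", name, out$status, out$seconds)
    out
  }

  ## ---- QC: DAPI stainability filter wherever a dapi column exists --------
  st <- run_stage("qc", character(0), function() {
    has_dapi <- !is.na(events$dapi)
    qc_rows <- list()
    keep <- rep(TRUE, nrow(events))
    key <- paste(events$preparation, events$detection, events$measurand,
                 events$construct, events$iptg_umol_per_L, events$replicate)
    for (k in unique(key[has_dapi])) {
      idx <- which(key == k & has_dapi)
      thr <- 0.5 * mean(events$dapi[idx])
      drop <- events$dapi[idx] < thr
      keep[idx[drop]] <- FALSE
      qc_rows[[k]] <- data.frame(table = k, n_cells = length(idx),
                                 n_excluded = sum(drop))
    }
    list(events = events[keep, , drop = FALSE],
         qc = if (length(qc_rows)) do.call(rbind, qc_rows) else
           data.frame(table = character(0), n_cells = integer(0),
                      n_excluded = integer(0)))
  })
  manifest$stages$qc <- st[setdiff(names(st), "value")]
  if (st$status == "ok") {
    events <- st$value$events
    results$qc <- st$value$qc
    ran <- c(ran, "qc")
  }

  method_key <- function(d) paste(d$preparation, d$detection, d$measurand)
  inducible <- events[events$construct == "inducible", ]

  ## ---- resolvability ------------------------------------------------------
  st <- run_stage("resolvability", "qc", function() {
    prof_rows <- list()
    summ_rows <- list()
    for (mk in unique(method_key(inducible))) {
      sub <- inducible[method_key(inducible) == mk, ]
      for (r in sort(unique(sub$replicate))) {
        sr <- sub[sub$replicate == r, ]
        sigs <- split(sr$signal, sr$iptg_umol_per_L)
        prof <- auc_profile(sigs, levels = sort(unique(sr$iptg_umol_per_L)),
                            replicate = r)
        lv <- prof$levels
        prof_rows[[paste(mk, r)]] <- data.frame(
          method = mk, replicate = r,
          level_low = lv[-length(lv)], level_high = lv[-1],
          auc = unname(prof$auc_adjacent))
        summ_rows[[paste(mk, r)]] <- data.frame(
          method = mk, replicate = r, average_auc = prof$average_auc)
      }
    }
    list(auc_profiles = do.call(rbind, prof_rows),
         auc_summary = do.call(rbind, summ_rows))
  })
  manifest$stages$resolvability <- st[setdiff(names(st), "value")]
  if (st$status == "ok") {
    results$auc_profiles <- st$value$auc_profiles
    results$auc_summary <- st$value$auc_summary
    ran <- c(ran, "resolvability")
  }

  ## ---- dose response ------------------------------------------------------
  st <- run_stage("dose_response", "qc", function() {
    rows <- list()
    for (mk in unique(method_key(events))) {
      sub <- events[method_key(events) == mk, ]
      for (r in sort(unique(sub$replicate))) {
        sr <- sub[sub$replicate == r, ]
        ind <- sr[sr$construct == "inducible", ]
        if (nrow(ind) == 0L) next
        lv <- sort(unique(ind$iptg_umol_per_L))
        locs <- lapply(lv, function(l) {
          location_with_bootstrap(
            ind$signal[ind$iptg_umol_per_L == l], n_boot = cfg$n_boot,
            seed = substream_seed(cfg$seed, paste("boot", mk, r, l)))
        })
        med <- vapply(locs, `[[`, numeric(1), "median")
        vb <- vapply(locs, `[[`, numeric(1),
                     "bootstrap_variance_of_median")
        w <- clamp_weights(1 / vb)
        pos <- sr$signal[sr$construct == "positive_control"]
        neg <- sr$signal[sr$construct == "negative_control"]
        fits <- list(raw = fit_hill(lv, med, w))
        if (length(pos) && length(neg)) {
          lp <- location_with_bootstrap(pos, n_boot = cfg$n_boot,
                  seed = substream_seed(cfg$seed, paste("boot+", mk, r)))
          ln <- location_with_bootstrap(neg, n_boot = cfg$n_boot,
                  seed = substream_seed(cfg$seed, paste("boot-", mk, r)))
          rpu <- mapply(function(m, v) {
            u <- rpu_normalize(m, lp$median, ln$median, v,
                               lp$bootstrap_variance_of_median,
                               ln$bootstrap_variance_of_median)
            c(u$rpu, u$variance)
          }, med, vb)
          w_rpu <- clamp_weights(1 / rpu[2, ])
          fits$rpu <- fit_hill(lv, rpu[1, ], w_rpu, rpu_normalized = TRUE)
        }
        for (nm in names(fits)) {
          f <- fits[[nm]]
          for (par in names(f$coefficients)) {
            rows[[length(rows) + 1L]] <- data.frame(
              method = mk, replicate = r, normalization = nm,
              parameter = par, estimate = unname(f$coefficients[par]),
              ci_low = if (is.null(f$ci)) NA_real_ else f$ci[par, "lower"],
              ci_high = if (is.null(f$ci)) NA_real_ else f$ci[par, "upper"],
              status = f$status)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
  manifest$stages$dose_response <- st[setdiff(names(st), "value")]
  if (st$status == "ok") {
    results$hill_fits <- st$value
    ran <- c(ran, "dose_response")
  }

  ## ---- bias attribution ---------------------------------------------------
  st <- run_stage("bias", c("qc", "dose_response"), function() {
    fr <- bias_report(results$hill_fits)
    methods <- unique(events[events$construct == "inducible",
                             c("preparation", "detection", "measurand")])
    pw_rows <- list()
    for (step in c("M", "D", "P")) {
      pairs <- attribution_pairs(methods, step)
      for (i in seq_len(nrow(pairs))) {
        pa <- pairs[i, ]
        sub_a <- inducible[inducible$preparation == pa$preparation_a &
                           inducible$detection == pa$detection_a &
                           inducible$measurand == pa$measurand_a, ]
        sub_b <- inducible[inducible$preparation == pa$preparation_b &
                           inducible$detection == pa$detection_b &
                           inducible$measurand == pa$measurand_b, ]
        reps <- intersect(unique(sub_a$replicate), unique(sub_b$replicate))
        profs_a <- lapply(reps, function(r) {
          sr <- sub_a[sub_a$replicate == r, ]
          auc_profile(split(sr$signal, sr$iptg_umol_per_L), replicate = r)
        })
        profs_b <- lapply(reps, function(r) {
          sr <- sub_b[sub_b$replicate == r, ]
          auc_profile(split(sr$signal, sr$iptg_umol_per_L), replicate = r)
        })
        cmp <- pairwise_auc_table(profs_a, profs_b,
                                  label_a = pa$label_a, label_b = pa$label_b)
        pw_rows[[length(pw_rows) + 1L]] <- data.frame(
          method_a = pa$label_a, method_b = pa$label_b,
          differing_step = step,
          n_a_higher = cmp$n_a_higher, n_b_higher = cmp$n_b_higher,
          n_ties = cmp$n_ties, p_two_sided = cmp$p_two_sided)
      }
    }
    list(friedman = fr, pairwise = do.call(rbind, pw_rows))
  })
  manifest$stages$bias <- st[setdiff(names(st), "value")]
  if (st$status == "ok") {
    results$friedman <- st$value$friedman
    results$pairwise <- st$value$pairwise
    ran <- c(ran, "bias")
  }

  ## ---- burst inference ----------------------------------------------------
  st <- run_stage("burst", "qc", function() {
    counts_tabs <- events[events$measurand == "rna_count", ]
    if (nrow(counts_tabs) == 0L) stop("no rna_count tables available")
    ## HCR efficiency relative to the FISH reference, estimated from the
    ## data (pooled median of mean and Fano-1 ratios); 1 if HCR is absent
    ind <- counts_tabs[counts_tabs$construct == "inducible", ]
    rel_hcr <- tryCatch({
      by_prep <- function(prep) {
        s <- ind[ind$preparation == prep, ]
        split(as.integer(s$signal), paste(s$iptg_umol_per_L, s$replicate))
      }
      .overall_ratio_point(by_prep("HCR"), by_prep("FISH"))
    }, error = function(e) 1)
    rows <- list()
    key <- paste(counts_tabs$preparation, counts_tabs$construct,
                 counts_tabs$iptg_umol_per_L, counts_tabs$replicate)
    for (k in unique(key)) {
      sub <- counts_tabs[key == k, ]
      eff <- if (sub$preparation[1] == "FISH") cfg$reference_efficiency else
        min(cfg$reference_efficiency * rel_hcr, 1)
      fit <- tryCatch(fit_negative_binomial(as.integer(sub$signal)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      bp <- if (fit$status == "ok") {
        burst_parameters(fit$r, fit$p_nb, cfg$tau_rna_min, eff)
      } else NULL
      rows[[k]] <- data.frame(
        method = paste(sub$preparation[1], "microscopy rna_count"),
        preparation = sub$preparation[1],
        construct = sub$construct[1],
        iptg_umol_per_L = sub$iptg_umol_per_L[1],
        replicate = sub$replicate[1],
        r = fit$r, p_nb = fit$p_nb,
        burst_size = if (is.null(bp)) NA_real_ else bp$burst_size,
        burst_frequency = if (is.null(bp)) NA_real_ else bp$burst_frequency,
        efficiency = eff,
        corrected_burst_size = if (is.null(bp)) NA_real_ else
          bp$corrected_burst_size,
        status = fit$status)
    }
    if (length(rows) == 0L) stop("no RNA-count table could be fitted")
    do.call(rbind, rows)
  })
  manifest$stages$burst <- st[setdiff(names(st), "value")]
  if (st$status == "ok") {
    results$burst_fits <- st$value
    ran <- c(ran, "burst")
  }

  ## ---- hybridization efficiency ------------------------------------------
  st <- run_stage("efficiency", "qc", function() {
    counts_tabs <- events[events$measurand == "rna_count" &
                          events$construct == "inducible", ]
    if (nrow(counts_tabs) == 0L) stop("no rna_count tables available")
    skey <- paste(counts_tabs$iptg_umol_per_L, counts_tabs$replicate)
    tab_of <- function(prep) {
      sub <- counts_tabs[counts_tabs$preparation == prep, ]
      split(as.integer(sub$signal),
            paste(sub$iptg_umol_per_L, sub$replicate))
    }
    hcr <- tab_of("HCR")
    fish <- tab_of("FISH")
    if (length(hcr) == 0L || length(fish) == 0L) {
      stop("need both FISH and HCR rna_count tables")
    }
    est <- efficiency_ratio(hcr, fish, n_boot = cfg$n_boot,
                            reference_efficiency = cfg$reference_efficiency,
                            seed = substream_seed(cfg$seed, "efficiency"))
    df <- est$per_sample
    df$overall_ratio <- est$overall_ratio
    df$overall_ci_low <- est$overall_ci[1]
    df$overall_ci_high <- est$overall_ci[2]
    df$absolute_efficiency <- est$absolute_efficiency
    df
  })
  manifest$stages$efficiency <- st[setdiff(names(st), "value")]
  if (st$status == "ok") {
    results$efficiency <- st$value
    ran <- c(ran, "efficiency")
  }

  manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
  results$manifest <- manifest
  class(results) <- "analysis_result_set"
  if (!is.null(cfg$out_dir)) {
    write_results(results[setdiff(names(results), "manifest")],
                  cfg$out_dir,
                  config = list(hash = manifest$config_hash,
                                stages = cfg$stages, n_boot = cfg$n_boot,
                                tau_rna_min = cfg$tau_rna_min,
                                reference_efficiency = cfg$reference_efficiency),
                  seed = cfg$seed)
  }
  results
}

#' @export
print.analysis_result_set <- function(x, ...) {
  cat("<analysis result set>\n")
  for (nm in setdiff(names(x), "manifest")) {
    cat(sprintf("  %-13s %d rows\n", nm, nrow(x[[nm]])))
  }
  st <- x$manifest$stages
  cat("stages:", paste(sprintf("%s=%s", names(st),
                               vapply(st, `[[`, "", "status")),
                       collapse = ", "), "\n")
  invisible(x)
}
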