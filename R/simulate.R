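#' Hill function
#'
#' `offset + A * x^n / (K_half^n + x^n)`, defined at `x = 0` as `offset`.
#'
#' @param x non-negative stimulus concentration(s).
#' @param offset baseline signal at zero stimulus.
#' @param A response amplitude.
#' @param K_half concentration of half-maximal response (same units as `x`).
#' @param n effective cooperativity (> 0).
#' @return numeric vector of the same length as `x`.
#' @export
hill_function <- function(x, offset, A, K_half, n) {
  if (K_half <= 0 || n <= 0 || A < 0) stop("invalid Hill parameters")
  xn <- ifelse(x > 0, x^n, 0)
  offset + A * xn / (K_half^n + xn)
}

#' Simulation configuration for a synthetic split-sample experiment
#'
#' Defaults describe the benchmark design the analysis targets: 10 cultures
#' per replicate (8 IPTG levels of an inducible construct plus constitutive
#' positive and empty negative controls), 3 biological replicates, 20000
#' cells per flow-cytometry sample and 500 per microscopy sample, latent RNA
#' counts from a two-state (negative-binomial) bursting model whose burst
#' frequency and size follow Hill dose-responses, binomial thinning by
#' hybridization efficiency per labeling preparation (FISH 0.95, HCR 0.341),
#' a Hill-shaped protein response with lognormal cell-to-cell noise, and a
#' per-replicate stimulus-potency multiplier emulating variability of active
#' inducer concentration between replicates.
#'
#' @param stimulus stimulus series (micromol/L IPTG).
#' @param n_replicates number of biological replicates.
#' @param cells_flow,cells_microscopy cells measured per sample per detection.
#' @param hill_f,hill_b Hill parameters (lists with `offset`, `A`, `K_half`,
#'   `n`) for burst frequency (per minute) and burst size (transcripts/burst)
#'   as functions of effective stimulus.
#' @param tau_rna_min RNA lifetime in minutes.
#' @param eff_fish,eff_hcr hybridization efficiencies in (0, 1].
#' @param hill_protein Hill parameters of the protein response (a.u.).
#' @param cv_protein lognormal cell-to-cell CV of the protein level.
#' @param rho per-replicate stimulus potency multipliers (> 0), recycled to
#'   `n_replicates`.
#' @param brightness,cv_brightness mean fluorescence per detected transcript
#'   (a.u.) and its lognormal per-cell CV.
#' @param background named list with `flow` and `microscopy` elements, each
#'   `c(mean, sd)` of additive background fluorescence (a.u.).
#' @param cv_detection named list with `flow` and `microscopy` multiplicative
#'   detection-noise CVs.
#' @param prep_protein_scale named multiplier on protein signal per
#'   preparation (fixation/hybridization dims fluorescent protein).
#' @param dapi_meanlog,dapi_sdlog lognormal parameters of the DAPI stain.
#' @param frac_poor_permeabilized fraction of cells with poor
#'   permeabilization (their DAPI and RNA signals are suppressed).
#' @param poor_factor multiplicative suppression for poorly permeabilized
#'   cells.
#' @param pos_protein positive-control protein level (a.u.).
#' @param pos_f,pos_b constitutive burst frequency/size of the positive
#'   control.
#' @param neg_protein negative-control (autofluorescence) level (a.u.).
#' @param neg_lambda mean nonspecific count in the negative control.
#' @param couple_rna_protein if `TRUE`, RNA and protein share a per-cell
#'   lognormal scaling factor; off by default (no per-cell correlation is
#'   modeled).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(stimulus = stimulus_series(),
                       n_replicates = 3L,
                       cells_flow = 20000L,
                       cells_microscopy = 500L,
                       hill_f = list(offset = 0.05, A = 1.0, K_half = 40, n = 1.7),
                       hill_b = list(offset = 1.0, A = 4.0, K_half = 40, n = 1.7),
                       tau_rna_min = 2.8,
                       eff_fish = 0.95,
                       eff_hcr = 0.341,
                       hill_protein = list(offset = 200, A = 20000,
                                           K_half = 40, n = 1.7),
                       cv_protein = 0.35,
                       rho = c(1, 0.7, 1.4),
                       brightness = 120,
                       cv_brightness = 0.25,
                       background = list(flow = c(mean = 150, sd = 50),
                                         microscopy = c(mean = 300, sd = 100)),
                       cv_detection = list(flow = 0.05, microscopy = 0.15),
                       prep_protein_scale = c(Kn = 1, Cm = 0.97,
                                              FISH = 0.8, HCR = 0.85),
                       dapi_meanlog = log(1000),
                       dapi_sdlog = 0.3,
                       frac_poor_permeabilized = 0.05,
                       poor_factor = 0.2,
                       pos_protein = 18000,
                       pos_f = 1.0,
                       pos_b = 4.0,
                       neg_protein = 150,
                       neg_lambda = 0.05,
                       couple_rna_protein = FALSE) {
  cfg <- as.list(environment())
  if (cfg$eff_fish <= 0 || cfg$eff_fish > 1 ||
      cfg$eff_hcr <= 0 || cfg$eff_hcr > 1) {
    stop("hybridization efficiencies must lie in (0, 1]")
  }
  if (any(cfg$rho <= 0)) stop("potency multipliers must be > 0")
  if (cfg$cv_protein < 0 || cfg$cv_brightness < 0) stop("CVs must be >= 0")
  cfg$rho <- rep_len(cfg$rho, cfg$n_replicates)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate latent RNA counts from the two-state bursting model
#'
#' Stationary counts of the two-state promoter model are negative binomial
#' with size `r = f * tau` and success probability `p = 1 / (1 + b)`, so the
#' mean is `r * b`.
#'
#' @param f_per_min burst frequency (bursts per minute, > 0).
#' @param b burst size (transcripts per burst, > 0).
#' @param tau_min RNA lifetime in minutes (> 0).
#' @param n_cells number of cells to draw.
#' @return integer vector of RNA counts per cell.
#' @export
simulate_rna_counts <- function(f_per_min, b, tau_min = 2.8, n_cells = 1L) {
  if (f_per_min <= 0 || b <= 0 || tau_min <= 0) {
    stop("f, b and tau must all be > 0")
  }
  r <- f_per_min * tau_min
  p <- 1 / (1 + b)
  stats::rnbinom(n_cells, size = r, prob = p)
}

#' Binomial thinning of molecule counts
#'
#' Each molecule is detected independently with probability `efficiency`
#' (the hybridization efficiency of the labeling method).
#'
#' @param counts non-negative integer vector of latent molecule counts.
#' @param efficiency detection probability in (0, 1].
#' @return integer vector of detected counts, elementwise `<= counts`.
#' @export
thin_counts <- function(counts, efficiency) {
  if (!is_count_vector(counts)) stop("counts must be non-negative integers")
  if (efficiency <= 0 || efficiency > 1) {
    stop("efficiency must lie in (0, 1]")
  }
  if (efficiency == 1) return(as.integer(counts))
  stats::rbinom(length(counts), size = counts, prob = efficiency)
}

#' Simulate per-cell protein signals
#'
#' Deterministic Hill response times unit-mean lognormal cell-to-cell noise,
#' plus an additive background draw.
#'
#' @param x stimulus concentration.
#' @param hill list with `offset`, `A`, `K_half`, `n`.
#' @param n_cells number of cells.
#' @param cv lognormal cell-to-cell coefficient of variation (>= 0).
#' @param background `c(mean, sd)` of Gaussian additive background.
#' @return numeric vector of per-cell signals.
#' @export
simulate_protein <- function(x, hill, n_cells, cv = 0,
                             background = c(mean = 0, sd = 0)) {
  mu <- hill_function(x, hill$offset, hill$A, hill$K_half, hill$n)
  sig <- mu * rlnorm_cv(n_cells, cv)
  if (background[[2]] > 0 || background[[1]] != 0) {
    sig <- sig + stats::rnorm(n_cells, background[[1]], background[[2]])
  }
  sig
}

## latent biology of one culture (shared by every method derived from it)
.simulate_culture <- function(cfg, construct, iptg, replicate, n_pool) {
  if (construct == "inducible") {
    x_eff <- iptg * cfg$rho[replicate]
    f <- hill_function(x_eff, cfg$hill_f$offset, cfg$hill_f$A,
                       cfg$hill_f$K_half, cfg$hill_f$n)
    b <- hill_function(x_eff, cfg$hill_b$offset, cfg$hill_b$A,
                       cfg$hill_b$K_half, cfg$hill_b$n)
    counts <- simulate_rna_counts(f, b, cfg$tau_rna_min, n_pool)
    protein <- hill_function(x_eff, cfg$hill_protein$offset,
                             cfg$hill_protein$A, cfg$hill_protein$K_half,
                             cfg$hill_protein$n) * rlnorm_cv(n_pool, cfg$cv_protein)
  } else if (construct == "positive_control") {
    counts <- simulate_rna_counts(cfg$pos_f, cfg$pos_b, cfg$tau_rna_min, n_pool)
    protein <- cfg$pos_protein * rlnorm_cv(n_pool, cfg$cv_protein)
  } else {
    counts <- stats::rpois(n_pool, cfg$neg_lambda)
    protein <- cfg$neg_protein * rlnorm_cv(n_pool, cfg$cv_protein)
  }
  if (isTRUE(cfg$couple_rna_protein)) {
    shared <- rlnorm_cv(n_pool, 0.2)
    counts <- stats::rbinom(n_pool, counts + stats::rpois(n_pool, counts),
                            pmin(shared / 2, 1))
    protein <- protein * shared
  }
  ## permeabilization quality affects hybridization-dependent signals + DAPI
  poor <- stats::runif(n_pool) < cfg$frac_poor_permeabilized
  list(counts = counts, protein = protein, poor = poor)
}

#' Simulate a complete split-sample experiment
#'
#' Generates per-cell event tables for every method in the validity table,
#' every culture (8 stimulus levels of the inducible construct plus positive
#' and negative controls) and every replicate.  The split-sample contract
#' holds by construction: all methods derived from one culture share that
#' culture's latent RNA counts and protein levels; FISH- and HCR-derived
#' tables differ only by their thinning efficiency and method noise layers;
#' each labeling preparation's thinning outcome is shared between flow and
#' microscopy detection of the same culture; protein and RNA measurands of
#' one (preparation, detection) route observe the same cells.  Per-table
#' random substreams are derived from the single seed by stable key hashing,
#' so the output is fully deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param validity method validity table (defaults to the packaged
#'   twelve-method design).
#' @return data.frame in the canonical long event format (one row per cell).
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1L,
                                validity = method_validity()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_pool <- max(cfg$cells_flow, cfg$cells_microscopy)
  cultures <- rbind(
    data.frame(construct = "inducible", iptg = cfg$stimulus),
    data.frame(construct = c("positive_control", "negative_control"),
               iptg = 0))
  out <- vector("list", 0L)
  for (rep_i in seq_len(cfg$n_replicates)) {
    for (ci in seq_len(nrow(cultures))) {
      construct <- cultures$construct[ci]
      iptg <- cultures$iptg[ci]
      ckey <- paste("culture", construct, iptg, rep_i)
      lat <- with_substream(seed, ckey,
        .simulate_culture(cfg, construct, iptg, rep_i, n_pool))
      ## thinning outcome is per labeling preparation, shared across detection
      thinned <- list()
      for (prep in intersect(c("FISH", "HCR"), validity$preparation)) {
        eff <- if (prep == "FISH") cfg$eff_fish else cfg$eff_hcr
        thinned[[prep]] <- with_substream(seed, paste("thin", prep, ckey), {
          tc <- thin_counts(lat$counts, eff)
          ## poorly permeabilized cells label poorly
          tc[lat$poor] <- thin_counts(tc[lat$poor], cfg$poor_factor)
          tc
        })
      }
      routes <- unique(validity[c("preparation", "detection")])
      for (ri in seq_len(nrow(routes))) {
        prep <- routes$preparation[ri]
        det <- routes$detection[ri]
        n_det <- if (det == "flow") cfg$cells_flow else cfg$cells_microscopy
        rkey <- paste("route", prep, det, ckey)
        idx <- with_substream(seed, rkey,
                              sample.int(n_pool, min(n_det, n_pool)))
        dapi <- if (det == "microscopy") {
          with_substream(seed, paste("dapi", rkey), {
            d <- stats::rlnorm(length(idx), cfg$dapi_meanlog, cfg$dapi_sdlog)
            d[lat$poor[idx]] <- d[lat$poor[idx]] * cfg$poor_factor
            d
          })
        } else NULL
        bg <- cfg$background[[det]]
        cvd <- cfg$cv_detection[[det]]
        meas <- validity$measurand[validity$preparation == prep &
                                   validity$detection == det]
        for (m in meas) {
          mkey <- paste("meas", m, rkey)
          sig <- with_substream(seed, mkey, {
            if (m == "protein") {
              lat$protein[idx] * cfg$prep_protein_scale[[prep]] *
                rlnorm_cv(length(idx), cvd) +
                stats::rnorm(length(idx), bg[[1]], bg[[2]])
            } else if (m == "rna_fluorescence") {
              thinned[[prep]][idx] * cfg$brightness *
                rlnorm_cv(length(idx), cfg$cv_brightness) *
                rlnorm_cv(length(idx), cvd) +
                stats::rnorm(length(idx), bg[[1]], bg[[2]])
            } else {
              as.numeric(thinned[[prep]][idx])
            }
          })
          out[[length(out) + 1L]] <- data.frame(
            preparation = prep, detection = det, measurand = m,
            construct = construct, iptg_umol_per_L = iptg,
            replicate = rep_i, signal = sig,
            dapi = if (is.null(dapi)) NA_real_ else dapi)
        }
      }
    }
  }
  do.call(rbind, out)
}
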