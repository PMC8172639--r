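# shared fixtures and independent oracles for the test suite

## brute-force AUC: average over all (high, low) pairs, ties counting half
auc_brute <- function(low, high) {
  cmp <- outer(high, low, ">") + 0.5 * outer(high, low, "==")
  mean(cmp)
}

## build a small long-format event data.frame for one method
make_events <- function(preparation = "Kn", detection = "flow",
                        measurand = "protein", construct = "inducible",
                        iptg = 0, replicate = 1, signal = c(1, 2, 3),
                        dapi = NA_real_) {
  data.frame(preparation = preparation, detection = detection,
             measurand = measurand, construct = construct,
             iptg_umol_per_L = iptg, replicate = replicate,
             signal = signal, dapi = dapi)
}

## negative-binomial log-likelihood used by the grid-search oracle
nb_loglik <- function(counts, r, p) {
  sum(dnbinom(counts, size = r, prob = p, log = TRUE))
}

## block-based Monte-Carlo standard error of a statistic of iid draws
block_se <- function(x, stat, n_blocks = 100) {
  blocks <- split(x, rep(seq_len(n_blocks), length.out = length(x)))
  vals <- vapply(blocks, stat, numeric(1))
  sd(vals) / sqrt(n_blocks)
}

## reduced-scale simulation config used by integration tests
small_sim <- function(...) {
  sim_config(cells_flow = 300L, cells_microscopy = 150L, ...)
}
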