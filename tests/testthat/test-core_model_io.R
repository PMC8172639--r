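test_that("method identity validates the benchmark design and rejects impossible routes", {
  validity <- method_validity()
  expect_equal(nrow(validity), 12L)
  for (i in seq_len(nrow(validity))) {
    m <- method_id(validity$preparation[i], validity$detection[i],
                   validity$measurand[i])
    expect_s3_class(m, "method_id")
  }
  # RNA counting needs microscopy and an in-situ labeling preparation
  expect_error(method_id("FISH", "flow", "rna_count"), "microscopy")
  expect_error(method_id("Kn", "microscopy", "rna_count"))
  expect_error(method_id("Kn", "flow", "rna_fluorescence"), "labeling")
  # validity table is data: a combination outside it is rejected even if
  # structurally possible
  expect_error(method_id("Kn", "microscopy", "protein"), "validity")
})

test_that("sample identity enforces control conventions", {
  s <- sample_id("inducible", 40, 2)
  expect_equal(s$iptg_umol_per_L, 40)
  expect_error(sample_id("positive_control", 10), "iptg")
  expect_error(sample_id("inducible", -5))
  expect_error(sample_id("inducible", 0, 0))
  expect_equal(stimulus_series(), c(0, 5, 10, 20, 40, 100, 400, 1000))
})

test_that("event tables read from CSV partition by method, sample and replicate", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "events.csv")
  df <- make_events(signal = c(1, 2, 3))
  write.csv(df, f, row.names = FALSE)
  tabs <- read_event_tables(f)
  expect_length(tabs, 1L)
  expect_equal(tabs[[1]]$n_cells, 3L)
  expect_equal(tabs[[1]]$signal, c(1, 2, 3))

  # two replicates in one file partition into two tables
  df2 <- rbind(make_events(replicate = 1, signal = 1:3),
               make_events(replicate = 2, signal = 4:5))
  write.csv(df2, f, row.names = FALSE)
  tabs2 <- read_event_tables(f)
  expect_length(tabs2, 2L)
  expect_setequal(vapply(tabs2, function(t) t$n_cells, integer(1)), c(3L, 2L))

  # negative RNA count is a validation error naming the row
  df3 <- make_events(preparation = "FISH", detection = "microscopy",
                     measurand = "rna_count", signal = c(0, 2, -1))
  write.csv(df3, f, row.names = FALSE)
  expect_error(read_event_tables(f), "row")

  # missing required column is a schema error
  df4 <- df[, setdiff(names(df), "replicate")]
  write.csv(df4, f, row.names = FALSE)
  expect_error(read_event_tables(f), "replicate")
})

test_that("a YAML schema maps user column names onto the canonical ones", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "events.csv")
  df <- make_events(signal = c(5, 6))
  names(df)[names(df) == "signal"] <- "fl_au"
  write.csv(df, f, row.names = FALSE)
  sf <- file.path(dir, "schema.yaml")
  writeLines("signal: fl_au", sf)
  tabs <- read_event_tables(f, schema = sf)
  expect_equal(tabs[[1]]$signal, c(5, 6))
  writeLines("signal: no_such_column", sf)
  expect_error(read_event_tables(f, schema = sf), "schema")
})

test_that("DAPI stainability filter excludes cells below half the pre-exclusion mean", {
  tab <- function(dapi) {
    cell_event_table(seq_along(dapi),
                     method_id("FISH", "microscopy", "protein"),
                     sample_id("inducible", 40, 1), dapi = dapi)
  }
  # all equal: nothing excluded
  expect_equal(dapi_stainability_filter(tab(rep(2, 5)))$n_excluded, 0L)
  # mean 0.85, threshold 0.425: only the 0.4 cell goes
  res <- dapi_stainability_filter(tab(c(1, 1, 1, 0.4)))
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$table$dapi, c(1, 1, 1))
  # mean 0.75, threshold 0.375: both retained (0.5 is not below half the mean)
  expect_equal(dapi_stainability_filter(tab(c(1, 0.5)))$n_excluded, 0L)
  # contract errors
  no_dapi <- cell_event_table(1:3, method_id("FISH", "microscopy", "protein"),
                              sample_id("inducible", 40, 1))
  expect_error(dapi_stainability_filter(no_dapi), "dapi")
})

test_that("the DAPI filter is single-pass: the threshold uses the pre-exclusion mean", {
  # dapi {10, 2.2, 1}: mean 4.4, threshold 2.2 -> the tie at 2.2 is retained
  # and only the 1 is excluded.  Re-filtering the retained cells (mean 6.1,
  # threshold 3.05) would drop the 2.2, so a recomputed-mean rule would give
  # a different answer.
  tab <- cell_event_table(1:3, method_id("FISH", "microscopy", "protein"),
                          sample_id("inducible", 40, 1),
                          dapi = c(10, 2.2, 1))
  res <- dapi_stainability_filter(tab)
  expect_equal(res$n_excluded, 1L)
  expect_true(2.2 %in% res$table$dapi)
  res2 <- dapi_stainability_filter(res$table)
  expect_equal(res2$n_excluded, 1L)  # re-application excludes more
})

test_that("result sets round-trip through CSV plus manifest", {
  dir <- withr::local_tempdir()
  auc <- data.frame(method = "Kn flow protein", replicate = 1L,
                    level_low = stimulus_series()[-8],
                    level_high = stimulus_series()[-1],
                    auc = c(0.5, 0.61, 0.721234567891234, 0.9, 1, 1, 0.97))
  hill <- data.frame(method = "Kn flow protein", replicate = 1L,
                     normalization = "raw",
                     parameter = c("offset", "A", "K_half", "n"),
                     estimate = c(0.1, 1.23456789012345678, 20, 2),
                     ci_low = c(0, 1.1, 18, 1.9),
                     ci_high = c(0.2, 1.3, 22, 2.1),
                     status = "converged")
  mf <- write_results(list(auc_profiles = auc, hill_fits = hill), dir,
                      config = list(n_boot = 10), seed = 42L)
  expect_length(mf$files, 2L)
  back <- read_results(dir)
  # an 8-level series gives 7 adjacent-pair rows
  expect_equal(nrow(back$auc_profiles), 7L)
  expect_equal(back$auc_profiles$level_low, auc$level_low)
  expect_equal(back$auc_profiles$auc, auc$auc, tolerance = 1e-15)
  expect_equal(back$hill_fits$estimate, hill$estimate, tolerance = 1e-15)
  expect_equal(back$manifest$seed, 42L)
  expect_error(write_results(list(), dir), "empty")
  expect_error(write_results(list(auc = auc[0, ]), dir), "empty")
})
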