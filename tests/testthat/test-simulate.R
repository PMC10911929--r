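test_that("identical config and seed reproduce the cohort field for field", {
  a <- simulate_cohort(simulation_config(seed = 99, n_samples = 40L,
                                         n_lines = 15L))
  b <- simulate_cohort(simulation_config(seed = 99, n_samples = 40L,
                                         n_lines = 15L))
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_config(seed = 100, n_samples = 40L,
                                          n_lines = 15L))
  expect_false(identical(a$segments, c2$segments))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, f_amp = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(seed = 1, delta = -1), "non-negative")
  # passenger farther from the oncogene than the widest amplicon
  cfg <- simulation_config(seed = 1, passenger_indices = c(20L, 11L),
                           amplicon_width = c(1e6, 2e6))
  expect_error(simulate_cohort(cfg), "unachievable inclusion")
})

test_that("a noiseless cohort closes the loop: calls equal the planted truth", {
  cfg <- simulation_config(seed = 33, n_samples = 60L, f_coamp = 1,
                           log2_noise_sd = 0, line_cn_noise_sd = 0,
                           log2_amp_mean = 2)
  co <- simulate_cohort(cfg)
  calls <- merge_amplified_intervals(
    gene_level_calls(co$segments, co$annotation))
  cc <- calls$calls
  tr <- co$truth

  # every truly amplified sample calls both the oncogene and (f_coamp = 1)
  # the primary passenger amplified, across all four platform cutoffs
  for (smp in tr$samples$sample) {
    onc <- cc$status[cc$sample == smp & cc$gene == tr$oncogene]
    expect_equal(onc == "amplified",
                 tr$samples$amplified[tr$samples$sample == smp])
    pas <- cc$status[cc$sample == smp & cc$gene == tr$primary_passenger]
    expect_equal(pas == "amplified",
                 tr$samples$coamplified[tr$samples$sample == smp])
  }

  grp <- classify_cell_lines(co$line_cn, tr$oncogene, tr$primary_passenger)
  rep <- truth_report(co, calls = calls, groups = grp)
  expect_equal(unname(rep$amplification), c(1, 1))
  expect_equal(unname(rep$coamplification), c(1, 1))
  # group assignment reproduces the planted line labels exactly
  expect_setequal(grp$coamp_ids, tr$lines$line[tr$lines$group == "coamp"])
  expect_setequal(grp$onc_only_ids,
                  tr$lines$line[tr$lines$group == "onc_only"])
  expect_setequal(grp$excluded$id,
                  tr$lines$line[tr$lines$group == "not_amplified"])
})

test_that("empirical frequencies converge to f_amp and f_coamp", {
  co <- simulate_cohort(simulation_config(seed = 61, n_samples = 2000L,
                                          n_lines = 10L))
  tr <- co$truth$samples
  f_amp_hat <- mean(tr$amplified)
  se_amp <- sqrt(0.43 * 0.57 / 2000)
  expect_lte(abs(f_amp_hat - 0.43), 3 * se_amp)

  n_amp <- sum(tr$amplified)
  f_coamp_hat <- sum(tr$coamplified) / n_amp
  se_co <- sqrt(0.58 * 0.42 / n_amp)
  expect_lte(abs(f_coamp_hat - 0.58), 3 * se_co)
})

test_that("the planted dependency effect dominates the volcano", {
  co <- simulate_cohort(simulation_config(seed = 5, n_samples = 30L,
                                          n_lines = 60L, delta = 1,
                                          dep_noise_sd = 0.1))
  tr <- co$truth
  grp <- classify_cell_lines(co$line_cn, tr$oncogene, tr$primary_passenger)
  scr <- coamp_screen(co$dependency, grp)
  rep <- truth_report(co, groups = grp, screen = scr)
  expect_true(all(rep$targets$significant))
  expect_true(all(rep$targets$is_min_p))
  expect_equal(rep$targets$median_diff, rep(-1, 3), tolerance = 0.2)
})

test_that("an empty planted-target set reports recovery as not applicable", {
  co <- simulate_cohort(simulation_config(seed = 9, n_samples = 20L,
                                          n_lines = 40L,
                                          n_collateral_targets = 0L))
  grp <- classify_cell_lines(co$line_cn, co$truth$oncogene,
                             co$truth$primary_passenger)
  scr <- coamp_screen(co$dependency, grp)
  rep <- truth_report(co, groups = grp, screen = scr)
  expect_identical(rep$targets, NA)
})

test_that("cohort files round-trip through the package readers", {
  co <- simulate_cohort(simulation_config(seed = 14, n_samples = 12L,
                                          n_lines = 8L))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  seg <- read_segments(paths[["segments"]],
                       platform_map = co$platform_map)
  expect_equal(as.data.frame(seg)[order(seg$sample, seg$chromosome, seg$start), ],
               as.data.frame(co$segments)[order(co$segments$sample,
                                                co$segments$chromosome,
                                                co$segments$start), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  dep <- read_matrix(paths[["dependency"]], "dependency_score")
  expect_equal(dep, co$dependency, tolerance = 1e-12, ignore_attr = TRUE)
  ann <- read_gene_annotation(paths[["genes"]],
                              oncogenes = co$truth$oncogene)
  expect_equal(ann$start, co$annotation$start)
})
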