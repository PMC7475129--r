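test_that("flow simulator produces the scheduled breath train deterministically", {
  spec <- sim_protocol(duration_s = 600, f_R = 80, noise_sd = 0, seed = 1)
  sim <- simulate_flow_trace(spec)
  expect_equal(length(sim$trace$samples), 600 * 200)
  expect_equal(nrow(sim$log), 0)
  # 80 brpm x 10 min = 800 cycles; segmentation reports all but the last
  bt <- segment_breaths(sim$trace)
  expect_equal(nrow(bt), 799)

  s1 <- simulate_flow_trace(sim_protocol(duration_s = 60, seed = 7))
  s2 <- simulate_flow_trace(sim_protocol(duration_s = 60, seed = 7))
  expect_identical(s1$trace$samples, s2$trace$samples)
  s3 <- simulate_flow_trace(sim_protocol(duration_s = 60, seed = 8))
  expect_false(identical(s1$trace$samples, s3$trace$samples))
})

test_that("flow simulator logs every planted event exactly once", {
  spec <- sim_protocol(
    duration_s = 300, sigh_times = c(50, 120, 200), sigh_gain = 2.5,
    apnoea_specs = list(list(onset_s = 80, duration_ttot = 2.5, post_sigh = FALSE),
                        list(onset_s = 250, duration_ttot = 2.5, post_sigh = FALSE)),
    seed = 2)
  log <- simulate_flow_trace(spec)$log
  expect_equal(nrow(log), 5)
  expect_equal(sum(log$kind == "sigh"), 3)
  expect_equal(sum(log$kind == "spontaneous_apnoea"), 2)
  expect_true(!is.unsorted(log$onset_s))
  # a post-sigh apnoea logs both the sigh and the apnoea
  log2 <- simulate_flow_trace(sim_protocol(
    duration_s = 120,
    apnoea_specs = list(list(onset_s = 60, duration_ttot = 3.5, post_sigh = TRUE)),
    seed = 3))$log
  expect_equal(log2$kind, c("sigh", "post_sigh_apnoea"))
})

test_that("overlapping planted events are rejected with the offending pair named", {
  expect_error(
    sim_protocol(duration_s = 300, sigh_times = c(100),
                 apnoea_specs = list(list(onset_s = 100.2, duration_ttot = 3,
                                          post_sigh = FALSE))),
    "overlap")
  expect_error(sim_protocol(duration_s = 60, sigh_times = c(59.9)), "inside")
})

test_that("pressure simulator plants the requested beats and RR structure", {
  sp <- rr_sim_spec(mean_rr_ms = 150, sbp_mmHg = 120, dbp_mmHg = 80,
                    jitter_sd_ms = 0, duration_s = 30)
  tr <- simulate_pressure_trace(sp)
  expect_equal(length(tr$samples), 30 * 1000)
  # no components, no jitter: constant planted RR series
  expect_true(all(abs(tr$planted_rr$rr_ms - 150) < 1e-12))
  bt <- detect_beats(tr)
  expect_equal(mean(bt$SBP), 120, tolerance = 1e-9)
  expect_equal(mean(bt$DBP), 80, tolerance = 1e-9)
  expect_equal(mean(bt$RR), 150, tolerance = 1e-3)
  expect_true(all(bt$MAP > bt$DBP & bt$MAP < bt$SBP))
  # a component at/above the beat-rate Nyquist is rejected
  expect_error(rr_sim_spec(mean_rr_ms = 150, band_components =
                             list(list(freq_hz = 3.4, amplitude_ms = 5))),
               "Nyquist")
  expect_error(rr_sim_spec(sbp_mmHg = 80, dbp_mmHg = 90), "below")
})

test_that("planted sinusoidal RR power is recovered by the spectral estimator", {
  sp <- rr_sim_spec(mean_rr_ms = 150,
                    band_components = list(list(freq_hz = 1.5, amplitude_ms = 5)),
                    jitter_sd_ms = 0, duration_s = 180)
  rr <- simulate_pressure_trace(sp)$planted_rr$rr_ms
  h <- spectral_hrv(rr)
  expect_equal(h$HF_ms2, 5^2 / 2, tolerance = 0.15)
  expect_gt(h$HF_nu, 95)
})

test_that("gas trace algebra inverts exactly and guards impossible fractions", {
  g <- simulate_gas_traces(9, 6, 3000, inlet_o2 = 0.2093, inlet_co2 = 0)
  expect_equal(g$o2_out[1], 0.2063, tolerance = 1e-12)
  expect_equal(g$co2_out[1], 0.002, tolerance = 1e-12)
  g0 <- simulate_gas_traces(0, 0.5, 3000)
  expect_equal(g0$o2_out[1], g0$o2_in[1])
  expect_error(simulate_gas_traces(1000, 6, 3000), "outlet fraction")
})

test_that("count simulator is overdispersed-compositional with planted effects", {
  # dispersion -> 0 with equal proportions: near-identical compositions
  spec <- count_sim_spec(n_taxa = 20, n_samples_per_group = 4,
                         base_proportions = rep(1 / 20, 20),
                         dispersion = 1e-6, seed = 4)
  sim <- simulate_count_table(spec)
  rel <- sweep(unclass(sim$counts), 2, colSums(sim$counts), "/")
  expect_lt(max(apply(rel, 1, sd)), 0.01)

  # planted 4-fold change recovered with the correct sign at large n
  spec2 <- count_sim_spec(n_taxa = 30, n_samples_per_group = 40,
                          dispersion = 0.005,
                          planted_effects = list(list(taxon = 5,
                            factor = "exposure", level = "CIH", log2fc = 2)),
                          seed = 5)
  sim2 <- simulate_count_table(spec2)
  sd2 <- attr(sim2$counts, "sample_data")
  clr <- clr_transform(filter_features(sim2$counts)$counts)
  d <- mean(clr["taxon_005", sd2$exposure == "CIH"]) -
    mean(clr["taxon_005", sd2$exposure == "Sham"])
  expect_gt(d, 0.5 * log(4))
  expect_equal(sim2$truth$feature_id, "taxon_005")

  expect_error(count_sim_spec(n_taxa = 10, planted_effects =
                                list(list(taxon = 11, factor = "diet",
                                          level = "PREB", log2fc = 1))),
               "out of range")
})

test_that("study simulator bundles a reproducible 2x2 dataset", {
  des <- study_design(n_per_group = 2, flow_duration_s = 30,
                      pressure_duration_s = 30, seed = 11)
  st1 <- simulate_study(des)
  st2 <- simulate_study(des)
  expect_identical(st1$subjects, st2$subjects)
  expect_identical(st1$flow[[1]]$trace$samples, st2$flow[[1]]$trace$samples)
  expect_equal(nrow(st1$subjects), 8)
  expect_equal(as.vector(table(st1$subjects$exposure)), c(4L, 4L))
  # masses drawn around the configured group means
  m <- tapply(st1$subjects$body_mass_g,
              paste(st1$subjects$exposure, st1$subjects$diet, sep = "."),
              mean)
  expect_true(all(abs(m - des$body_mass_means[names(m)]) < 60))
  expect_error(study_design(n_per_group = 1), ">= 2")
})
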