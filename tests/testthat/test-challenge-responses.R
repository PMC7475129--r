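test_that("metabolism round-trips through the gas algebra", {
  g <- simulate_gas_traces(9, 5.7, 3000)
  m <- compute_metabolism(g, body_mass_g = 300, V_I = 53)
  expect_equal(m$VO2, 9 / 300 * 100, tolerance = 1e-9)
  expect_equal(m$VCO2, 5.7 / 300 * 100, tolerance = 1e-9)
  # printed-scale ventilatory equivalent: V_I 53, VCO2 1.9 -> 27.89
  expect_equal(m$VE_eq, 53 / 1.9, tolerance = 1e-9)
  expect_equal(53 / 1.9, 27.8947, tolerance = 1e-4)
  # flow 3000, delta O2 0.003, 300 g -> 3.0 ml/min/100 g
  g2 <- simulate_gas_traces(3000 * 0.003, 1, 3000)
  expect_equal(compute_metabolism(g2, body_mass_g = 300)$VO2, 3.0)
  # outlet = inlet -> zero uptake
  g0 <- simulate_gas_traces(0, 0.5, 3000)
  expect_equal(compute_metabolism(g0, body_mass_g = 300)$VO2, 0)
})

test_that("baseline pooling is the unweighted mean of epoch means", {
  ep <- data.frame(label = c("baseline_1", "baseline_2", "baseline_3"),
                   start_s = c(0, 100, 200), end_s = c(100, 200, 500))
  ser <- data.frame(time_s = c(50, 150, 250, 300, 400),
                    value = c(50, 52, 54, 54, 54))
  # third epoch is 3x as long but still contributes one epoch mean
  expect_equal(baseline_from_epochs(ser, ep), 52)
  pooled <- mean(ser$value)
  expect_false(isTRUE(all.equal(52, pooled)))
  one <- ep[2, , drop = FALSE]
  expect_equal(baseline_from_epochs(ser, one), 52)
  expect_error(baseline_from_epochs(ser, ep[0, ]), "no baseline")
})

test_that("challenge windowing follows the pleth and anaesthetised rules", {
  t <- seq(0, 2400, 0.5)
  val <- ifelse(t < 1800, 53, 99)
  ser <- data.frame(time_s = t, value = val)
  ep <- data.frame(label = c("baseline_1", "baseline_2", "baseline_3", "hypoxia"),
                   start_s = c(0, 600, 1200, 1800),
                   end_s = c(600, 1200, 1800, 2400))
  cr <- challenge_response(ser, ep, "hypoxia", mode = "pleth", metric = "V_I")
  expect_equal(cr$delta, 46)
  expect_equal(cr$baseline_value, 53)
  # delta / pct consistency
  expect_equal(cr$pct_change * cr$baseline_value / 100, cr$delta,
               tolerance = 1e-12)
  # response equal to baseline: zero change
  flat <- data.frame(time_s = t, value = 53)
  cr0 <- challenge_response(flat, ep, "hypoxia", mode = "pleth")
  expect_equal(cr0$delta, 0)
  expect_equal(cr0$pct_change, 0)
  # anaesthetised mode: last 1 min vs 1 min pre-challenge
  cr2 <- challenge_response(ser, ep, "hypoxia", mode = "anaesth")
  expect_equal(cr2$baseline_value, 53)
  expect_equal(cr2$response_value, 99)
  expect_equal(cr2$pct_change, 100 * 46 / 53)
  # zero baseline flags the percent as undefined
  zb <- data.frame(time_s = t, value = ifelse(t < 1800, 0, 10))
  cr3 <- challenge_response(zb, ep, "hypoxia", mode = "pleth")
  expect_true(cr3$pct_undefined)
  expect_equal(cr3$delta, 10)
  short <- data.frame(label = "hypoxia", start_s = 0, end_s = 100)
  expect_error(challenge_response(ser, short, "hypoxia", mode = "pleth"),
               "shorter")
})

test_that("windowing has no hidden snapping: shifting the epoch shifts the window", {
  t <- seq(0, 2400, 0.5)
  ser <- data.frame(time_s = t, value = sin(t / 40) * 10 + 50)
  base <- data.frame(label = "baseline_1", start_s = 0, end_s = 300)
  for (shift in c(0, 7.5, 13)) {
    ep <- rbind(base, data.frame(label = "hypoxia", start_s = 600 + shift,
                                 end_s = 1500 + shift))
    cr <- challenge_response(ser, ep, "hypoxia", mode = "pleth")
    w <- t >= 1200 + shift & t < 1500 + shift
    expect_equal(cr$response_value, mean(ser$value[w]), tolerance = 1e-12)
  }
})

test_that("drug peak search recovers planted transients with sign", {
  t <- seq(0, 300, 0.1)
  # depressor transient: -30% for 10 s starting 10 s post-injection
  v <- rep(100, length(t))
  v[t >= 130 & t < 140] <- 70
  dr <- drug_response(data.frame(time_s = t, value = v), 120, bin_s = 3)
  expect_equal(dr$pct_change, -30, tolerance = 1)
  # pressor transient comes out positive
  v2 <- rep(100, length(t))
  v2[t >= 130 & t < 140] <- 124
  dr2 <- drug_response(data.frame(time_s = t, value = v2), 120, bin_s = 3)
  expect_equal(dr2$pct_change, 24, tolerance = 1)
  # flat series: zero percent change
  dr0 <- drug_response(data.frame(time_s = t, value = rep(80, length(t))), 120)
  expect_equal(dr0$pct_change, 0)
  expect_error(drug_response(data.frame(time_s = t, value = v), 290),
               "search window")
  expect_error(drug_response(data.frame(time_s = t, value = v), 30), "baseline")
})

test_that("PBG apnoea and tachypnoea are reported in baseline cycle units", {
  # baseline T_tot 600 ms; apnoea of 3.0 s = 5.0 cycles
  n <- 300
  bt <- structure(data.frame(onset_s = cumsum(rep(0.6, n)) - 0.6,
                             T_i = 200, T_e = 400, T_tot = 600,
                             V_T = 2, V_T_over_Ti = 10, inst_f_R = 100,
                             artifact_flag = FALSE),
                  class = c("breath_table", "data.frame"))
  inj <- bt$onset_s[100]
  bt$T_tot[120] <- 3000
  expect_equal(pbg_apnoea_tachypnoea(bt, inj)$apnoea_cycles, 5.0)
  # no apnoea: flagged zeros
  bt0 <- bt
  bt0$T_tot[120] <- 600
  r0 <- pbg_apnoea_tachypnoea(bt0, inj)
  expect_false(r0$found_apnoea)
  expect_equal(r0$apnoea_cycles, 0)
  # planted apnoea 4 cycles followed by 10 fast breaths at 0.7x cycle
  bt2 <- bt
  base_sd <- 20
  set.seed(1)
  bt2$T_tot <- bt2$T_tot + round(rnorm(n, 0, base_sd))
  bt2$T_tot[120] <- 4 * 600
  bt2$T_tot[121:130] <- 0.7 * 600
  r2 <- pbg_apnoea_tachypnoea(bt2, inj)
  expect_equal(r2$apnoea_cycles, 4, tolerance = 0.1)
  expect_equal(r2$tachypnoea_cycles, 10 * 0.7, tolerance = 0.1 * 7)
})

test_that("tissue and chromatography utilities compute their ratios", {
  expect_equal(oedema_index(1000, 220), 78)
  expect_equal(oedema_index(500, 125), 75)
  expect_equal(oedema_index(100, 100), 0)
  expect_error(oedema_index(100, 120), "exceeds")
  expect_equal(ratio_quantify(2, 1, 2), 4)
  expect_equal(ratio_quantify(0, 1, 2), 0)
  expect_equal(ratio_quantify(3, 1, 2, calibration = 0.5), 3)
  expect_error(ratio_quantify(1, 0, 2), "> 0")
})
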