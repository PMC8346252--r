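# Generators: design crossing, determinism, and self-consistency of the
# synthesized signals with the downstream feature extractors.

test_that("study design is fully crossed with the right cell counts", {
  d6 <- gen_study_design(6)
  expect_equal(nrow(d6), 72)
  d1 <- gen_study_design(1)
  expect_equal(nrow(d1), 12)
  d3 <- gen_study_design(3)
  expect_equal(nrow(d3), 36)  # 2 genotypes x 2 sexes x 3 ages x 3 replicates
  tab <- table(d6$genotype, d6$sex, d6$age_months)
  expect_true(all(tab == 6))
  expect_false(anyDuplicated(d6$subject_id) > 0)
  expect_error(gen_study_design(0), "n_per_cell")
})

test_that("generators are deterministic in seed and spec", {
  expect_identical(gen_arm_entries(0.5, 50, seed = 9),
                   gen_arm_entries(0.5, 50, seed = 9))
  expect_false(identical(gen_arm_entries(0.5, 50, seed = 9),
                         gen_arm_entries(0.5, 50, seed = 10)))
  s <- eeg_sim_spec(duration_s = 60, seed = 4)
  expect_identical(gen_eeg(s), gen_eeg(s))
  atlas <- grid_atlas(c(40, 40))
  dens <- stats::setNames(rep(0.02, 4), 1:4)
  expect_identical(gen_sections(atlas$labels, dens, n_sections = 2, seed = 3),
                   gen_sections(atlas$labels, dens, n_sections = 2, seed = 3))
  d <- gen_study_design(2)
  expect_identical(gen_expression(d, 20, seed = 8),
                   gen_expression(d, 20, seed = 8))
  expect_identical(gen_frailty(10, seed = 2), gen_frailty(10, seed = 2))
  expect_identical(gen_pet(seed = 2), gen_pet(seed = 2))
})

test_that("synthesized EEG epochs hit the target band ratios", {
  spec <- eeg_sim_spec(duration_s = 300, seed = 21)
  sim <- gen_eeg(spec)
  feats <- epoch_band_powers(sim$recording)
  tgt_d <- spec$stage_delta[sim$hypnogram$stage]
  tgt_t <- spec$stage_theta[sim$hypnogram$stage]
  ok <- abs(feats$delta_ratio - tgt_d) <= 0.05 &
    abs(feats$theta_ratio - tgt_t) <= 0.05
  expect_gte(mean(ok), 0.95)
})

test_that("EEG generator honors trivial stage and event structure", {
  sim <- gen_eeg(eeg_sim_spec(duration_s = 100,
                              stage_dwell_means = c(WAKE = 1e5), seed = 2))
  expect_true(all(sim$hypnogram$stage == "WAKE"))
  expect_equal(nrow(sim$swd_events), 0)
  expect_equal(nrow(sim$hypnogram), 10)
  # activity is zero in sleep epochs, EMG tone separates wake from sleep
  sim2 <- gen_eeg(eeg_sim_spec(duration_s = 400, seed = 6))
  feats <- epoch_band_powers(sim2$recording)
  sleep <- sim2$hypnogram$stage != "WAKE"
  expect_true(all(feats$activity_sum[sleep] == 0))
  expect_true(all(feats$emg_rms[sleep] < 40))
  # overlapping SWD events rejected
  ev <- data.frame(start_s = c(10, 10.5), n_spikes = 6,
                   inter_spike_s = 0.2, amplitude_multiplier = 8)
  expect_error(eeg_sim_spec(duration_s = 60, swd_events = ev), "overlap")
})

test_that("section generator truth equals the rendered masks", {
  atlas <- grid_atlas(c(60, 60))
  dens <- stats::setNames(c(0.03, 0.01, 0, 0.05), 1:4)
  sim <- gen_sections(atlas$labels, dens, n_sections = 3, seed = 7)
  # recompute fractional area from the masks with direct arithmetic
  for (r in 1:4) {
    sel <- atlas$labels == r
    mp <- sum(vapply(sim$masks, function(m) sum(m[sel]), numeric(1)))
    row <- sim$truth[sim$truth$region_id == r, ]
    expect_identical(row$masked_pixels, mp)
    expect_equal(row$fractional_area, mp / (sum(sel) * 3))
  }
  expect_equal(sim$truth$fractional_area[sim$truth$region_id == 3], 0)
  # densities above the admissible range and unknown regions are rejected
  expect_error(gen_sections(atlas$labels, stats::setNames(0.5, 1)), "0.2")
  expect_error(gen_sections(atlas$labels, stats::setNames(0.01, 99)), "absent")
})

test_that("arm-entry generator respects its bias and never re-enters", {
  e1 <- gen_arm_entries(1, 30, seed = 1)
  expect_equal(percent_alternation(e1)$percent, 100)
  e0 <- gen_arm_entries(0, 30, seed = 1)
  expect_equal(percent_alternation(e0)$percent, 0)
  for (s in 1:5) {
    e <- gen_arm_entries(0.5, 100, seed = s)
    expect_true(all(e[-1] != e[-length(e)]))
  }
  expect_error(gen_arm_entries(0.5, 2), "at least 3")
})

test_that("expression generator recovers its coefficients in the noiseless limit", {
  d <- gen_study_design(6)
  eff <- data.frame(gene = 1, beta1 = 0, beta2 = 0, beta12 = 1)
  sim <- gen_expression(d, 3, effects = eff, sigma = 1e-9, seed = 3)
  sel <- d$age_months == 4
  res <- fit_glm_per_gene(sim$log_expr[, sel, drop = FALSE], d[sel, ])
  expect_equal(res$beta12[1], 1, tolerance = 1e-6)
  expect_equal(res$beta12[2], 0, tolerance = 1e-6)
  expect_error(gen_expression(d, 0), "n_genes")
  # single-gene genotype effect recovered within OLS sampling error
  eff2 <- data.frame(gene = 1, beta1 = 0, beta2 = 2, beta12 = 0)
  sim2 <- gen_expression(d, 1, effects = eff2, sigma = 0.5, seed = 12)
  res2 <- fit_glm_per_gene(sim2$log_expr, d)
  expect_lt(abs(res2$beta2[1] - 2), 0.25)
})

test_that("PET generator includes a stable cerebellum reference", {
  sim <- gen_pet(seed = 9)
  expect_true("cerebellum" %in% sim$uptake$region)
  tr <- sim$truth[sim$truth$region == "cerebellum", ]
  expect_equal(tr$genotype_shift, 0)
  expect_equal(tr$age_slope, 0)
  lat <- gen_pet(lateralized = TRUE, seed = 9)
  expect_true(any(grepl("_left$", lat$uptake$region)))
})

test_that("frailty, wheel, open-field and rotarod generators keep their contracts", {
  fr <- gen_frailty(20, prevalence = 0.3, seed = 5)
  expect_equal(length(FRAILTY_TRAITS), 26)
  expect_true(all(FRAILTY_TRAITS %in% names(fr)))
  expect_true(all(unlist(fr[, FRAILTY_TRAITS]) %in% c(0, 0.5, 1)))
  wh <- gen_wheel(hours = 72, seed = 2)
  expect_equal(nrow(wh), 72 * 60)
  expect_true(all(wh$distance_m >= 0))
  of <- gen_openfield(seed = 2)
  expect_equal(nrow(of), 3600)
  rr <- gen_rotarod(5, seed = 2)
  expect_equal(nrow(rr), 15)
  expect_true(all(rr$latency_s <= 300))
})
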