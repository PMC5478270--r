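test_that("MEG block schedules honour the design structure", {
  for (seed in 1:5) {
    s <- build_block_schedule("meg", seed = seed)
    expect_identical(nrow(s$blocks), 4L)
    expect_identical(s$blocks$condition, c("safe", "threat", "safe",
                                           "threat"))
    expect_identical(sum(s$habituation), 4L)
    expect_identical(sum(!s$habituation), 32L)   # 8 probes x 4 blocks
    # inter-probe intervals within [6, 14] s (the first probe of each
    # segment also follows an interval from the previous probe)
    expect_true(all(diff(s$probe_times) >= 6 - 1e-9))
    expect_true(all(diff(s$probe_times) <= 14 + 1e-9))
    expect_lte(length(s$shock_times), 2L)
    # shocks only inside threat blocks
    for (st in s$shock_times) {
      b <- which(s$blocks$onset <= st & st <= s$blocks$offset)
      expect_true(length(b) == 1 && s$blocks$condition[b] == "threat")
    }
  }
})

test_that("fMRI schedules produce 245 TR labels and optional shocks", {
  s <- build_block_schedule("fmri", run_length_s = 490, tr_s = 2,
                            seed = 2)
  expect_identical(length(s$condition_per_frame), 245L)
  expect_identical(length(s$probe_times), 0L)
  tab <- table(s$condition_per_frame)
  expect_identical(as.integer(tab[c("safe", "threat")]), c(120L, 120L))
  expect_identical(as.integer(tab["pre"]), 5L)
  # degenerate shock probability
  s0 <- build_block_schedule("fmri", shock_prob = 0, seed = 3)
  expect_identical(length(s0$shock_times), 0L)
  expect_lte(length(build_block_schedule("fmri", shock_prob = 1,
                                         seed = 3)$shock_times), 3L)
  expect_error(build_block_schedule("fmri", run_length_s = 100),
               "too short")
})

test_that("schedule and cohort generation are seed-deterministic", {
  expect_identical(build_block_schedule("meg", seed = 9),
                   build_block_schedule("meg", seed = 9))
  c1 <- make_fmri_cohort(tiny_fmri_cfg(seed = 4))
  c2 <- make_fmri_cohort(tiny_fmri_cfg(seed = 4))
  expect_identical(c1$subjects[[2]]$data, c2$subjects[[2]]$data)
  expect_identical(c1$subjects[[1]]$motion, c2$subjects[[1]]$motion)
  m1 <- make_meg_cohort(tiny_meg_cfg(seed = 4))
  m2 <- make_meg_cohort(tiny_meg_cfg(seed = 4))
  expect_identical(m1$subjects[[1]]$epochs, m2$subjects[[1]]$epochs)
  expect_identical(m1$ground_truth$iaf_hz, m2$ground_truth$iaf_hz)
})

test_that("fMRI generator rejects unattainable delta_rho", {
  expect_error(fmri_sim_config(delta_rho = 0.4, rho0 = 0.25),
               "not attainable")
  expect_error(fmri_sim_config(delta_rho = -0.1), "delta_rho")
})

test_that("fMRI generator injects the stated connectivity increment", {
  # null effect: hub-nonhub GBC difference ~ 0
  coh0 <- make_fmri_cohort(tiny_fmri_cfg(seed = 5, delta_rho = 0,
                                         n_subjects = 4L))
  dz0 <- sapply(coh0$subjects, function(ts) {
    d <- gbc_map(ts$data, ts$labels, "threat") -
      gbc_map(ts$data, ts$labels, "safe")
    mean(d[coh0$ground_truth$hub_voxels]) -
      mean(d[-coh0$ground_truth$hub_voxels])
  })
  expect_lt(abs(mean(dz0)), 0.05)
  # injected effect recovers the atanh-scale target within 25%
  cfg <- fmri_sim_config(n_subjects = 6L, delta_rho = 0.15, seed = 6)
  coh <- make_fmri_cohort(cfg)
  hub <- coh$ground_truth$hub_voxels
  dz <- rowMeans(sapply(coh$subjects, function(ts) {
    gbc_map(ts$data, ts$labels, "threat")[hub] -
      gbc_map(ts$data, ts$labels, "safe")[hub]
  }))
  ratio <- mean(dz) / coh$ground_truth$target_hub_dz
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})

test_that("MEG generator: power ratio, artifacts, geometry", {
  # alpha_mod = 1 -> threat ~ safe sensor power (low-noise config)
  cfg1 <- tiny_meg_cfg(seed = 7, alpha_mod = 1, sensor_noise_sd = 0.1,
                       n_background = 0L, artifact_rate = 0)
  coh1 <- make_meg_cohort(cfg1)
  ep <- coh1$subjects[[1]]
  bp <- iaf_band_power(ep, coh1$ground_truth$iaf_hz[1])
  ratio1 <- mean(bp[ep$condition == "threat", ]) /
    mean(bp[ep$condition == "safe", ])
  expect_gt(ratio1, 0.8); expect_lt(ratio1, 1.25)
  # alpha_mod = 0.8 -> power ratio ~ 0.64 (amplitude squared)
  cfg2 <- tiny_meg_cfg(seed = 7, alpha_mod = 0.8, sensor_noise_sd = 0.1,
                       n_background = 0L, artifact_rate = 0,
                       trials_per_condition = 40L)
  coh2 <- make_meg_cohort(cfg2)
  ep2 <- coh2$subjects[[1]]
  bp2 <- iaf_band_power(ep2, coh2$ground_truth$iaf_hz[1])
  ratio2 <- mean(bp2[ep2$condition == "threat", ]) /
    mean(bp2[ep2$condition == "safe", ])
  expect_gt(ratio2, 0.52); expect_lt(ratio2, 0.78)
  # artifact flags ~ binomial expectation
  cfg3 <- tiny_meg_cfg(seed = 8, artifact_rate = 0.1,
                       trials_per_condition = 32L)
  coh3 <- make_meg_cohort(cfg3)
  expect_equal(mean(sapply(coh3$ground_truth$artifact_trials, sum)),
               6.4, tolerance = 4)
  # sensors outside the conductor
  expect_error(meg_sim_config(sensor_radius_m = 0.08,
                              conductor_radius_m = 0.09), "outside")
})

test_that("EMG session: scaling, nulls, rating range", {
  sched <- tiny_schedule(seed = 11)
  # null config: zero injected APS and rating effect
  ses0 <- make_emg_session(emg_sim_config(threat_multiplier = 1,
                                          rating_effect = 0, seed = 2),
                           sched)
  gt0 <- ses0$ground_truth
  expect_equal(gt0$subject_multiplier, 1)
  expect_equal(gt0$subject_rating_effect, 0)
  # threat_multiplier = 2 doubles threat blink amplitudes pre-scoring
  ses2 <- make_emg_session(emg_sim_config(threat_multiplier = 2,
                                          subject_sd = 0, seed = 3),
                           sched)
  gt2 <- ses2$ground_truth
  keep <- !ses2$trace$habituation
  thr <- gt2$amplitude[keep][ses2$trace$condition[keep] == "threat"]
  saf <- gt2$amplitude[keep][ses2$trace$condition[keep] == "safe"]
  # amplitudes carry lognormal jitter; the injected multiplier is exact
  expect_equal(gt2$subject_multiplier, 2)
  expect_gt(median(thr) / median(saf), 1.3)
  expect_true(all(ses2$ratings$rating >= 0 & ses2$ratings$rating <= 255))
  expect_error(make_emg_session(emg_sim_config(
    blink_latency_ms = c(10, 60))), "scoring window")
  fmri_sched <- build_block_schedule("fmri", seed = 1)
  expect_error(make_emg_session(emg_sim_config(), fmri_sched), "probes")
})
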