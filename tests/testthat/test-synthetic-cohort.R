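# Virtual-patient generator: waveforms, geometry, noise, cohorts, I/O.

test_that("generated waveforms carry the requested mean and positivity", {
  # zero phasicity forces a constant waveform at the converted mean
  wf <- generate_waveform(1.0, 3.2, phasicity = 0, n_samples = 64, seed = 7)
  expect_equal(wf$flows, rep(lmin_to_mm3s(1), 64), tolerance = 1e-12)
  # phasic waveform: independently integrated mean equals the request
  wf2 <- generate_waveform(0.73, 3.2, phasicity = 0.3, n_samples = 64,
                           seed = 1)
  expect_equal(trapz_mean(wf2$times, wf2$flows, wf2$period),
               lmin_to_mm3s(0.73), tolerance = 1e-9)
  expect_equal(waveform_mean_flow(wf2), lmin_to_mm3s(0.73),
               tolerance = 1e-9)
  # near-unit phasicity stays non-negative and above the stated floor
  wf3 <- generate_waveform(1.0, 3.0, phasicity = 0.999, n_samples = 64,
                           seed = 2)
  expect_true(all(wf3$flows >= 0))
  expect_true(min(wf3$flows) >= lmin_to_mm3s(1) * (1 - 0.999) - 1e-9)
  expect_error(generate_waveform(-1, 3.2), "mean_flow")
  expect_error(generate_waveform(1, 0), "period")
  expect_error(generate_waveform(1, 3.2, phasicity = 1), "phasicity")
  expect_error(generate_waveform(1, 3.2, n_samples = 4), "n_samples")
})

test_that("geometry builder shapes the stenosis and only the stenosis", {
  areas <- c(IVC = 280, RCIV = 196.3, LCIV = 130, REIV = 110, LEIV = 110,
             RIIV = 60, LIIV = 60)
  lens <- c(IVC = 100, RCIV = 60, LCIV = 60, REIV = 80, LEIV = 80,
            RIIV = 60, LIIV = 60)
  # severity 0: every segment constant
  g0 <- generate_geometry(areas, lens, stenosis_spec(0, 30, 30))
  for (s in g0) expect_true(all(s$area_profile == s$area_profile[1]))
  # severity 0.5 on 130 mm^2: throat exactly 65 mm^2 (center on-grid)
  g1 <- generate_geometry(areas, lens, stenosis_spec(0.5, 30, 30))
  expect_equal(min(g1$LCIV$area_profile), 65, tolerance = 1e-9)
  expect_true(all(g1$RCIV$area_profile == 196.3))
  # severity 0.44 lands near the subject-scale compressed lumen
  g2 <- generate_geometry(areas, lens, stenosis_spec(0.44, 30, 30))
  expect_equal(min(g2$LCIV$area_profile), 72.8, tolerance = 1e-6)
  # profile is continuous (no jumps above one station's bump slope)
  expect_lt(max(abs(diff(g1$LCIV$area_profile))), 10)
  expect_error(generate_geometry(areas, lens, stenosis_spec(0.5, 5, 30)),
               "beyond the LCIV")
})

test_that("throat area decreases strictly with severity", {
  areas <- c(IVC = 280, RCIV = 196.3, LCIV = 130, REIV = 110, LEIV = 110,
             RIIV = 60, LIIV = 60)
  lens <- c(IVC = 100, RCIV = 60, LCIV = 60, REIV = 80, LEIV = 80,
            RIIV = 60, LIIV = 60)
  throats <- vapply(seq(0, 0.9, by = 0.1), function(s) {
    min(generate_geometry(areas, lens,
                          stenosis_spec(s, 30, 30))$LCIV$area_profile)
  }, numeric(1))
  expect_true(all(diff(throats) < 0))
})

test_that("patient generation is deterministic and honest about noise", {
  cfg <- subject_template()
  p1 <- make_virtual_patient(cfg, 11)
  p2 <- make_virtual_patient(cfg, 11)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
  # with noise disabled, the ultrasound velocity is exactly Qbar / A
  cfg0 <- subject_template(noise_cv = 0)
  p0 <- make_virtual_patient(cfg0, 5)
  q_left <- waveform_mean_flow(p0$inflows$LEIV) +
    waveform_mean_flow(p0$inflows$LIIV)
  rec <- p0$us_records$LCIV
  a_slice <- approx(p0$segments$LCIV$arclength_grid,
                    p0$segments$LCIV$area_profile, rec$slice_position)$y
  expect_equal(rec$mean_velocity, q_left / a_slice, tolerance = 1e-12)
  expect_equal(rec$mean_area, a_slice, tolerance = 1e-12)
  # forced compression: the minimum LCIV area is below 90% of baseline
  p11 <- make_virtual_patient(subject_template(), 11)
  expect_lt(min(p11$segments$LCIV$area_profile), 0.9 * 131.8)
})

test_that("ground-truth inlet flows are mass-consistent with the IVC", {
  for (seed in c(1, 9, 33)) {
    p <- make_virtual_patient(control_template(), seed)
    routed <- route_flows(p$inflows)
    inlet_sum <- sum(vapply(p$inflows, waveform_mean_flow, numeric(1)))
    expect_equal(waveform_mean_flow(routed$IVC), inlet_sum,
                 tolerance = 1e-9)
  }
})

test_that("cohorts respect templates and are reproducible", {
  ctrl <- make_cohort(control_template(), 4, 77)
  expect_length(ctrl, 4)
  expect_true(all(vapply(ctrl, function(p) p$severity, numeric(1)) == 0))
  subj <- make_cohort(subject_template(), 4, 77)
  sev <- vapply(subj, function(p) p$severity, numeric(1))
  expect_true(all(sev >= 0.4 & sev <= 0.8))
  per <- vapply(subj, function(p) p$period, numeric(1))
  expect_true(all(per >= 3.0 & per <= 3.75))
  subj2 <- make_cohort(subject_template(), 4, 77)
  expect_identical(serialize(subj, NULL), serialize(subj2, NULL))
  expect_error(make_cohort(control_template(), 0, 1), "n must be >= 1")
})

test_that("measurement noise has the advertised moments and floor", {
  expect_identical(apply_measurement_noise(123.4, 0), 123.4)
  draws <- apply_measurement_noise(rep(100, 10000), 0.05, seed = 42)
  expect_equal(mean(draws), 100, tolerance = 0.01)
  expect_equal(sd(draws) / 100, 0.05, tolerance = 0.05)
  # extreme noise cannot produce non-positive values
  wild <- apply_measurement_noise(rep(100, 5000), 5, seed = 1)
  expect_true(all(wild > 0))
  expect_true(min(wild) >= 100 * 0.05 - 1e-12)
})

test_that("patient bundles round-trip through CSV + JSON", {
  p <- make_virtual_patient(subject_template(), 21)
  dir <- tempfile("bundle")
  on.exit(unlink(dir, recursive = TRUE))
  write_patient_bundle(p, dir)
  q <- read_patient_bundle(dir)
  expect_identical(q$group, p$group)
  expect_equal(q$severity, p$severity, tolerance = 1e-12)
  for (nm in names(p$segments)) {
    expect_equal(q$segments[[nm]]$area_profile,
                 p$segments[[nm]]$area_profile, tolerance = 1e-9)
  }
  for (nm in names(p$inflows)) {
    expect_equal(q$inflows[[nm]]$flows, p$inflows[[nm]]$flows,
                 tolerance = 1e-9)
    expect_equal(q$inflows[[nm]]$period, p$inflows[[nm]]$period,
                 tolerance = 1e-12)
  }
  expect_equal(q$us_records$LCIV$mean_velocity,
               p$us_records$LCIV$mean_velocity, tolerance = 1e-9)
})

test_that("configuration rules are enforced", {
  expect_error(patient_config(group = "Control",
                              severity_range = c(0.2, 0.4)),
               "Controls must have severity 0")
  expect_error(subject_template(severity_range = c(0, 0)),
               "severity > 0")
  expect_error(stenosis_spec(0.99, 30, 30), "severity")
})
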