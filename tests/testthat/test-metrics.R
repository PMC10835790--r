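# Control-volume rules and shear-rate summary metrics.

test_that("stenotic extent follows the 90% rule on a printed-style profile", {
  # constant-area vessel: no extent
  flat <- vessel_segment("LCIV", 0:60, rep(120, 61))
  expect_null(detect_stenosis_extent(flat))
  # the canonical 7-station example: refs 100/100, extent = (80, 60, 80)
  seg <- vessel_segment("LCIV", 0:6, c(100, 100, 80, 60, 80, 100, 100))
  cv <- detect_stenosis_extent(seg, threshold = 0.9, flank_window = 5)
  inside <- seg$arclength_grid[seg$arclength_grid >= cv$z_start &
                                 seg$arclength_grid <= cv$z_end]
  expect_identical(inside, c(2, 3, 4))
  expect_equal(cv$start_distance, cv$z_start)
})

test_that("detected cosine-bump extent matches the analytic crossings", {
  areas <- c(IVC = 280, RCIV = 196.3, LCIV = 131.8, REIV = 110,
             LEIV = 110, RIIV = 60, LIIV = 60)
  lens <- c(IVC = 100, RCIV = 60, LCIV = 60, REIV = 80, LEIV = 80,
            RIIV = 60, LIIV = 60)
  for (s in c(0.5, 0.7)) {
    g <- generate_geometry(areas, lens, stenosis_spec(s, 30, 30))
    cv <- detect_stenosis_extent(g$LCIV)
    # analytic solution of A(z) = 0.9 A0 on the cosine bump
    theta <- acos(2 * 0.1 / s - 1)
    z_lo <- 30 - 30 * theta / (2 * pi)
    z_hi <- 30 + 30 * theta / (2 * pi)
    expect_lt(abs(cv$z_start - z_lo), 1)
    expect_lt(abs(cv$z_end - z_hi), 1)
    # enclosed volume agrees with fine-grid integration of the bump
    zf <- seq(cv$z_start, cv$z_end, length.out = 2001)
    af <- approx(g$LCIV$arclength_grid, g$LCIV$area_profile, zf)$y
    expect_equal(cv$volume, pracma::trapz(zf, af), tolerance = 1e-3)
  }
})

test_that("disjoint sub-threshold runs raise an ambiguity error", {
  a <- rep(100, 61)
  a[11:15] <- 70
  a[41:45] <- 75
  seg <- vessel_segment("LCIV", 0:60, a)
  expect_error(detect_stenosis_extent(seg), "ambiguity error")
})

test_that("contralateral control volumes are volume- and start-matched", {
  lciv <- vessel_segment("LCIV", 0:60, rep(100, 61))
  rciv_same <- vessel_segment("RCIV", 0:60, rep(100, 61))
  cv_l <- iliacshear:::.cv_from_bounds(lciv, 10, 30)
  cv_r <- matched_contralateral_cv(cv_l, rciv_same)
  expect_equal(cv_r$z_start, 10, tolerance = 1e-9)
  expect_equal(cv_r$z_end, 30, tolerance = 1e-6)
  # doubled area: half the axial length
  rciv_wide <- vessel_segment("RCIV", 0:60, rep(200, 61))
  cv_w <- matched_contralateral_cv(cv_l, rciv_wide)
  expect_equal(cv_w$z_end - cv_w$z_start, 10, tolerance = 1e-6)
  expect_equal(cv_w$volume, cv_l$volume, tolerance = 1e-3)
  # tapered vessel A(z) = 150 - z: the cumulative volume from z = 10 is
  # quadratic, int_{10}^{z}(150 - s) ds = 2000  =>  z^2 - 300 z + 6900 = 0
  rciv_tap <- vessel_segment("RCIV", 0:60, 150 - (0:60))
  cv_t <- matched_contralateral_cv(cv_l, rciv_tap)
  z_ref <- (300 - sqrt(300^2 - 4 * 6900)) / 2
  expect_equal(cv_t$z_end, z_ref, tolerance = 1e-3)
  # vessel too short for the requested volume
  short <- vessel_segment("RCIV", 0:12, rep(100, 13))
  expect_error(matched_contralateral_cv(cv_l, short), "too short")
})

test_that("control-group volumes average the subject placements", {
  vessel <- vessel_segment("RCIV", 0:60, rep(100, 61))
  cv1 <- control_volume("LCIV", 10, 11, 100, 10)
  cv2 <- control_volume("LCIV", 20, 23, 300, 20)
  # single subject: pass-through
  one <- control_volume_for_control_group(list(cv1), vessel)
  expect_equal(one$start_distance, 10)
  expect_equal(one$volume, 100, tolerance = 1e-6)
  # two subjects: mean start 15, mean volume 200
  two <- control_volume_for_control_group(list(cv1, cv2), vessel)
  expect_equal(two$start_distance, 15)
  expect_equal(two$volume, 200, tolerance = 1e-6)
  expect_equal(two$z_end - two$z_start, 2, tolerance = 1e-6)
})

test_that("metric chain reproduces closed-form Poiseuille statistics", {
  p <- make_virtual_patient(steady_config(), 2)
  opt <- sim_options(n_store = 4L, rheology = newtonian_params(0.0035))
  sol <- simulate_patient(p, opt)
  seg <- p$segments$LCIV
  cv <- iliacshear:::.cv_from_bounds(seg, 10, 50)
  m <- cv_shear_metrics(sol, cv)
  q <- mean(sol$segments$LCIV$q)
  R <- sqrt(130 / pi)
  gw <- 4 * q / (pi * R^3)
  expect_equal(m$mean_shear, 2 / 3 * gw, tolerance = 0.01)
  expect_equal(m$q1_shear, 0.5 * gw, tolerance = 0.01)
  expect_equal(m$q3_shear, sqrt(3) / 2 * gw, tolerance = 0.01)
  # steady flow: the peak of the spatial mean equals its time average
  expect_equal(m$mean_peak_shear, m$mean_shear, tolerance = 1e-9)
  # weights close to the control volume within 0.5%
  expect_lt(abs(m$weight_total / m$cv_volume - 1), 0.005)
  # clinical area column is the vessel average
  expect_equal(m$mean_area, 130, tolerance = 1e-9)
})

test_that("phasic Newtonian flow scales mean-peak by the phasicity", {
  p <- make_virtual_patient(symmetric_config(), 2)  # phasicity 0.3
  opt <- sim_options(n_store = 16L, rheology = newtonian_params(0.0035))
  sol <- simulate_patient(p, opt)
  cv <- iliacshear:::.cv_from_bounds(p$segments$LCIV, 10, 50)
  m <- cv_shear_metrics(sol, cv)
  expect_equal(m$mean_peak_shear / m$mean_shear, 1.3, tolerance = 0.01)
})

test_that("quartiles are ordered and the distribution is coherent", {
  p <- make_virtual_patient(fixed_subject_config(0.55), 8)
  sol <- simulate_patient(p, fast_options())
  cv <- detect_stenosis_extent(p$segments$LCIV)
  m <- cv_shear_metrics(sol, cv)
  expect_lte(m$q1_shear, m$q3_shear)
  expect_gte(m$mean_peak_shear, m$mean_shear)
  expect_true(all(c(m$mean_shear, m$q1_shear, m$q3_shear) >= 0))
  # count weighting is a valid sensitivity variant with the same ordering
  m2 <- cv_shear_metrics(sol, cv, weighting = "count")
  expect_lte(m2$q1_shear, m2$q3_shear)
  expect_error(cv_shear_metrics(sol, control_volume("LCIV", 50, 70, 100, 50)),
               "coverage error")
})

test_that("the shear-rate ratio behaves like the underlying physics", {
  # mirror-symmetric patient: ratio identically 1
  p <- make_virtual_patient(symmetric_config(), 4)
  sol <- simulate_patient(p, fast_options())
  cv_l <- iliacshear:::.cv_from_bounds(p$segments$LCIV, 15, 45)
  cv_r <- matched_contralateral_cv(cv_l, p$segments$RCIV)
  rs <- ratio_series(sol, cv_l, cv_r)
  expect_equal(rs$ratio, rep(1, length(rs$ratio)), tolerance = 1e-9)
  expect_equal(rs$mean_ratio, 1, tolerance = 1e-9)
  # Newtonian linearity: scaling the left-leg flow scales the ratio
  k <- 1.8
  cfgk <- symmetric_config(leg_mean_flows = c(right = 0.8, left = 0.8 * k))
  pk <- make_virtual_patient(cfgk, 4)
  optn <- sim_options(n_store = 8L, dt = 0.02, n_cycles = 2L,
                      rheology = newtonian_params(0.0035))
  soln0 <- simulate_patient(p, optn)
  solnk <- simulate_patient(pk, optn)
  r0 <- ratio_series(soln0, cv_l, cv_r)$mean_ratio
  rk <- ratio_series(solnk, cv_l, cv_r)$mean_ratio
  expect_equal(rk / r0, k, tolerance = 1e-6)
})

test_that("the ratio exceeds 1 and grows with severity", {
  opt <- fast_options()
  ratios <- vapply(c(0.45, 0.75), function(s) {
    p <- make_virtual_patient(fixed_subject_config(s), 8)
    sol <- simulate_patient(p, opt)
    cv <- detect_stenosis_extent(p$segments$LCIV)
    rcv <- matched_contralateral_cv(cv, p$segments$RCIV)
    ratio_series(sol, cv, rcv)$mean_ratio
  }, numeric(1))
  expect_true(all(ratios > 1))
  expect_gt(ratios[2], ratios[1])
})
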