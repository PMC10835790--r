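# Profile solver, flow routing and the RCR Windkessel.

test_that("stress inversion is exact in the Newtonian limit and stable", {
  p <- rheology_params()
  expect_identical(invert_stress(0, p), 0)
  newt <- newtonian_params(0.0035)
  expect_equal(invert_stress(3.5, newt), 1000, tolerance = 1e-9)
  # frozen from a 40-digit root solve of mu(g) g = 1 Pa
  expect_equal(invert_stress(1, p), 258.14800385148, tolerance = 1e-8)
  # round trip through the constitutive law
  for (tau in c(1e-4, 0.02, 1, 40)) {
    expect_equal(shear_stress(invert_stress(tau, p), p), tau,
                 tolerance = 1e-8)
  }
  expect_error(invert_stress(-1, p), "tau")
})

test_that("generalized Poiseuille matches the Newtonian closed form", {
  q <- lmin_to_mm3s(1)
  R <- 5
  newt <- newtonian_params(0.0035)
  pr <- solve_generalized_poiseuille(q, R, newt)
  gw <- 4 * q / (pi * R^3)
  expect_equal(pr$wall_shear_rate, gw, tolerance = 1e-6)
  expect_equal(pr$pressure_gradient, 8 * 0.0035 * q / (pi * R^4),
               tolerance = 1e-6)
  u_exact <- 2 * q / (pi * R^2) * (1 - (pr$radius_grid / R)^2)
  expect_equal(pr$axial_velocity, u_exact, tolerance = 1e-6)
  expect_equal(pr$shear_rate, gw * pr$radius_grid / R, tolerance = 1e-6)
  # discrete mass conservation under the solver's own quadrature
  n <- length(pr$radius_grid)
  wq <- rep(c(2, 4), length.out = n)
  wq[c(1, n)] <- 1
  wq <- wq * (pr$radius_grid[2] - pr$radius_grid[1]) / 3
  expect_equal(2 * pi * sum(wq * pr$radius_grid * pr$axial_velocity), q,
               tolerance = 1e-6)
  # volume-mean shear of Poiseuille flow is 2/3 of the wall value
  expect_equal(profile_mean_shear(pr) / pr$wall_shear_rate, 2 / 3,
               tolerance = 1e-4)
})

test_that("zero flow yields the null profile", {
  pr <- solve_generalized_poiseuille(0, 4, rheology_params())
  expect_identical(pr$pressure_gradient, 0)
  expect_true(all(pr$axial_velocity == 0))
  expect_true(all(pr$shear_rate == 0))
})

test_that("shear-thinning wall shear matches a grid-refinement oracle", {
  p <- rheology_params()
  pr <- solve_generalized_poiseuille(lmin_to_mm3s(0.635), 4.8, p)
  # frozen from a 10x-finer radial grid run of the same formulation
  expect_equal(pr$wall_shear_rate, 127.1373, tolerance = 1e-3)
  # u is monotone non-increasing in r and satisfies no slip
  expect_true(all(diff(pr$axial_velocity) <= 1e-12))
  expect_equal(pr$axial_velocity[length(pr$axial_velocity)], 0)
  # grid convergence: < 0.1% change when doubling the default resolution
  pr2 <- solve_generalized_poiseuille(lmin_to_mm3s(0.635), 4.8, p,
                                      n_radial = 257)
  expect_lt(abs(pr2$wall_shear_rate - pr$wall_shear_rate) /
              pr$wall_shear_rate, 0.001)
})

test_that("routing conserves mass at both bifurcations", {
  mkconst <- function(q) flow_waveform(seq(0, 3.1, length.out = 16),
                                       rep(q, 16), 3.2)
  routed <- route_flows(list(REIV = mkconst(1), RIIV = mkconst(2),
                             LEIV = mkconst(3), LIIV = mkconst(4)))
  expect_equal(unique(routed$RCIV$flows), 3)
  expect_equal(unique(routed$LCIV$flows), 7)
  expect_equal(unique(routed$IVC$flows), 10)
  # an idle left leg leaves the LCIV with identically zero flow
  routed0 <- route_flows(list(REIV = mkconst(1), RIIV = mkconst(2),
                              LEIV = mkconst(0), LIIV = mkconst(0)))
  expect_true(all(routed0$LCIV$flows == 0))
  # group-average legs reproduce the expected IVC mean
  subj <- route_flows(list(
    REIV = generate_waveform(1.46 * 0.7, 3.2),
    RIIV = generate_waveform(1.46 * 0.3, 3.2),
    LEIV = generate_waveform(0.73 * 0.7, 3.2),
    LIIV = generate_waveform(0.73 * 0.3, 3.2)))
  expect_equal(mm3s_to_lmin(waveform_mean_flow(subj$IVC)), 2.19,
               tolerance = 1e-9)
  bad <- list(REIV = mkconst(1), RIIV = mkconst(2), LEIV = mkconst(3),
              LIIV = flow_waveform(seq(0, 2.9, length.out = 16),
                                   rep(4, 16), 3.0))
  expect_error(route_flows(bad), "mismatched periods")
})

test_that("Windkessel pressure has the exact steady fixed point", {
  wk <- windkessel_params(0.002, 20, 0.04, reference_pressure = 100)
  q <- 30000
  wf <- flow_waveform(seq(0, 3.1, length.out = 32), rep(q, 32), 3.2)
  sol <- windkessel_pressure(wf, wk)
  expect_equal(sol$mean_pressure, 100 + (0.002 + 0.04) * q,
               tolerance = 1e-6)
  expect_lt(diff(range(sol$pressure)) / sol$mean_pressure, 1e-9)
  expect_error(windkessel_pressure(wf, wk, dt = 0.5), "dt")
  expect_error(windkessel_pressure(wf, wk, n_cycles = 1), "n_cycles")
})

test_that("published group-average resistances reproduce 10 mmHg", {
  # subjects: (Rp + Rd) x (right + left leg flow)
  wk_s <- windkessel_params(0.00187, 22.4, 0.0355)
  q_s <- lmin_to_mm3s(1.46 + 0.73)
  wf_s <- flow_waveform(seq(0, 3.1, length.out = 32), rep(q_s, 32), 3.2)
  p_s <- pa_to_mmhg(windkessel_pressure(wf_s, wk_s)$mean_pressure)
  expect_equal(round(p_s), 10)
  wk_c <- windkessel_params(0.00237, 12.6, 0.0451)
  q_c <- lmin_to_mm3s(0.82 + 0.91)
  wf_c <- flow_waveform(seq(0, 3.1, length.out = 32), rep(q_c, 32), 3.2)
  p_c <- pa_to_mmhg(windkessel_pressure(wf_c, wk_c)$mean_pressure)
  expect_equal(round(p_c), 10)
})

test_that("compliance shifts phase but not the cycle mean", {
  wk <- windkessel_params(0.002, 20, 0.04)
  wf <- generate_waveform(2, 3.2, phasicity = 0.4)
  sol <- windkessel_pressure(wf, wk, dt = 0.005, n_cycles = 6)
  expect_equal(sol$mean_pressure, (0.002 + 0.04) * lmin_to_mm3s(2),
               tolerance = 1e-3)
})

test_that("the zero-compliance limit tracks resistive pressure pointwise", {
  wk <- windkessel_params(0.002, 0.1, 0.04)
  wf <- generate_waveform(2, 3.2, phasicity = 0.3)
  sol <- windkessel_pressure(wf, wk, dt = 0.002, n_cycles = 4)
  q_at <- approx(c(wf$times, wf$period), c(wf$flows, wf$flows[1]),
                 xout = sol$times, rule = 2)$y
  expect_lt(max(abs(sol$pressure - (0.002 + 0.04) * q_at)) /
              mean(sol$pressure), 0.005)
})

test_that("Windkessel tuning matches the published resistance scale", {
  q <- lmin_to_mm3s(2.122)
  wk <- tune_windkessel(q, mmhg_to_pa(10), capacitance = 22.4)
  expect_equal(wk$r_proximal, 0.00187, tolerance = 0.02)
  expect_equal(wk$r_distal, 0.0355, tolerance = 0.02)
  # doubling the flow halves both resistances
  wk2 <- tune_windkessel(2 * q, mmhg_to_pa(10), capacitance = 22.4)
  expect_equal(wk2$r_proximal, wk$r_proximal / 2, tolerance = 1e-12)
  expect_equal(wk2$r_distal, wk$r_distal / 2, tolerance = 1e-12)
  expect_error(tune_windkessel(q, 0), "invalid-target")
})

test_that("a mirror-symmetric patient yields symmetric shear fields", {
  p <- make_virtual_patient(symmetric_config(), 3)
  sol <- simulate_patient(p, fast_options())
  ml <- colMeans(sol$segments$LCIV$mean_shear)
  mr <- colMeans(sol$segments$RCIV$mean_shear)
  expect_equal(ml, mr, tolerance = 0.01)
  expect_lt(junction_imbalance(sol), 1e-9)
  # quasi-steady consistency: time-mean station velocity = mean Q / A
  s <- sol$segments$RCIV
  expect_equal(colMeans(s$velocity), mean(s$q) / s$area, tolerance = 1e-12)
})

test_that("stenosis raises throat shear; pressure falls downstream", {
  p0 <- make_virtual_patient(fixed_subject_config(0.01), 3)
  p6 <- make_virtual_patient(fixed_subject_config(0.6), 3)
  opt <- fast_options()
  s0 <- simulate_patient(p0, opt)
  s6 <- simulate_patient(p6, opt)
  throat <- which.min(p6$segments$LCIV$area_profile)
  expect_gt(mean(s6$segments$LCIV$mean_shear[, throat]),
            mean(s0$segments$LCIV$mean_shear[, throat]))
  # venous drainage: pressure decreases from every inlet to the outlet
  for (nm in c("REIV", "LEIV", "RIIV", "LIIV")) {
    inlet_end <- ncol(s6$segments[[nm]]$pressure)
    expect_true(all(s6$segments[[nm]]$pressure[, inlet_end] >
                      s6$outlet_pressure))
  }
  # and monotonically along each segment's flow direction
  civ <- s6$segments$LCIV$pressure
  expect_true(all(civ[, ncol(civ)] >= civ[, 1]))
})
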