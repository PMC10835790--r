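# Reduced-order network hemodynamics: quasi-steady generalized-Poiseuille
# profiles per station under Carreau-Yasuda viscosity, flow routing by
# conservation, and an RCR Windkessel outflow at the infrarenal IVC.

#' Invert the constitutive law for shear rate
#'
#' Returns the unique \eqn{\dot\gamma \ge 0} with
#' \eqn{\mu(\dot\gamma)\dot\gamma = \tau}. Because \eqn{\mu} is bounded by
#' \eqn{[\mu_\infty, \mu_0]}, the root is bracketed by
#' \eqn{[\tau/\mu_0, \tau/\mu_\infty]} and found by safeguarded bisection
#' to a relative tolerance of 1e-10. Vectorized in `tau`.
#'
#' @param tau shear stress(es), Pa, >= 0.
#' @param params a [rheology_params()] object.
#' @param rel_tol relative tolerance on the returned shear rate.
#' @return Shear rate(s), 1/s.
#' @export
invert_stress <- function(tau, params = rheology_params(), rel_tol = 1e-10) {
  if (!is.numeric(tau) || any(!is.finite(tau)))
    stop("tau must be finite numeric", call. = FALSE)
  if (any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tp <- tau[pos]
  mu_inf <- params$mu_inf
  dmu <- params$mu_0 - params$mu_inf
  n1a <- (params$n - 1) / params$a
  a <- params$a
  lam <- params$lam
  lo <- tp / params$mu_0
  hi <- tp / mu_inf
  n_iter <- ceiling(log2(max(hi / pmax(lo, .Machine$double.xmin)) / rel_tol)) + 2L
  n_iter <- min(max(n_iter, 40L), 200L)
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    below <- (mu_inf + dmu * (1 + (lam * mid)^a)^n1a) * mid < tp
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out[pos] <- (lo + hi) / 2
  out
}

#' Solve quasi-steady generalized-Poiseuille flow in a circular tube
#'
#' Finds the pressure gradient \eqn{G = -dp/dz} for which fully developed,
#' axisymmetric flow of a Carreau-Yasuda fluid carries the requested
#' volumetric flow. In fully developed tube flow the stress profile is
#' \eqn{\tau(r) = G r / 2}; the local shear rate follows from
#' [invert_stress()], the axial velocity from the no-slip integral
#' \eqn{u(r) = \int_r^R \dot\gamma(s)\,ds}, and the flow from
#' \eqn{Q = 2\pi \int_0^R r\,u(r)\,dr}. The outer root-solve on \eqn{G}
#' uses the same discrete quadrature as the returned profile, so the
#' returned profile conserves mass to the solver tolerance; in the
#' Newtonian limit the discretization is exact and the solution matches
#' the Poiseuille closed form.
#'
#' @param flow volumetric flow Q, mm^3/s, >= 0.
#' @param radius tube radius R, mm, > 0.
#' @param params a [rheology_params()] object.
#' @param n_radial number of radial nodes (>= 32; forced odd for Simpson
#'   quadrature). Default 129.
#' @param rel_tol relative tolerance of the outer solve on G.
#' @return An object of class `radial_profile` with fields `radius_grid`
#'   (mm), `axial_velocity` (mm/s), `shear_rate` (1/s), `pressure_gradient`
#'   (G, Pa/mm), `flow` (mm^3/s) and `wall_shear_rate` (1/s).
#' @export
solve_generalized_poiseuille <- function(flow, radius,
                                         params = rheology_params(),
                                         n_radial = 129L, rel_tol = 1e-8) {
  .assert_scalar_number(flow, "flow", nonneg = TRUE)
  .assert_scalar_number(radius, "radius", positive = TRUE)
  if (n_radial < 32L) stop("n_radial must be >= 32", call. = FALSE)
  kern <- .gp_kernel(radius, params, n_radial)
  if (flow == 0) {
    n <- length(kern$r)
    return(structure(list(radius_grid = kern$r, axial_velocity = numeric(n),
                          shear_rate = numeric(n), pressure_gradient = 0,
                          flow = 0, wall_shear_rate = 0),
                     class = "radial_profile"))
  }
  g_grad <- .gp_solve_g(kern, flow, rel_tol = rel_tol)
  pr <- kern$profile(g_grad)
  structure(list(radius_grid = kern$r, axial_velocity = pr$u,
                 shear_rate = pr$gam, pressure_gradient = g_grad,
                 flow = flow, wall_shear_rate = pr$gam[length(kern$r)]),
            class = "radial_profile")
}

# Discrete generalized-Poiseuille kernel on a fixed radial grid: maps a
# candidate pressure gradient G to the shear-rate profile (via the stress
# inversion), the no-slip velocity (reverse cumulative trapezoid) and the
# discrete flow (Simpson quadrature of 2 pi r u). The outer solves use
# the same quadrature as the returned profile, so mass closure holds to
# the solver tolerance; in the Newtonian limit every rule is exact.
.gp_kernel <- function(radius, params, n_radial) {
  n <- as.integer(n_radial)
  if (n %% 2L == 0L) n <- n + 1L
  r <- seq(0, radius, length.out = n)
  wq <- .simpson_weights(n, r[2] - r[1])
  dr <- diff(r)
  profile <- function(g_grad) {
    gam <- invert_stress(g_grad * r / 2, params)
    ct <- c(0, cumsum((gam[-n] + gam[-1]) / 2 * dr))
    u <- ct[n] - ct
    list(gam = gam, u = u, q = 2 * pi * sum(wq * r * u))
  }
  list(r = r, radius = radius, params = params,
       profile = profile, flow_of = function(g) profile(g)$q)
}

# Solve flow_of(G) = target for G >= 0. With a warm start (`g_init` from
# a neighbouring time step) a safeguarded secant converges in a few
# kernel evaluations; otherwise Brent on the Newtonian bracket
# [8 mu_inf Q / (pi R^4), 8 mu_0 Q / (pi R^4)] (widened) is used.
.gp_solve_g <- function(kern, target, g_init = NULL, rel_tol = 1e-8) {
  g_lo <- 8 * kern$params$mu_inf * target / (pi * kern$radius^4) * 0.25
  g_hi <- 8 * kern$params$mu_0 * target / (pi * kern$radius^4) * 4
  if (!is.null(g_init) && is.finite(g_init) && g_init > 0) {
    g0 <- min(max(g_init, g_lo), g_hi)
    r0 <- kern$flow_of(g0) - target
    if (abs(r0) <= rel_tol * target) return(g0)
    # second point: scale as if Q were locally proportional to G
    g1 <- min(max(g0 * target / (target + r0), g_lo), g_hi)
    for (i in 1:30) {
      r1 <- kern$flow_of(g1) - target
      if (abs(r1) <= rel_tol * target) return(g1)
      if (r1 < 0) g_lo <- max(g_lo, g1) else g_hi <- min(g_hi, g1)
      step_ok <- is.finite(r0) && r1 != r0
      g2 <- if (step_ok) g1 - r1 * (g1 - g0) / (r1 - r0) else NA_real_
      if (!is.finite(g2) || g2 <= g_lo || g2 >= g_hi)
        g2 <- (g_lo + g_hi) / 2
      g0 <- g1; r0 <- r1; g1 <- g2
    }
    return(g1)
  }
  root <- tryCatch(
    stats::uniroot(function(g) kern$flow_of(g) - target,
                   lower = g_lo, upper = g_hi, extendInt = "upX",
                   tol = rel_tol * g_lo),
    error = function(e) stop("solver error: failed to bracket the pressure ",
                             "gradient (Q = ", target, " mm^3/s, R = ",
                             kern$radius, " mm): ", conditionMessage(e),
                             call. = FALSE))
  root$root
}

#' Volume-weighted mean shear rate of a radial profile
#'
#' For an axisymmetric profile the volume-weighted mean over the tube cross
#' section is \eqn{(2/R^2)\int_0^R \dot\gamma(r)\, r\, dr}; in Poiseuille
#' flow this equals \eqn{(2/3)\dot\gamma_{wall}}.
#'
#' @param profile a `radial_profile`.
#' @return Mean shear rate, 1/s.
#' @export
profile_mean_shear <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  r <- profile$radius_grid
  R <- r[length(r)]
  2 / R^2 * sum(.trapz_weights(r) * r * profile$shear_rate)
}

#' Periodic flow waveform
#'
#' One period of a volumetric flow waveform, treated as T-periodic. Sample
#' times must span exactly `[0, period)`.
#'
#' @param times sample times, s, strictly increasing, starting at 0 and
#'   ending before `period`.
#' @param flows volumetric flow at each time, mm^3/s; the time mean must
#'   be non-negative (inlet generators additionally enforce a strictly
#'   positive mean; a zero-mean branch is allowed so that routed trees
#'   with an idle leg remain representable).
#' @param period the period T, s.
#' @return An object of class `flow_waveform`.
#' @export
flow_waveform <- function(times, flows, period) {
  .assert_scalar_number(period, "period", positive = TRUE)
  if (length(times) != length(flows) || length(times) < 2L)
    stop("times and flows must have equal length >= 2", call. = FALSE)
  if (any(diff(times) <= 0) || times[1] != 0 || times[length(times)] >= period)
    stop("times must be strictly increasing and span [0, period)", call. = FALSE)
  if (mean(flows) < 0)
    stop("waveform must have non-negative mean flow", call. = FALSE)
  structure(list(times = as.numeric(times), flows = as.numeric(flows),
                 period = period), class = "flow_waveform")
}

#' Time-mean flow of a waveform
#'
#' Periodic trapezoidal mean over one full period (the wrap-around segment
#' from the last sample back to t = T is included).
#'
#' @param wf a [flow_waveform()].
#' @return Mean flow, mm^3/s.
#' @export
waveform_mean_flow <- function(wf) {
  stopifnot(inherits(wf, "flow_waveform"))
  t_ext <- c(wf$times, wf$period)
  q_ext <- c(wf$flows, wf$flows[1])
  pracma::trapz(t_ext, q_ext) / wf$period
}

# Periodic linear interpolation of a waveform at arbitrary times.
.waveform_at <- function(wf, t) {
  tm <- t %% wf$period
  t_ext <- c(wf$times, wf$period)
  q_ext <- c(wf$flows, wf$flows[1])
  stats::approx(t_ext, q_ext, xout = tm, rule = 2)$y
}

# Resample a waveform onto a given time grid (within one period).
.resample_waveform <- function(wf, times, period) {
  flow_waveform(times, .waveform_at(wf, times), period)
}

#' Route inlet flows through the iliac venous tree
#'
#' Applies conservation of mass at the fixed topology
#' REIV + RIIV -> RCIV, LEIV + LIIV -> LCIV, RCIV + LCIV -> IVC,
#' pointwise in time after resampling all four inlet waveforms onto a
#' shared time grid.
#'
#' @param inflows named list of [flow_waveform()]s with names `REIV`,
#'   `LEIV`, `RIIV`, `LIIV`, on a common period.
#' @return Named list of seven `flow_waveform`s (the four inlets resampled
#'   plus `RCIV`, `LCIV`, `IVC`).
#' @export
route_flows <- function(inflows) {
  need <- c("REIV", "LEIV", "RIIV", "LIIV")
  if (!all(need %in% names(inflows)))
    stop("configuration error: all four inlets (REIV, LEIV, RIIV, LIIV) ",
         "must be present", call. = FALSE)
  periods <- vapply(inflows[need], function(w) w$period, numeric(1))
  if (max(abs(periods - periods[1])) > 1e-9 * periods[1])
    stop("configuration error: inlet waveforms have mismatched periods",
         call. = FALSE)
  period <- periods[[1]]
  n <- max(vapply(inflows[need], function(w) length(w$times), integer(1)))
  times <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  res <- lapply(inflows[need], .resample_waveform, times = times,
                period = period)
  res$RCIV <- flow_waveform(times, res$REIV$flows + res$RIIV$flows, period)
  res$LCIV <- flow_waveform(times, res$LEIV$flows + res$LIIV$flows, period)
  res$IVC <- flow_waveform(times, res$RCIV$flows + res$LCIV$flows, period)
  res
}

#' Three-element (RCR) Windkessel parameters
#'
#' Proximal resistance, compliance and distal resistance of the lumped
#' outflow model coupled to the infrarenal IVC, in mm-g-s units
#' (resistance Pa s/mm^3, compliance mm^3/Pa).
#'
#' @param r_proximal proximal resistance, Pa s/mm^3, > 0.
#' @param capacitance compliance C, mm^3/Pa, > 0.
#' @param r_distal distal resistance, Pa s/mm^3, > 0.
#' @param reference_pressure venous outflow reference pressure, Pa
#'   (default 0, gauge).
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(r_proximal, capacitance, r_distal,
                              reference_pressure = 0) {
  .assert_scalar_number(r_proximal, "r_proximal", positive = TRUE)
  .assert_scalar_number(capacitance, "capacitance", positive = TRUE)
  .assert_scalar_number(r_distal, "r_distal", positive = TRUE)
  .assert_scalar_number(reference_pressure, "reference_pressure")
  structure(list(r_proximal = r_proximal, capacitance = capacitance,
                 r_distal = r_distal, reference_pressure = reference_pressure),
            class = "windkessel_params")
}

#' Integrate the RCR Windkessel outlet pressure
#'
#' Integrates the compliance state equation
#' \eqn{C\,dP_c/dt = Q(t) - (P_c - P_{ref})/R_d} with fixed-step RK4
#' (via \pkg{deSolve}), with outlet pressure \eqn{P = R_p Q + P_c}. The
#' state is initialized at the steady value \eqn{P_{ref} + R_d \bar Q} and
#' the first cycle is discarded as transient; the last full cycle is
#' returned.
#'
#' @param outlet_flow a [flow_waveform()] of the total outflow, mm^3/s.
#' @param wk a [windkessel_params()] object.
#' @param dt time step, s; must satisfy `dt <= period / 50`.
#' @param n_cycles number of periods to integrate (>= 2).
#' @return A list with `times` (one period, s), `pressure` (Pa) and
#'   `mean_pressure` (Pa, periodic trapezoidal mean).
#' @export
windkessel_pressure <- function(outlet_flow, wk, dt = 0.01, n_cycles = 4L) {
  stopifnot(inherits(outlet_flow, "flow_waveform"),
            inherits(wk, "windkessel_params"))
  period <- outlet_flow$period
  if (dt > period / 50)
    stop("dt must be <= period / 50", call. = FALSE)
  if (n_cycles < 2L) stop("n_cycles must be >= 2", call. = FALSE)
  times <- seq(0, n_cycles * period, by = dt)
  qbar <- waveform_mean_flow(outlet_flow)
  p0 <- wk$reference_pressure + wk$r_distal * qbar
  rhs <- function(t, y, parms) {
    q <- .waveform_at(outlet_flow, t)
    list((q - (y[1] - wk$reference_pressure) / wk$r_distal) / wk$capacitance)
  }
  sol <- deSolve::ode(y = c(pc = p0), times = times, func = rhs,
                      parms = NULL, method = "rk4")
  pc <- sol[, "pc"]
  if (any(!is.finite(pc)))
    stop("step-size error: Windkessel integration diverged (non-finite ",
         "pressure); reduce dt", call. = FALSE)
  p <- wk$r_proximal * .waveform_at(outlet_flow, times) + pc
  keep <- times >= (n_cycles - 1L) * period - 1e-12
  tt <- times[keep] - (n_cycles - 1L) * period
  pp <- p[keep]
  mean_p <- pracma::trapz(tt, pp) / (tt[length(tt)] - tt[1])
  list(times = tt, pressure = pp, mean_pressure = mean_p)
}

#' Tune RCR Windkessel resistances to a target mean outlet pressure
#'
#' Sets the total resistance from the steady balance
#' \eqn{R_{tot} = (P_{target} - P_{ref}) / \bar Q} and splits it into
#' proximal and distal parts by `proximal_fraction` (default 5%, the split
#' implied by published subject- and control-average resistances). The
#' tuned parameters are verified by integrating the Windkessel at constant
#' flow: the achieved mean must match the target within 0.5%.
#'
#' @param mean_flow mean outflow, mm^3/s, > 0.
#' @param target_mean_pressure target mean outlet pressure, Pa (e.g.
#'   `mmhg_to_pa(10)`).
#' @param proximal_fraction fraction of total resistance assigned to the
#'   proximal element, in (0, 1).
#' @param capacitance compliance, mm^3/Pa.
#' @param reference_pressure venous reference pressure, Pa.
#' @return A [windkessel_params()] object.
#' @export
tune_windkessel <- function(mean_flow, target_mean_pressure,
                            proximal_fraction = 0.05, capacitance = 20,
                            reference_pressure = 0) {
  .assert_scalar_number(mean_flow, "mean_flow", positive = TRUE)
  .assert_scalar_number(target_mean_pressure, "target_mean_pressure")
  if (proximal_fraction <= 0 || proximal_fraction >= 1)
    stop("proximal_fraction must lie in (0, 1)", call. = FALSE)
  if (target_mean_pressure <= reference_pressure)
    stop("invalid-target error: target pressure must exceed the reference ",
         "pressure", call. = FALSE)
  r_total <- (target_mean_pressure - reference_pressure) / mean_flow
  wk <- windkessel_params(r_proximal = proximal_fraction * r_total,
                          capacitance = capacitance,
                          r_distal = (1 - proximal_fraction) * r_total,
                          reference_pressure = reference_pressure)
  chk <- windkessel_pressure(
    flow_waveform(seq(0, 3.1, length.out = 32), rep(mean_flow, 32), 3.2),
    wk, dt = 0.01, n_cycles = 2L)
  if (abs(chk$mean_pressure - target_mean_pressure) >
      0.005 * target_mean_pressure)
    stop("Windkessel tuning failed verification (mean pressure off target ",
         "by more than 0.5%)", call. = FALSE)
  wk
}
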