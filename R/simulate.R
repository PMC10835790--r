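# Patient-level network simulation: per-station generalized-Poiseuille
# profiles over one respiratory cycle, pressure assembly from the
# Windkessel outlet upward.

#' Solver options for [simulate_patient()]
#'
#' @param dt Windkessel integration step, s.
#' @param n_cycles respiratory cycles to integrate (first discarded as
#'   transient; the last is stored).
#' @param n_store number of stored time samples over the final cycle.
#' @param n_radial radial nodes per station profile.
#' @param rheology a [rheology_params()] object.
#' @param windkessel optional [windkessel_params()]; when `NULL` the
#'   Windkessel is tuned to `target_pressure` from the patient's mean
#'   IVC flow.
#' @param target_pressure mean IVC pressure target, Pa.
#' @param proximal_fraction proximal share of the tuned total resistance.
#' @param capacitance compliance used when tuning; `NULL` takes the
#'   patient's configured value.
#' @return An object of class `sim_options`.
#' @export
sim_options <- function(dt = 0.01, n_cycles = 4L, n_store = 32L,
                        n_radial = 129L, rheology = rheology_params(),
                        windkessel = NULL,
                        target_pressure = mmhg_to_pa(10),
                        proximal_fraction = 0.05, capacitance = NULL) {
  structure(list(dt = dt, n_cycles = as.integer(n_cycles),
                 n_store = as.integer(n_store),
                 n_radial = as.integer(n_radial), rheology = rheology,
                 windkessel = windkessel, target_pressure = target_pressure,
                 proximal_fraction = proximal_fraction,
                 capacitance = capacitance),
            class = "sim_options")
}

# Solve profiles for one segment at all stored times. Stations sharing a
# radius share one solve per time step.
.solve_segment <- function(seg, q_t, options) {
  z <- seg$arclength_grid
  n_z <- length(z)
  n_t <- length(q_t)
  radius <- sqrt(seg$area_profile / pi)
  key <- signif(radius, 12)
  uk <- unique(key)
  map <- match(key, uk)
  n_r <- options$n_radial
  if (n_r %% 2L == 0L) n_r <- n_r + 1L
  xi <- seq(0, 1, length.out = n_r)

  gmat <- matrix(0, n_t, n_z)
  wall <- matrix(0, n_t, n_z)
  msh <- matrix(0, n_t, n_z)
  gam <- array(0, c(n_t, n_z, n_r))
  for (ui in seq_along(uk)) {
    kern <- .gp_kernel(uk[ui], options$rheology, n_r)
    rw <- .trapz_weights(kern$r) * kern$r * 2 / uk[ui]^2
    cols <- which(map == ui)
    g_prev <- NULL
    q_prev <- NULL
    for (ti in seq_len(n_t)) {
      q <- q_t[ti]
      if (q <= 0) {
        g_prev <- NULL
        next
      }
      g_init <- if (!is.null(g_prev)) g_prev * q / q_prev else NULL
      g <- .gp_solve_g(kern, q, g_init = g_init)
      pr <- kern$profile(g)
      gmat[ti, cols] <- g
      wall[ti, cols] <- pr$gam[n_r]
      msh[ti, cols] <- sum(rw * pr$gam)
      gam[ti, cols, ] <- matrix(pr$gam, length(cols), n_r, byrow = TRUE)
      g_prev <- g
      q_prev <- q
    }
  }
  list(z = z, area = seg$area_profile, radius = radius,
       origin_distance = seg$origin_distance, q = q_t,
       velocity = outer(q_t, seg$area_profile, "/"),
       G = gmat, wall_shear = wall, mean_shear = msh, gamma = gam, xi = xi)
}

# Axial pressure accumulation: int G dz per time, cumulative along z.
.cum_pressure <- function(G, z) {
  n_z <- length(z)
  if (n_z < 2L) return(G * 0)
  dz <- diff(z)
  seg_drop <- (G[, -n_z, drop = FALSE] + G[, -1L, drop = FALSE]) / 2 *
    matrix(dz, nrow(G), n_z - 1L, byrow = TRUE)
  cs <- if (ncol(seg_drop) == 1L) seg_drop
        else t(apply(seg_drop, 1L, cumsum))
  cbind(0, cs)
}

#' Simulate one virtual patient
#'
#' The reduced-order surrogate for a full 3D unsteady CFD solve: inlet
#' waveforms are routed by conservation through the fixed bilateral
#' topology; at every stored time and arclength station a quasi-steady,
#' fully developed generalized-Poiseuille profile is solved at the local
#' radius and instantaneous flow; the outlet pressure comes from the RCR
#' Windkessel (tuned to the target mean IVC pressure unless explicit
#' parameters are supplied) and station pressures are assembled from the
#' outlet upward by accumulating the local pressure gradients.
#'
#' The model is quasi-steady and axisymmetric: it omits secondary flows
#' and post-stenotic jets, so absolute shear magnitudes are surrogates
#' while severity trends and left/right ratios are preserved.
#'
#' @param patient a `virtual_patient` (from [make_virtual_patient()] or
#'   [read_patient_bundle()]).
#' @param options a [sim_options()] object.
#' @return An object of class `network_solution`: stored `times` (s, one
#'   cycle), `period`, per-segment lists (station grid `z`, `area`,
#'   `radius`, flow `q`, `velocity`, pressure-gradient `G`, `wall_shear`,
#'   `mean_shear`, radial shear array `gamma` `[time, station, node]` on
#'   the normalized radial grid `xi`, and `pressure`), `outlet_pressure`,
#'   and the `windkessel` used.
#' @export
simulate_patient <- function(patient, options = sim_options()) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(options, "sim_options"))
  flows <- route_flows(patient$inflows)
  period <- flows$IVC$period
  n_t <- options$n_store
  times <- seq(0, period, length.out = n_t + 1L)[seq_len(n_t)]

  wk <- options$windkessel
  if (is.null(wk)) {
    cap <- options$capacitance %||% patient$config$capacitance %||% 20
    wk <- tune_windkessel(waveform_mean_flow(flows$IVC),
                          options$target_pressure,
                          proximal_fraction = options$proximal_fraction,
                          capacitance = cap)
  }
  wsol <- windkessel_pressure(flows$IVC, wk, dt = options$dt,
                              n_cycles = options$n_cycles)
  p_out <- stats::approx(wsol$times, wsol$pressure, xout = times,
                         rule = 2)$y

  segs <- lapply(.SEGMENT_NAMES, function(nm) {
    q_t <- .waveform_at(flows[[nm]], times)
    .solve_segment(patient$segments[[nm]], q_t, options)
  })
  names(segs) <- .SEGMENT_NAMES

  # Pressure assembly. Orientations: IVC z runs confluence -> outlet
  # (along flow); CIVs z runs confluence -> leg (against flow); inlets z
  # runs CIV junction -> periphery (against flow).
  ivc <- segs$IVC
  drop_ivc <- .cum_pressure(ivc$G, ivc$z)     # [t, z] pressure drop from z=0
  n_zi <- length(ivc$z)
  p_conf <- p_out + drop_ivc[, n_zi]          # confluence pressure
  segs$IVC$pressure <- p_conf - drop_ivc      # decreases toward outlet
  for (nm in c("RCIV", "LCIV")) {
    segs[[nm]]$pressure <- p_conf + .cum_pressure(segs[[nm]]$G, segs[[nm]]$z)
  }
  p_junc <- list(R = segs$RCIV$pressure[, length(segs$RCIV$z)],
                 L = segs$LCIV$pressure[, length(segs$LCIV$z)])
  for (nm in c("REIV", "RIIV")) {
    segs[[nm]]$pressure <- p_junc$R + .cum_pressure(segs[[nm]]$G, segs[[nm]]$z)
  }
  for (nm in c("LEIV", "LIIV")) {
    segs[[nm]]$pressure <- p_junc$L + .cum_pressure(segs[[nm]]$G, segs[[nm]]$z)
  }

  structure(list(times = times, period = period, segments = segs,
                 outlet_pressure = p_out, mean_outlet_pressure =
                   wsol$mean_pressure, windkessel = wk,
                 patient_id = patient$id, group = patient$group,
                 options = options),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf("Network solution for %s (%s)\n", x$patient_id, x$group))
  cat(sprintf("  %d stored times over one %.2f s cycle\n",
              length(x$times), x$period))
  cat(sprintf("  mean outlet pressure %.2f mmHg\n",
              pa_to_mmhg(x$mean_outlet_pressure)))
  qbar <- vapply(x$segments, function(s) mean(s$q), numeric(1))
  cat(sprintf("  mean flows (L/min): %s\n",
              paste(sprintf("%s=%.2f", names(qbar), mm3s_to_lmin(qbar)),
                    collapse = ", ")))
  invisible(x)
}

#' Verify junction mass conservation of a solution
#'
#' Returns the maximum relative imbalance over stored times at the three
#' junctions (REIV+RIIV vs RCIV, LEIV+LIIV vs LCIV, RCIV+LCIV vs IVC).
#'
#' @param solution a `network_solution`.
#' @return Maximum relative flow imbalance (dimensionless).
#' @export
junction_imbalance <- function(solution) {
  s <- solution$segments
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
  max(rel(s$REIV$q + s$RIIV$q, s$RCIV$q),
      rel(s$LEIV$q + s$LIIV$q, s$LCIV$q),
      rel(s$RCIV$q + s$LCIV$q, s$IVC$q))
}

#' Export a network solution to per-segment CSV files
#'
#' One CSV per segment with columns `t_s, z_mm, q_mm3_s, p_pa,
#' wall_shear_1_s, mean_shear_1_s`, plus a JSON run manifest with the
#' solver options and Windkessel parameters.
#'
#' @param solution a `network_solution`.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
export_solution_csv <- function(solution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(solution$segments)) {
    s <- solution$segments[[nm]]
    d <- expand.grid(t_s = solution$times, z_mm = s$z)
    d$q_mm3_s <- rep(s$q, times = length(s$z))
    d$p_pa <- as.vector(s$pressure)
    d$wall_shear_1_s <- as.vector(s$wall_shear)
    d$mean_shear_1_s <- as.vector(s$mean_shear)
    utils::write.csv(d, file.path(dir, sprintf("segment_%s.csv", nm)),
                     row.names = FALSE)
  }
  opts <- solution$options
  manifest <- list(patient_id = solution$patient_id, group = solution$group,
                   period = solution$period,
                   windkessel = unclass(solution$windkessel),
                   options = list(dt = opts$dt, n_cycles = opts$n_cycles,
                                  n_store = opts$n_store,
                                  n_radial = opts$n_radial,
                                  rheology = unclass(opts$rheology)))
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
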