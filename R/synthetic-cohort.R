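# Virtual-patient generator: bilateral iliac venous trees (IVC, RCIV,
# LCIV, REIV/LEIV, RIIV/LIIV), a parameterized LCIV compression,
# respiratory-periodic inflow waveforms and ultrasound-like measurements.

.SEGMENT_NAMES <- c("IVC", "RCIV", "LCIV", "REIV", "LEIV", "RIIV", "LIIV")

#' Stenosis specification
#'
#' Parameterizes the left common iliac vein compression as a smooth cosine
#' bump: inside the extent the area is
#' \eqn{A(z) = A_0 [1 - s (1 + \cos(2\pi (z - z_c)/L)) / 2]}, equal to
#' \eqn{A_0} at the edges and \eqn{A_0 (1 - s)} at the throat.
#'
#' @param severity fraction of the reference area removed at the throat,
#'   in `[0, 0.95]`.
#' @param center_position arclength of the throat along the LCIV, measured
#'   from the iliac confluence, mm.
#' @param length axial extent L of the narrowing, mm, > 0.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(severity, center_position, length) {
  .assert_scalar_number(severity, "severity", nonneg = TRUE)
  if (severity > 0.95)
    stop("invalid-parameter error: severity must lie in [0, 0.95]",
         call. = FALSE)
  .assert_scalar_number(center_position, "center_position", positive = TRUE)
  .assert_scalar_number(length, "length", positive = TRUE)
  structure(list(severity = severity, center_position = center_position,
                 length = length), class = "stenosis_spec")
}

#' Vessel segment
#'
#' A one-dimensional description of a vessel: a strictly increasing
#' arclength grid with the cross-sectional area at each station. For the
#' common iliac veins, arclength is measured from the iliac confluence
#' (z = 0 at the confluence, increasing caudally); `origin_distance`
#' records the distance of the segment start from the confluence so that
#' control-volume positions are comparable across vessels.
#'
#' @param name one of `IVC`, `RCIV`, `LCIV`, `REIV`, `LEIV`, `RIIV`, `LIIV`.
#' @param arclength_grid strictly increasing positions, mm.
#' @param area_profile cross-sectional area at each position, mm^2, > 0.
#' @param origin_distance distance of the segment start from the iliac
#'   confluence, mm.
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(name, arclength_grid, area_profile,
                           origin_distance = 0) {
  name <- match.arg(name, .SEGMENT_NAMES)
  if (length(arclength_grid) != length(area_profile))
    stop("arclength_grid and area_profile must have equal length",
         call. = FALSE)
  if (any(diff(arclength_grid) <= 0))
    stop("arclength_grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(area_profile)) || any(area_profile <= 0))
    stop("area_profile must be positive everywhere", call. = FALSE)
  .assert_scalar_number(origin_distance, "origin_distance", nonneg = TRUE)
  structure(list(name = name, arclength_grid = as.numeric(arclength_grid),
                 area_profile = as.numeric(area_profile),
                 origin_distance = origin_distance),
            class = "vessel_segment")
}

#' Ultrasound-like measurement record
#'
#' Emulates a spectral-Doppler + B-mode acquisition at one slice: the
#' time-averaged velocity and the cross-sectional area, with the slice
#' position along the vessel.
#'
#' @param vessel vessel name.
#' @param mean_velocity time-mean velocity, mm/s, >= 0.
#' @param mean_area cross-sectional area at the slice, mm^2, > 0.
#' @param slice_position arclength of the measurement, mm.
#' @param mean_flow optional directly measured mean flow, mm^3/s; when
#'   `NULL` the measured flow is taken as `mean_velocity * mean_area`.
#' @return An object of class `ultrasound_record`.
#' @export
ultrasound_record <- function(vessel, mean_velocity, mean_area,
                              slice_position, mean_flow = NULL) {
  vessel <- match.arg(vessel, .SEGMENT_NAMES)
  .assert_scalar_number(mean_velocity, "mean_velocity", nonneg = TRUE)
  .assert_scalar_number(mean_area, "mean_area", positive = TRUE)
  .assert_scalar_number(slice_position, "slice_position", nonneg = TRUE)
  if (!is.null(mean_flow))
    .assert_scalar_number(mean_flow, "mean_flow", positive = TRUE)
  structure(list(vessel = vessel, mean_velocity = mean_velocity,
                 mean_area = mean_area, slice_position = slice_position,
                 mean_flow = mean_flow), class = "ultrasound_record")
}

#' Generate a respiratory-periodic inflow waveform
#'
#' Waveform family \eqn{Q(t) = \bar Q\,[1 + \phi \cos(2\pi t / T)]}: a
#' single-harmonic phasic signal whose sampled time mean equals the
#' requested mean exactly (uniform sampling of whole periods) and whose
#' minimum is \eqn{\bar Q (1 - \phi) > 0}.
#'
#' @param mean_flow mean flow, L/min, > 0.
#' @param period respiratory period T, s, > 0.
#' @param phasicity relative amplitude \eqn{\phi}, dimensionless in
#'   `[0, 1)`.
#' @param n_samples number of samples over one period (>= 8).
#' @param seed integer seed, kept for interface stability; the waveform
#'   family is deterministic.
#' @return A [flow_waveform()] with flows in mm^3/s.
#' @export
generate_waveform <- function(mean_flow, period, phasicity = 0.3,
                              n_samples = 64L, seed = 0L) {
  .assert_scalar_number(mean_flow, "mean_flow", positive = TRUE)
  .assert_scalar_number(period, "period", positive = TRUE)
  if (phasicity < 0 || phasicity >= 1)
    stop("invalid-parameter error: phasicity must lie in [0, 1)",
         call. = FALSE)
  if (n_samples < 8L)
    stop("invalid-parameter error: n_samples must be >= 8", call. = FALSE)
  qbar <- lmin_to_mm3s(mean_flow)
  times <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  flows <- qbar * (1 + phasicity * cos(2 * pi * times / period))
  flow_waveform(times, flows, period)
}

# Cosine-bump area profile for the LCIV.
.stenosed_area <- function(z, baseline, stenosis) {
  a <- rep(baseline, length(z))
  if (stenosis$severity == 0) return(a)
  zc <- stenosis$center_position
  half <- stenosis$length / 2
  inside <- abs(z - zc) <= half
  a[inside] <- baseline *
    (1 - stenosis$severity *
       (1 + cos(2 * pi * (z[inside] - zc) / stenosis$length)) / 2)
  a
}

#' Generate the seven-segment iliac tree geometry
#'
#' Builds constant-area segments for all vessels except the LCIV, which
#' receives a smooth cosine-bump narrowing per the [stenosis_spec()]. The
#' stenosis must lie strictly inside the LCIV.
#'
#' @param baseline_areas named numeric vector of reference areas, mm^2,
#'   one entry per segment name.
#' @param lengths named numeric vector of segment lengths, mm.
#' @param stenosis a [stenosis_spec()] (use severity 0 for an
#'   uncompressed tree).
#' @param station_spacing arclength spacing of the stored stations, mm.
#' @return Named list of seven [vessel_segment()]s.
#' @export
generate_geometry <- function(baseline_areas, lengths, stenosis,
                              station_spacing = 1) {
  if (!all(.SEGMENT_NAMES %in% names(baseline_areas)) ||
      !all(.SEGMENT_NAMES %in% names(lengths)))
    stop("baseline_areas and lengths must be named with all seven segments",
         call. = FALSE)
  if (any(baseline_areas <= 0) || any(lengths <= 0))
    stop("invalid-parameter error: areas and lengths must be > 0",
         call. = FALSE)
  stopifnot(inherits(stenosis, "stenosis_spec"))
  if (stenosis$severity > 0) {
    lo <- stenosis$center_position - stenosis$length / 2
    hi <- stenosis$center_position + stenosis$length / 2
    if (lo <= 0 || hi >= lengths[["LCIV"]])
      stop("invalid-parameter error: stenosis extends beyond the LCIV",
           call. = FALSE)
  }
  segs <- list()
  for (nm in .SEGMENT_NAMES) {
    z <- seq(0, lengths[[nm]], by = station_spacing)
    if (z[length(z)] < lengths[[nm]]) z <- c(z, lengths[[nm]])
    area <- if (nm == "LCIV") .stenosed_area(z, baseline_areas[[nm]], stenosis)
            else rep(baseline_areas[[nm]], length(z))
    origin <- if (nm %in% c("REIV", "RIIV")) lengths[["RCIV"]]
              else if (nm %in% c("LEIV", "LIIV")) lengths[["LCIV"]]
              else 0
    segs[[nm]] <- vessel_segment(nm, z, area, origin)
  }
  segs
}

#' Apply multiplicative measurement noise
#'
#' Emulates ultrasound measurement variability:
#' `noisy = true * max(0.05, 1 + cv * g)` with `g` standard normal. The
#' positivity floor of 0.05 keeps noisy areas and velocities physical.
#' With `cv = 0` the value is returned unchanged (and no random draw is
#' consumed).
#'
#' @param true_value positive true value(s).
#' @param coefficient_of_variation relative noise level, >= 0.
#' @param seed optional integer seed for a self-contained draw; when
#'   `NULL` the current RNG stream is used.
#' @return Noisy value(s), always > 0.
#' @export
apply_measurement_noise <- function(true_value, coefficient_of_variation,
                                    seed = NULL) {
  if (any(true_value <= 0)) stop("true_value must be > 0", call. = FALSE)
  cv <- coefficient_of_variation
  .assert_scalar_number(cv, "coefficient_of_variation", nonneg = TRUE)
  if (cv == 0) return(true_value)
  draw <- function() {
    true_value * pmax(0.05, 1 + cv * stats::rnorm(length(true_value)))
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Virtual-patient configuration
#'
#' The study conditions for one simulated case. Defaults follow the
#' published cohort where values are reported (group-average leg flows,
#' respiratory periods 3.0-3.75 s, common iliac areas, compliances) and
#' documented stand-ins elsewhere (30:70 internal:external iliac split,
#' waveform phasicity 0.3, 5% measurement noise).
#'
#' @param group `"Subject"` (stenosed) or `"Control"`.
#' @param leg_mean_flows named vector `c(right = , left = )`, L/min: total
#'   venous return per leg.
#' @param period_range respiratory period sampling range, s.
#' @param phasicity waveform phasicity in `[0, 1)`.
#' @param iiv_fraction fraction of each leg's flow entering through the
#'   internal iliac vein.
#' @param baseline_areas,lengths named per-segment geometry, mm^2 / mm.
#' @param severity_range stenosis severity sampling range; must be
#'   `c(0, 0)` for Controls.
#' @param stenosis_center,stenosis_length stenosis position and extent
#'   along the LCIV, mm.
#' @param flow_scale_range multiplicative per-leg flow variability range.
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param capacitance Windkessel compliance, mm^3/Pa.
#' @param n_waveform_samples samples per waveform period.
#' @param frozen_inlets character vector of inlet names whose waveforms
#'   the calibration loop must not rescale.
#' @return An object of class `patient_config`.
#' @seealso [subject_template()], [control_template()]
#' @export
patient_config <- function(group = c("Subject", "Control"),
                           leg_mean_flows = c(right = 1.0, left = 1.0),
                           period_range = c(3.2, 3.2),
                           phasicity = 0.3,
                           iiv_fraction = 0.3,
                           baseline_areas = c(IVC = 280, RCIV = 138.5,
                                              LCIV = 131.8, REIV = 110,
                                              LEIV = 110, RIIV = 60,
                                              LIIV = 60),
                           lengths = c(IVC = 100, RCIV = 60, LCIV = 60,
                                       REIV = 80, LEIV = 80, RIIV = 60,
                                       LIIV = 60),
                           severity_range = c(0, 0),
                           stenosis_center = 30, stenosis_length = 30,
                           flow_scale_range = c(1, 1),
                           noise_cv = 0.05,
                           capacitance = 20,
                           n_waveform_samples = 64L,
                           frozen_inlets = character(0)) {
  group <- match.arg(group)
  if (!all(c("right", "left") %in% names(leg_mean_flows)))
    stop("leg_mean_flows must be named c(right=, left=)", call. = FALSE)
  if (group == "Control" && any(severity_range != 0))
    stop("configuration error: Controls must have severity 0", call. = FALSE)
  if (group == "Subject" && severity_range[1] <= 0)
    stop("configuration error: Subjects must have severity > 0", call. = FALSE)
  if (iiv_fraction < 0 || iiv_fraction >= 1)
    stop("iiv_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(group = group, leg_mean_flows = leg_mean_flows,
                 period_range = period_range, phasicity = phasicity,
                 iiv_fraction = iiv_fraction,
                 baseline_areas = baseline_areas, lengths = lengths,
                 severity_range = severity_range,
                 stenosis_center = stenosis_center,
                 stenosis_length = stenosis_length,
                 flow_scale_range = flow_scale_range,
                 noise_cv = noise_cv, capacitance = capacitance,
                 n_waveform_samples = as.integer(n_waveform_samples),
                 frozen_inlets = frozen_inlets),
            class = "patient_config")
}

#' Subject-group (stenosed) configuration template
#'
#' Group-average conditions for a compressed patient: right/left leg flows
#' 1.46 / 0.73 L/min, stenosis severity sampled in 0.4-0.8 on an LCIV
#' baseline of 131.8 mm^2, RCIV area 196.3 mm^2, compliance 22.4 mm^3/Pa,
#' respiratory period 3.0-3.75 s.
#'
#' @param ... overrides forwarded to [patient_config()].
#' @return A `patient_config`.
#' @export
subject_template <- function(...) {
  args <- list(group = "Subject",
               leg_mean_flows = c(right = 1.46, left = 0.73),
               period_range = c(3.0, 3.75),
               baseline_areas = c(IVC = 280, RCIV = 196.3, LCIV = 131.8,
                                  REIV = 110, LEIV = 110, RIIV = 60,
                                  LIIV = 60),
               severity_range = c(0.4, 0.8),
               flow_scale_range = c(0.7, 1.3),
               capacitance = 22.4)
  args[names(list(...))] <- list(...)
  do.call(patient_config, args)
}

#' Control-group (uncompressed) configuration template
#'
#' Group-average conditions for an uncompressed patient: right/left leg
#' flows 0.82 / 0.91 L/min, severity 0, RCIV area 138.5 mm^2, LCIV area
#' 131.8 mm^2, compliance 12.6 mm^3/Pa.
#'
#' @param ... overrides forwarded to [patient_config()].
#' @return A `patient_config`.
#' @export
control_template <- function(...) {
  args <- list(group = "Control",
               leg_mean_flows = c(right = 0.82, left = 0.91),
               period_range = c(3.0, 3.75),
               severity_range = c(0, 0),
               flow_scale_range = c(0.7, 1.3),
               capacitance = 12.6)
  args[names(list(...))] <- list(...)
  do.call(patient_config, args)
}

#' Generate one virtual patient
#'
#' Samples the free quantities of a [patient_config()] (severity, period,
#' per-leg flow scales) with a local RNG seeded by `seed`, builds the
#' seven-segment geometry and four inlet waveforms, and derives
#' ultrasound-like records for RCIV, LCIV and IVC from the ground-truth
#' flows and areas with multiplicative measurement noise. The result is
#' fully deterministic in `(config, seed)`.
#'
#' The LCIV record is taken at the stenosis throat (where a sonographer
#' would interrogate a compression); the RCIV and IVC records at
#' mid-vessel.
#'
#' @param config a [patient_config()].
#' @param seed integer seed.
#' @param id optional patient label.
#' @return An object of class `virtual_patient` with fields `id`, `group`,
#'   `segments`, `inflows`, `us_records`, `seed`, `severity`, `period`
#'   and `config`.
#' @export
make_virtual_patient <- function(config, seed, id = NULL) {
  stopifnot(inherits(config, "patient_config"))
  .with_seed(seed, {
    severity <- stats::runif(1, config$severity_range[1],
                             config$severity_range[2])
    if (config$group == "Control") severity <- 0
    period <- stats::runif(1, config$period_range[1], config$period_range[2])
    scales <- stats::runif(2, config$flow_scale_range[1],
                           config$flow_scale_range[2])
    leg <- config$leg_mean_flows * scales   # right, left (L/min)

    sten <- stenosis_spec(severity, config$stenosis_center,
                          config$stenosis_length)
    segments <- generate_geometry(config$baseline_areas, config$lengths, sten)

    f_iiv <- config$iiv_fraction
    mk <- function(flow) generate_waveform(flow, period, config$phasicity,
                                           config$n_waveform_samples)
    inflows <- list(REIV = mk(leg[["right"]] * (1 - f_iiv)),
                    RIIV = mk(leg[["right"]] * f_iiv),
                    LEIV = mk(leg[["left"]] * (1 - f_iiv)),
                    LIIV = mk(leg[["left"]] * f_iiv))

    area_at <- function(seg, z) {
      stats::approx(seg$arclength_grid, seg$area_profile, z, rule = 2)$y
    }
    us_for <- function(name, q_lmin, z) {
      a_true <- area_at(segments[[name]], z)
      v_true <- lmin_to_mm3s(q_lmin) / a_true
      ultrasound_record(name,
                        apply_measurement_noise(v_true, config$noise_cv),
                        apply_measurement_noise(a_true, config$noise_cv),
                        z)
    }
    z_lciv <- if (severity > 0) config$stenosis_center
              else config$lengths[["LCIV"]] / 2
    us_records <- list(
      RCIV = us_for("RCIV", leg[["right"]], config$lengths[["RCIV"]] / 2),
      LCIV = us_for("LCIV", leg[["left"]], z_lciv),
      IVC = us_for("IVC", sum(leg), config$lengths[["IVC"]] / 2))

    structure(list(id = id %||% sprintf("%s-%d", config$group, seed),
                   group = config$group, segments = segments,
                   inflows = inflows, us_records = us_records,
                   seed = as.integer(seed), severity = severity,
                   period = period, config = config),
              class = "virtual_patient")
  })
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("Virtual patient %s (%s), seed %d\n", x$id, x$group, x$seed))
  cat(sprintf("  respiratory period %.2f s, LCIV stenosis severity %.2f\n",
              x$period, x$severity))
  ql <- mm3s_to_lmin(vapply(x$inflows, waveform_mean_flow, numeric(1)))
  cat(sprintf("  inlet mean flows (L/min): %s\n",
              paste(sprintf("%s=%.3f", names(ql), ql), collapse = ", ")))
  invisible(x)
}

#' Generate a cohort of virtual patients
#'
#' Derives one deterministic seed per patient from `master_seed` and calls
#' [make_virtual_patient()]; two calls with the same template and master
#' seed produce identical cohorts.
#'
#' @param template a [patient_config()].
#' @param n number of patients (>= 1).
#' @param master_seed integer master seed.
#' @return List of `virtual_patient`s.
#' @export
make_cohort <- function(template, n, master_seed) {
  if (n < 1) stop("invalid-parameter error: n must be >= 1", call. = FALSE)
  seeds <- as.integer(master_seed) + 1000L * seq_len(n)
  lapply(seq_len(n), function(i) {
    make_virtual_patient(template, seeds[i],
                         id = sprintf("%s-%d", template$group, i))
  })
}

#' Write a virtual patient to a plain-text bundle
#'
#' Writes `geometry.csv` (columns segment, z_mm, area_mm2,
#' origin_distance_mm), one `inflow_<name>.csv` per inlet (columns t_s,
#' q_mm3_s, with the period in a `#` header line), and a versioned JSON
#' manifest carrying the ultrasound records and seed.
#'
#' @param patient a `virtual_patient`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_patient_bundle <- function(patient, dir) {
  stopifnot(inherits(patient, "virtual_patient"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geo <- do.call(rbind, lapply(patient$segments, function(s) {
    data.frame(segment = s$name, z_mm = s$arclength_grid,
               area_mm2 = s$area_profile,
               origin_distance_mm = s$origin_distance)
  }))
  utils::write.csv(geo, file.path(dir, "geometry.csv"), row.names = FALSE)
  inflow_files <- list()
  for (nm in names(patient$inflows)) {
    wf <- patient$inflows[[nm]]
    f <- sprintf("inflow_%s.csv", nm)
    con <- file(file.path(dir, f), "w")
    writeLines(sprintf("# period_s=%.17g", wf$period), con)
    utils::write.csv(data.frame(t_s = wf$times, q_mm3_s = wf$flows), con,
                     row.names = FALSE)
    close(con)
    inflow_files[[nm]] <- f
  }
  manifest <- list(
    schema_version = "1.0", id = patient$id, group = patient$group,
    seed = patient$seed, severity = patient$severity,
    period = patient$period, geometry = "geometry.csv",
    inflows = inflow_files,
    us_records = lapply(patient$us_records, function(r) {
      list(vessel = r$vessel, mean_velocity = r$mean_velocity,
           mean_area = r$mean_area, slice_position = r$slice_position,
           mean_flow = r$mean_flow)
    }),
    capacitance = patient$config$capacitance)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a virtual patient bundle
#'
#' Reconstructs a `virtual_patient` written by [write_patient_bundle()].
#' The configuration object is not serialized; the returned patient
#' carries a minimal config with the bundled compliance.
#'
#' @param dir bundle directory.
#' @return A `virtual_patient`.
#' @export
read_patient_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  geo <- utils::read.csv(file.path(dir, "geometry.csv"))
  segments <- lapply(split(geo, geo$segment), function(d) {
    vessel_segment(d$segment[1], d$z_mm, d$area_mm2, d$origin_distance_mm[1])
  })[.SEGMENT_NAMES]
  inflows <- lapply(manifest$inflows, function(f) {
    hdr <- readLines(file.path(dir, f), n = 1L)
    period <- as.numeric(sub("# period_s=", "", hdr, fixed = TRUE))
    d <- utils::read.csv(file.path(dir, f), comment.char = "#")
    flow_waveform(d$t_s, d$q_mm3_s, period)
  })
  us_records <- lapply(manifest$us_records, function(r) {
    ultrasound_record(r$vessel, r$mean_velocity, r$mean_area,
                      r$slice_position, r$mean_flow)
  })
  structure(list(id = manifest$id, group = manifest$group,
                 segments = segments, inflows = inflows,
                 us_records = us_records, seed = manifest$seed,
                 severity = manifest$severity, period = manifest$period,
                 config = list(capacitance = manifest$capacitance)),
            class = "virtual_patient")
}
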