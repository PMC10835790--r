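# Control-volume definitions and shear-rate summary metrics: the stenotic
# LCIV extent, the volume-matched contralateral RCIV region, and the
# mean / Q1 / Q3 / mean-peak / LCIV-RCIV-ratio statistics.

#' Control volume
#'
#' An axial evaluation region of a vessel: arclength bounds, the enclosed
#' volume \eqn{\int A\,dz}, and the distance of the region start from the
#' iliac confluence (so regions are positionally comparable between the
#' left and right common iliac veins).
#'
#' @param segment vessel name.
#' @param z_start,z_end arclength bounds, mm, `z_end > z_start`.
#' @param volume enclosed volume, mm^3.
#' @param start_distance distance of `z_start` from the iliac confluence,
#'   mm.
#' @return An object of class `control_volume`.
#' @export
control_volume <- function(segment, z_start, z_end, volume, start_distance) {
  segment <- match.arg(segment, .SEGMENT_NAMES)
  if (z_end <= z_start) stop("z_end must exceed z_start", call. = FALSE)
  .assert_scalar_number(volume, "volume", positive = TRUE)
  structure(list(segment = segment, z_start = z_start, z_end = z_end,
                 volume = volume, start_distance = start_distance),
            class = "control_volume")
}

#' @export
print.control_volume <- function(x, ...) {
  cat(sprintf("Control volume in %s: z = [%.2f, %.2f] mm, volume %.1f mm^3",
              x$segment, x$z_start, x$z_end, x$volume),
      sprintf("(start %.2f mm from confluence)\n", x$start_distance))
  invisible(x)
}

# Linear-interpolated area function of a segment.
.area_fun <- function(seg) {
  stats::approxfun(seg$arclength_grid, seg$area_profile, rule = 2)
}

# Volume of a segment between two arclengths (trapezoid on the station
# grid refined with the exact interpolated endpoints).
.segment_volume <- function(seg, z1, z2) {
  af <- .area_fun(seg)
  zz <- sort(unique(c(z1, z2,
                      seg$arclength_grid[seg$arclength_grid > z1 &
                                         seg$arclength_grid < z2])))
  pracma::trapz(zz, af(zz))
}

# Build a control volume on `seg` from bounds.
.cv_from_bounds <- function(seg, z1, z2) {
  control_volume(seg$name, z1, z2, .segment_volume(seg, z1, z2),
                 seg$origin_distance + z1)
}

#' Detect the stenotic extent of a compressed vessel
#'
#' Operationalizes the rule that the stenotic control volume is the region
#' where the lumen is smaller than 90% of the uncompressed proximal and
#' distal luminal areas. Each reference area is the uncompressed lumen
#' read just outside the candidate region: the maximum area over a flank
#' window of width `flank_window` (iterated to a fixed point, so the
#' windows sit immediately outside the detected run). The extent is the
#' maximal contiguous run of stations with
#' `A < threshold * min(ref_prox, ref_dist)` (the conservative both-sided
#' rule), with the exact bounds linearly interpolated between stations.
#'
#' @param lciv a [vessel_segment()] (typically the LCIV).
#' @param threshold area fraction defining "compressed" (default 0.9).
#' @param flank_window reference-window width, mm (default 5).
#' @return A [control_volume()], or `NULL` when no station falls below
#'   the threshold (an uncompressed, Control-type vessel).
#' @export
detect_stenosis_extent <- function(lciv, threshold = 0.9, flank_window = 5) {
  stopifnot(inherits(lciv, "vessel_segment"))
  z <- lciv$arclength_grid
  a <- lciv$area_profile
  n <- length(z)
  if (n < 3L) stop("segment must have >= 3 stations", call. = FALSE)

  window_ref <- function(lo, hi) {
    sel <- z >= lo & z <= hi
    if (!any(sel)) return(NA_real_)
    max(a[sel])
  }
  ref_for <- function(run) {
    # flank windows just outside [z[run1], z[runN]]
    zp <- if (is.null(run)) c(z[1], z[1] + flank_window)
          else c(max(z[1], z[run[1]] - flank_window), z[run[1]])
    zd <- if (is.null(run)) c(z[n] - flank_window, z[n])
          else c(z[run[length(run)]], min(z[n], z[run[length(run)]] +
                                            flank_window))
    rp <- window_ref(zp[1], zp[2])
    rd <- window_ref(zd[1], zd[2])
    min(rp, rd, na.rm = TRUE)
  }

  run <- NULL
  for (iter in 1:5) {
    cutoff <- threshold * ref_for(run)
    below <- a < cutoff
    if (!any(below)) return(NULL)
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- Map(seq, starts[r$values], ends[r$values])
    if (length(runs) > 1L) {
      desc <- paste(vapply(runs, function(rr)
        sprintf("[%.1f, %.1f] mm", z[rr[1]], z[rr[length(rr)]]),
        character(1)), collapse = ", ")
      stop("ambiguity error: multiple disjoint sub-threshold runs: ", desc,
           call. = FALSE)
    }
    new_run <- runs[[1]]
    if (identical(new_run, run)) break
    run <- new_run
  }

  i1 <- run[1]
  i2 <- run[length(run)]
  # interpolate the exact threshold crossings just outside the run
  z_lo <- if (i1 > 1L) {
    stats::approx(a[c(i1 - 1L, i1)], z[c(i1 - 1L, i1)], xout = cutoff)$y
  } else z[1]
  z_hi <- if (i2 < n) {
    stats::approx(a[c(i2, i2 + 1L)], z[c(i2, i2 + 1L)], xout = cutoff)$y
  } else z[n]
  .cv_from_bounds(lciv, z_lo, z_hi)
}

# Solve z_end on `seg` so the volume from z_start equals `target`.
.cv_with_volume <- function(seg, start_distance, target_volume) {
  z_start <- start_distance - seg$origin_distance
  z <- seg$arclength_grid
  if (z_start < z[1] - 1e-9 || z_start >= z[length(z)])
    stop("geometry error: requested start lies outside the vessel",
         call. = FALSE)
  total <- .segment_volume(seg, z_start, z[length(z)])
  if (target_volume > total * (1 + 1e-9))
    stop(sprintf(paste0("geometry error: vessel too short to fit the ",
                        "required volume (shortfall %.1f mm^3)"),
                 target_volume - total), call. = FALSE)
  f <- function(ze) .segment_volume(seg, z_start, ze) - target_volume
  z_end <- stats::uniroot(f, lower = z_start + 1e-9, upper = z[length(z)],
                          tol = 1e-10 * (z[length(z)] - z_start))$root
  .cv_from_bounds(seg, z_start, z_end)
}

#' Volume-matched contralateral control volume
#'
#' Builds the RCIV control volume paired to a stenotic LCIV control
#' volume: it starts at the same distance from the iliac confluence and
#' encloses an identical volume, with the downstream bound found by
#' monotone root-finding on the cumulative volume.
#'
#' @param lciv_cv the LCIV [control_volume()].
#' @param rciv the RCIV [vessel_segment()].
#' @return A [control_volume()] on the RCIV.
#' @export
matched_contralateral_cv <- function(lciv_cv, rciv) {
  stopifnot(inherits(lciv_cv, "control_volume"),
            inherits(rciv, "vessel_segment"))
  .cv_with_volume(rciv, lciv_cv$start_distance, lciv_cv$volume)
}

#' Control-group control volume from the subject-group average
#'
#' For uncompressed vessels the evaluation region is placed at the mean
#' start distance of the supplied subject control volumes and sized to
#' their mean volume.
#'
#' @param subject_cvs list of subject [control_volume()]s (>= 1).
#' @param vessel the [vessel_segment()] on which to place the region.
#' @return A [control_volume()].
#' @export
control_volume_for_control_group <- function(subject_cvs, vessel) {
  if (length(subject_cvs) < 1L)
    stop("need at least one subject control volume", call. = FALSE)
  start <- mean(vapply(subject_cvs, function(cv) cv$start_distance,
                       numeric(1)))
  vol <- mean(vapply(subject_cvs, function(cv) cv$volume, numeric(1)))
  .cv_with_volume(vessel, start, vol)
}

# Weighted quantile on the empirical weighted CDF with linear
# interpolation between order statistics.
.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  f <- (cw - w / 2) / cw[length(cw)]
  stats::approx(f, x, xout = probs, rule = 2, ties = "ordered")$y
}

# Station axial weights clipped to [z1, z2]: each station owns the
# midpoint cell around it; weights sum exactly to z2 - z1.
.clipped_cell_weights <- function(z, z1, z2) {
  n <- length(z)
  edges <- c(z[1], (z[-n] + z[-1]) / 2, z[n])
  lo <- pmax(edges[-(n + 1L)], z1)
  hi <- pmin(edges[-1L], z2)
  pmax(hi - lo, 0)
}

#' Control-volume shear-rate metrics
#'
#' At each stored time the radial shear-rate profiles of all stations
#' inside the control volume are pooled into a volume-weighted
#' distribution (annular weights \eqn{2\pi r\,\Delta r\,\Delta z}); its
#' volume-weighted mean and quartiles are computed per time and averaged
#' over the respiratory cycle. The mean-peak shear rate is the maximum
#' over the cycle of the volume-weighted mean. The record also carries
#' the vessel-average cross-sectional area (the clinical mean area
#' between bifurcations) and the time-mean flow.
#'
#' @param solution a `network_solution` from [simulate_patient()].
#' @param cv a [control_volume()] covered by the stored stations.
#' @param weighting `"volume"` (default) or `"count"` (unweighted nodes;
#'   provided for sensitivity analysis).
#' @return An object of class `metrics_record` with fields `mean_shear`,
#'   `q1_shear`, `q3_shear`, `mean_peak_shear` (1/s), `mean_area` (mm^2),
#'   `mean_flow` (L/min), `vessel`, and the spatial-mean time series
#'   `mean_series`.
#' @export
cv_shear_metrics <- function(solution, cv,
                             weighting = c("volume", "count")) {
  stopifnot(inherits(solution, "network_solution"),
            inherits(cv, "control_volume"))
  weighting <- match.arg(weighting)
  seg <- solution$segments[[cv$segment]]
  if (is.null(seg))
    stop("coverage error: solution does not store segment ", cv$segment,
         call. = FALSE)
  z <- seg$z
  if (cv$z_start < z[1] - 1e-9 || cv$z_end > z[length(z)] + 1e-9)
    stop("coverage error: control volume outside stored stations",
         call. = FALSE)
  wz <- .clipped_cell_weights(z, cv$z_start, cv$z_end)
  idx <- which(wz > 0)
  xi <- seg$xi
  n_r <- length(xi)
  # normalized radial weights: 2 xi dxi (trapezoid), summing to 1 exactly
  wxi <- 2 * xi * .trapz_weights(xi)
  # node weights per (station, node): A_k * wz_k * wxi_j
  wnode <- outer(seg$area[idx] * wz[idx], wxi)
  if (weighting == "count") wnode[] <- 1
  wvec <- as.vector(wnode)

  n_t <- length(solution$times)
  m_t <- numeric(n_t)
  q1_t <- numeric(n_t)
  q3_t <- numeric(n_t)
  for (ti in seq_len(n_t)) {
    vals <- as.vector(seg$gamma[ti, idx, , drop = FALSE])
    m_t[ti] <- sum(wvec * vals) / sum(wvec)
    qq <- .weighted_quantile(vals, wvec, c(0.25, 0.75))
    q1_t[ti] <- qq[1]
    q3_t[ti] <- qq[2]
  }
  structure(list(vessel = cv$segment,
                 mean_shear = mean(m_t),
                 q1_shear = mean(q1_t),
                 q3_shear = mean(q3_t),
                 mean_peak_shear = max(m_t),
                 mean_area = mean(seg$area),
                 mean_flow = mm3s_to_lmin(mean(seg$q)),
                 mean_series = m_t,
                 weight_total = sum(wnode),
                 cv_volume = cv$volume),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("%s shear metrics: mean %.1f, Q1 %.1f, Q3 %.1f, mean-peak %.1f 1/s\n",
              x$vessel, x$mean_shear, x$q1_shear, x$q3_shear,
              x$mean_peak_shear))
  cat(sprintf("  mean area %.1f mm^2, mean flow %.3f L/min\n",
              x$mean_area, x$mean_flow))
  invisible(x)
}

#' LCIV/RCIV shear-rate ratio series
#'
#' Pointwise-in-time ratio of the volume-weighted mean shear rates of the
#' LCIV and RCIV control volumes over one normalized respiratory cycle,
#' plus its time mean (the patient-level shear-rate ratio).
#'
#' @param solution a `network_solution`.
#' @param lciv_cv,rciv_cv the paired [control_volume()]s.
#' @return An object of class `shear_ratio_series` with
#'   `normalized_time`, `ratio` and `mean_ratio`.
#' @export
ratio_series <- function(solution, lciv_cv, rciv_cv) {
  ml <- cv_shear_metrics(solution, lciv_cv)$mean_series
  mr <- cv_shear_metrics(solution, rciv_cv)$mean_series
  if (any(mr <= 0))
    stop("division guard error: RCIV mean shear rate is zero within the ",
         "cycle", call. = FALSE)
  r <- ml / mr
  structure(list(normalized_time = solution$times / solution$period,
                 ratio = r, mean_ratio = mean(r)),
            class = "shear_ratio_series")
}

#' @export
print.shear_ratio_series <- function(x, ...) {
  cat(sprintf("LCIV/RCIV shear-rate ratio: mean %.2f (range %.2f-%.2f)\n",
              x$mean_ratio, min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' @export
plot.shear_ratio_series <- function(x, ...) {
  graphics::plot(x$normalized_time, x$ratio, type = "l",
                 xlab = "normalized respiratory cycle",
                 ylab = "LCIV/RCIV shear-rate ratio", ...)
  graphics::abline(h = x$mean_ratio, lty = 2)
  invisible(x)
}

#' Export per-patient metrics to CSV
#'
#' One row per (patient, vessel) with the [cv_shear_metrics()] fields.
#'
#' @param records data frame of long-format records (as produced by
#'   [run_case_control_analysis()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
export_metrics_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
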