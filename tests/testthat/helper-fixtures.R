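# Shared test fixtures: small deterministic configurations and reduced
# solver options that keep unit tests fast without changing the physics.

# Reduced-resolution options for tests that only need qualitative fields.
fast_options <- function(...) {
  sim_options(n_store = 8L, dt = 0.02, n_cycles = 2L, ...)
}

# A mirror-symmetric uncompressed patient: equal legs, equal common iliac
# areas, no noise.
symmetric_config <- function(...) {
  control_template(leg_mean_flows = c(right = 0.8, left = 0.8),
                   baseline_areas = c(IVC = 280, RCIV = 130, LCIV = 130,
                                      REIV = 110, LEIV = 110, RIIV = 60,
                                      LIIV = 60),
                   period_range = c(3.2, 3.2),
                   flow_scale_range = c(1, 1), noise_cv = 0, ...)
}

# A steady (zero-phasicity), noise-free symmetric patient, for closed-form
# Poiseuille checks.
steady_config <- function(...) {
  symmetric_config(phasicity = 0, ...)
}

# A fixed-severity subject with sampling disabled.
fixed_subject_config <- function(severity, ...) {
  subject_template(severity_range = c(severity, severity),
                   period_range = c(3.2, 3.2),
                   flow_scale_range = c(1, 1), noise_cv = 0, ...)
}

# Independent trapezoid integrator (oracle for waveform means).
trapz_mean <- function(times, values, period) {
  pracma::trapz(c(times, period), c(values, values[1])) / period
}
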