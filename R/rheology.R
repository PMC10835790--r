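# Carreau-Yasuda rheology and the scalar shear-rate measure
# gamma = sqrt(2 D:D), D = (grad u + grad u^T)/2.

#' Carreau-Yasuda rheology parameters
#'
#' Container for the five constants of the Carreau-Yasuda shear-thinning
#' viscosity law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'   \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}.}
#' The defaults are the whole-blood constants used throughout the package:
#' \eqn{\mu_\infty = 0.0035} Pa s, \eqn{\mu_0 = 0.16} Pa s,
#' \eqn{n = 0.2128}, \eqn{a = 0.64}, \eqn{\lambda = 8.2} s.
#'
#' On construction the implied shear stress \eqn{\tau(\dot\gamma) =
#' \mu(\dot\gamma)\dot\gamma} is checked for strict monotonicity on a dense
#' logarithmic grid up to 1e6 1/s; a parameter set with non-monotone stress
#' would make the profile solver ill-posed and is rejected.
#'
#' @param mu_inf infinite-shear viscosity, Pa s.
#' @param mu_0 zero-shear viscosity, Pa s; must satisfy `mu_0 >= mu_inf`.
#' @param n power index, dimensionless, in (0, 1].
#' @param a Yasuda transition parameter, dimensionless, > 0.
#' @param lam time constant \eqn{\lambda}, s, > 0.
#' @return An object of class `rheology_params`.
#' @seealso [carreau_yasuda_viscosity()], [shear_stress()], [newtonian_params()]
#' @export
rheology_params <- function(mu_inf = 0.0035, mu_0 = 0.16, n = 0.2128,
                            a = 0.64, lam = 8.2) {
  .assert_scalar_number(mu_inf, "mu_inf", positive = TRUE)
  .assert_scalar_number(mu_0, "mu_0", positive = TRUE)
  .assert_scalar_number(n, "n")
  .assert_scalar_number(a, "a", positive = TRUE)
  .assert_scalar_number(lam, "lam", positive = TRUE)
  if (mu_0 < mu_inf) stop("mu_0 must be >= mu_inf", call. = FALSE)
  if (n <= 0 || n > 1) stop("power index n must lie in (0, 1]", call. = FALSE)
  p <- structure(list(mu_inf = mu_inf, mu_0 = mu_0, n = n, a = a, lam = lam),
                 class = "rheology_params")
  g <- c(0, 10^seq(-6, 6, length.out = 400))
  tau <- carreau_yasuda_viscosity(g, p) * g
  if (any(diff(tau) <= 0))
    stop("constitutive-model error: shear stress is not strictly increasing ",
         "on [0, 1e6] 1/s for these parameters", call. = FALSE)
  p
}

#' Newtonian degenerate parameter set
#'
#' Convenience constructor for a constant-viscosity fluid expressed in the
#' Carreau-Yasuda container (`mu_0 = mu_inf = mu`). Useful for validating
#' the solver against closed-form Poiseuille results.
#'
#' @param mu constant viscosity, Pa s.
#' @return An object of class `rheology_params`.
#' @export
newtonian_params <- function(mu = 0.0035) {
  rheology_params(mu_inf = mu, mu_0 = mu, n = 1, a = 2, lam = 1)
}

#' @export
print.rheology_params <- function(x, ...) {
  cat("Carreau-Yasuda rheology parameters\n")
  cat(sprintf("  mu_inf = %g Pa s, mu_0 = %g Pa s, n = %g, a = %g, lambda = %g s\n",
              x$mu_inf, x$mu_0, x$n, x$a, x$lam))
  invisible(x)
}

#' Carreau-Yasuda viscosity
#'
#' Evaluates \eqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#' [1 + (\lambda\dot\gamma)^a]^{(n-1)/a}}. The function is vectorized in
#' `gamma_dot`, monotone non-increasing, and bounded by
#' \eqn{[\mu_\infty, \mu_0]}; at zero shear it returns \eqn{\mu_0} exactly.
#'
#' @param gamma_dot shear rate(s), 1/s, >= 0.
#' @param params a [rheology_params()] object.
#' @return Viscosity in Pa s, same length as `gamma_dot`.
#' @export
carreau_yasuda_viscosity <- function(gamma_dot, params = rheology_params()) {
  if (!is.numeric(gamma_dot) || any(!is.finite(gamma_dot)))
    stop("gamma_dot must be finite numeric", call. = FALSE)
  if (any(gamma_dot < 0))
    stop("gamma_dot must be >= 0", call. = FALSE)
  params$mu_inf + (params$mu_0 - params$mu_inf) *
    (1 + (params$lam * gamma_dot)^params$a)^((params$n - 1) / params$a)
}

#' Shear stress under the Carreau-Yasuda law
#'
#' \eqn{\tau(\dot\gamma) = \mu(\dot\gamma)\,\dot\gamma}. Monotonicity of
#' \eqn{\tau} is guaranteed for parameter sets accepted by
#' [rheology_params()], which verifies it at construction.
#'
#' @inheritParams carreau_yasuda_viscosity
#' @return Shear stress in Pa, same length as `gamma_dot`.
#' @export
shear_stress <- function(gamma_dot, params = rheology_params()) {
  carreau_yasuda_viscosity(gamma_dot, params) * gamma_dot
}

#' Scalar shear rate of a velocity-gradient tensor
#'
#' Computes the rate-of-deformation tensor \eqn{D = (\nabla u +
#' \nabla u^T)/2} and returns \eqn{\dot\gamma = \sqrt{2\,D\!:\!D}}, the
#' frame-indifferent scalar shear rate used as an index of platelet
#' mechanical activation. Rigid-rotation (antisymmetric) input gives 0.
#'
#' @param velocity_gradient a 3x3 numeric matrix of velocity derivatives,
#'   entry (i, j) holding \eqn{\partial u_i/\partial x_j}, 1/s.
#' @return Scalar shear rate, 1/s.
#' @export
shear_rate_scalar <- function(velocity_gradient) {
  g <- velocity_gradient
  if (!is.matrix(g) || !all(dim(g) == c(3L, 3L)) || any(!is.finite(g)))
    stop("velocity_gradient must be a finite 3x3 matrix", call. = FALSE)
  d <- (g + t(g)) / 2
  sqrt(2 * sum(d * d))
}

#' Rectilinear velocity grid
#'
#' Bundles the three velocity components sampled on a uniform rectilinear
#' 3D grid. All components must share one shape with at least 3 nodes per
#' axis for derivative evaluation.
#'
#' @param u,v,w numeric 3D arrays of identical dimension, mm/s.
#' @param spacing grid step, mm; a scalar or a length-3 vector (per axis).
#' @return An object of class `velocity_grid`.
#' @export
velocity_grid <- function(u, v, w, spacing) {
  if (!is.array(u) || length(dim(u)) != 3L)
    stop("u, v, w must be 3D arrays", call. = FALSE)
  if (!identical(dim(u), dim(v)) || !identical(dim(u), dim(w)))
    stop("u, v, w must share one shape", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive (scalar or length 3)", call. = FALSE)
  structure(list(u = u, v = v, w = w, spacing = spacing),
            class = "velocity_grid")
}

# Partial derivative of a 3D array along one axis: second-order central
# differences in the interior, first-order one-sided at the boundary faces.
.array_grad <- function(a, axis, h) {
  n <- dim(a)[axis]
  if (n < 3L) stop("grid-too-small error: need >= 3 nodes per axis", call. = FALSE)
  idx <- function(i) {
    args <- list(a, TRUE, TRUE, TRUE)
    args[[axis + 1L]] <- i
    do.call(`[`, c(args, list(drop = FALSE)))
  }
  out <- array(0, dim(a))
  asg <- function(i, val) {
    args <- list(TRUE, TRUE, TRUE)
    args[[axis]] <- i
    do.call(`[<-`, c(list(out), args, list(value = val)))
  }
  out <- asg(2:(n - 1L), (idx(3:n) - idx(1:(n - 2L))) / (2 * h))
  out <- asg(1L, (idx(2L) - idx(1L)) / h)
  out <- asg(n, (idx(n) - idx(n - 1L)) / h)
  out
}

#' Shear-rate field of a gridded velocity field
#'
#' Applies [shear_rate_scalar()] node-wise: velocity gradients are formed
#' with central differences in the interior and one-sided differences at
#' the boundary, then \eqn{\dot\gamma = \sqrt{2 D\!:\!D}} is evaluated at
#' every node.
#'
#' @param grid a [velocity_grid()].
#' @return An object of class `scalar_field` with elements `values`
#'   (3D array of shear rates, 1/s) and `spacing` (mm).
#' @export
shear_rate_field <- function(grid) {
  stopifnot(inherits(grid, "velocity_grid"))
  h <- grid$spacing
  ux <- .array_grad(grid$u, 1L, h[1]); uy <- .array_grad(grid$u, 2L, h[2])
  uz <- .array_grad(grid$u, 3L, h[3])
  vx <- .array_grad(grid$v, 1L, h[1]); vy <- .array_grad(grid$v, 2L, h[2])
  vz <- .array_grad(grid$v, 3L, h[3])
  wx <- .array_grad(grid$w, 1L, h[1]); wy <- .array_grad(grid$w, 2L, h[2])
  wz <- .array_grad(grid$w, 3L, h[3])
  g2 <- 2 * (ux^2 + vy^2 + wz^2) + (uy + vx)^2 + (uz + wx)^2 + (vz + wy)^2
  structure(list(values = sqrt(g2), spacing = h), class = "scalar_field")
}

#' Read a velocity grid from CSV
#'
#' Expects columns `x, y, z, u, v, w` on a complete uniform rectilinear
#' grid (any row order). Coordinates in mm, velocities in mm/s.
#'
#' @param path CSV file path.
#' @return A [velocity_grid()].
#' @export
read_velocity_grid <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x", "y", "z", "u", "v", "w")
  if (!all(need %in% names(d)))
    stop("velocity grid CSV must have columns x,y,z,u,v,w", call. = FALSE)
  xs <- sort(unique(d$x)); ys <- sort(unique(d$y)); zs <- sort(unique(d$z))
  dims <- c(length(xs), length(ys), length(zs))
  if (nrow(d) != prod(dims))
    stop("CSV does not describe a complete rectilinear grid", call. = FALSE)
  sp <- c(mean(diff(xs)), mean(diff(ys)), mean(diff(zs)))
  o <- order(match(d$z, zs), match(d$y, ys), match(d$x, xs))
  mk <- function(col) array(d[[col]][o], dims)
  velocity_grid(mk("u"), mk("v"), mk("w"), sp)
}

#' Write a scalar field to CSV
#'
#' Writes columns `x, y, z, value` for a [shear_rate_field()] result,
#' with coordinates reconstructed from the grid spacing (origin at 0).
#'
#' @param field a `scalar_field`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_scalar_field <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  dm <- dim(field$values)
  co <- expand.grid(x = (seq_len(dm[1]) - 1) * field$spacing[1],
                    y = (seq_len(dm[2]) - 1) * field$spacing[2],
                    z = (seq_len(dm[3]) - 1) * field$spacing[3])
  co$value <- as.vector(field$values)
  utils::write.csv(co, path, row.names = FALSE)
  invisible(path)
}
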