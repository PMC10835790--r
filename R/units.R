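# Internal unit system: mm-g-s. Lengths in mm, areas in mm^2, flows in
# mm^3/s, shear rates in 1/s. In this system the derived pressure unit is
# the Pascal, so pressures are carried in Pa throughout.

#' Unit conversions for the mm-g-s system
#'
#' The solver works in millimetre-gram-second units, in which pressure is
#' expressed directly in pascal. Clinical quantities are usually reported
#' in L/min (flow) and mmHg (pressure); these helpers convert between the
#' two conventions.
#'
#' @param x numeric vector of values to convert.
#' @return Numeric vector of converted values.
#' @examples
#' lmin_to_mm3s(1)      # 16666.67 mm^3/s
#' pa_to_mmhg(1333.22)  # ~10 mmHg
#' @name units
NULL

# 1 L/min in mm^3/s (1e6 mm^3 per litre, 60 s per minute)
.LMIN_TO_MM3S <- 1e6 / 60

# 1 mmHg in Pa
.MMHG_TO_PA <- 133.322

#' @rdname units
#' @export
lmin_to_mm3s <- function(x) x * .LMIN_TO_MM3S

#' @rdname units
#' @export
mm3s_to_lmin <- function(x) x / .LMIN_TO_MM3S

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * .MMHG_TO_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / .MMHG_TO_PA

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Evaluate a function with a temporary RNG state seeded by `seed`, restoring
# the caller's RNG stream afterwards so generators are reproducible without
# clobbering the session.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Composite trapezoid weights for an arbitrary strictly increasing grid.
.trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("grid must have at least 2 points")
  dx <- diff(x)
  c(dx / 2, 0) + c(0, dx / 2)
}

# Composite Simpson weights on a uniform grid with an odd number of points.
.simpson_weights <- function(n, h) {
  stopifnot(n >= 3L, n %% 2L == 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}
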