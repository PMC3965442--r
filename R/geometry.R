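#' Axisymmetric conduit geometry
#'
#' An axisymmetric conduit is described by its wall radius \eqn{R(z)} as a
#' piecewise function of the axial coordinate: an ordered set of contiguous
#' segments, each either of constant radius or a linear cone. A sudden
#' expansion (or contraction) is represented as a radius jump between two
#' adjacent segments; by convention [radius_at()] returns the downstream
#' value at the jump location.
#'
#' @param segments a `data.frame` with columns `z_start`, `z_end` (m),
#'   `kind` (`"constant"` or `"cone"`), `R_start`, `R_end` (m). Segments must
#'   be contiguous (`z_end[i] == z_start[i+1]`), non-overlapping and have
#'   strictly positive radii. A `"constant"` segment must have
#'   `R_start == R_end`.
#' @return An object of class `nozzle_geometry` with elements `segments`,
#'   `z_min`, `z_max`, `r_max`.
#' @examples
#' tube <- straight_tube(radius = 0.002, length = 0.04)
#' radius_at(tube, 0.01)
#' @export
nozzle_geometry <- function(segments) {
  req <- c("z_start", "z_end", "kind", "R_start", "R_end")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("`segments` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  segments <- segments[order(segments$z_start), req, drop = FALSE]
  n <- nrow(segments)
  if (n < 1L) stop("geometry needs at least one segment")
  if (!all(segments$kind %in% c("constant", "cone")))
    stop("segment kind must be 'constant' or 'cone'")
  if (any(segments$z_end <= segments$z_start))
    stop("every segment needs z_end > z_start")
  if (n > 1L && any(abs(segments$z_end[-n] - segments$z_start[-1]) > 1e-12))
    stop("segments must be contiguous: z_end[i] == z_start[i+1]")
  if (any(segments$R_start <= 0) || any(segments$R_end <= 0))
    stop("all radii must be strictly positive")
  const <- segments$kind == "constant"
  if (any(abs(segments$R_start[const] - segments$R_end[const]) > 1e-12))
    stop("'constant' segments must have R_start == R_end")
  structure(
    list(segments = segments,
         z_min = segments$z_start[1L],
         z_max = segments$z_end[n],
         r_max = max(segments$R_start, segments$R_end)),
    class = "nozzle_geometry")
}

#' @export
print.nozzle_geometry <- function(x, ...) {
  cat(sprintf("<nozzle_geometry> %d segment(s), z in [%g, %g] m, max radius %g m\n",
              nrow(x$segments), x$z_min, x$z_max, x$r_max))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Straight tube geometry
#'
#' @param radius tube radius (m)
#' @param length tube length (m)
#' @param z_start axial position of the inlet (m)
#' @return a [nozzle_geometry()]
#' @export
straight_tube <- function(radius, length, z_start = 0) {
  nozzle_geometry(data.frame(
    z_start = z_start, z_end = z_start + length,
    kind = "constant", R_start = radius, R_end = radius))
}

#' Stepped tube geometry (sudden expansion)
#'
#' Two constant-radius sections joined by a sudden radius jump, the minimal
#' geometry exercising the downstream-value convention of [radius_at()].
#'
#' @param r1,r2 radii of the upstream and downstream sections (m)
#' @param l1,l2 lengths of the two sections (m)
#' @param z_start axial position of the inlet (m)
#' @return a [nozzle_geometry()]
#' @export
stepped_tube <- function(r1, r2, l1, l2, z_start = 0) {
  nozzle_geometry(data.frame(
    z_start = c(z_start, z_start + l1),
    z_end   = c(z_start + l1, z_start + l1 + l2),
    kind    = "constant",
    R_start = c(r1, r2), R_end = c(r1, r2)))
}

#' FDA benchmark nozzle geometry
#'
#' The idealized nozzle of the FDA computational interlaboratory benchmark:
#' a 12 mm diameter inlet tube, a 20-degree (full angle) conical collector
#' converging to a 4 mm diameter throat of 40 mm length, and a sudden
#' expansion back to 12 mm diameter. The axial origin `z = 0` is placed at
#' the sudden expansion, following the benchmark convention.
#'
#' @param z_inlet axial position of the upstream end of the computational
#'   domain (m); must leave room for the inlet tube (default -0.1).
#' @param z_outlet axial position of the downstream end (m), default 0.08.
#' @return a [nozzle_geometry()]
#' @export
fda_nozzle <- function(z_inlet = -0.1, z_outlet = 0.08) {
  r_in <- 0.006          # inlet/outlet tube radius (m)
  r_th <- 0.002          # throat radius (m)
  l_th <- 0.04           # throat length (m)
  l_cone <- (r_in - r_th) / tan(10 * pi / 180)  # 20 deg full-angle cone
  z_cone0 <- -l_th - l_cone
  if (z_inlet >= z_cone0) stop("z_inlet must be upstream of the conical collector")
  if (z_outlet <= 0) stop("z_outlet must be downstream of the sudden expansion")
  nozzle_geometry(data.frame(
    z_start = c(z_inlet, z_cone0, -l_th, 0),
    z_end   = c(z_cone0, -l_th, 0, z_outlet),
    kind    = c("constant", "cone", "constant", "constant"),
    R_start = c(r_in, r_in, r_th, r_in),
    R_end   = c(r_in, r_th, r_th, r_in)))
}

#' Conical tube geometry
#'
#' @param r_start,r_end inlet and outlet radii (m)
#' @param length axial length (m)
#' @param z_start axial position of the inlet (m)
#' @return a [nozzle_geometry()]
#' @export
cone_tube <- function(r_start, r_end, length, z_start = 0) {
  nozzle_geometry(data.frame(
    z_start = z_start, z_end = z_start + length,
    kind = "cone", R_start = r_start, R_end = r_end))
}

#' Wall radius at axial positions
#'
#' Evaluates the piecewise radius function \eqn{R(z)}. At a sudden-expansion
#' joint the downstream segment's value is returned (the choice only affects
#' a set of measure zero and is irrelevant for integrals over the geometry).
#'
#' @param geom a [nozzle_geometry()]
#' @param z numeric vector of axial positions (m), all within
#'   `[geom$z_min, geom$z_max]`
#' @return numeric vector of radii (m)
#' @export
radius_at <- function(geom, z) {
  stopifnot(inherits(geom, "nozzle_geometry"))
  if (any(z < geom$z_min - 1e-12) || any(z > geom$z_max + 1e-12))
    stop("z outside the geometry's axial extent [",
         geom$z_min, ", ", geom$z_max, "]")
  seg <- geom$segments
  # right-open intervals give the downstream segment at joints
  idx <- findInterval(z, seg$z_start, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(seg)] <- nrow(seg)
  zs <- seg$z_start[idx]; ze <- seg$z_end[idx]
  frac <- ifelse(ze > zs, (z - zs) / (ze - zs), 0)
  frac <- pmin(pmax(frac, 0), 1)
  seg$R_start[idx] + frac * (seg$R_end[idx] - seg$R_start[idx])
}

#' Rasterize geometry to a fluid/solid cell mask
#'
#' Cell-centered staircase rasterization: a cell is fluid iff its center
#' satisfies \eqn{r \le R(z)} at the cell-center axial position. Sub-cell
#' (volume-of-fluid) wall fractions are deliberately not modelled.
#'
#' @param geom a [nozzle_geometry()]
#' @param grid an [axi_grid()] covering the geometry
#' @return logical matrix `nr x nz`; `TRUE` marks fluid cells
#' @export
build_mask <- function(geom, grid) {
  stopifnot(inherits(geom, "nozzle_geometry"), inherits(grid, "axi_grid"))
  rmin <- min(geom$segments$R_start, geom$segments$R_end)
  if (grid$dr > rmin)
    stop(sprintf("radial spacing dr = %g exceeds the smallest radius %g; refine the grid",
                 grid$dr, rmin))
  if (grid$z[1] < geom$z_min - grid$dz || grid$z[grid$nz] > geom$z_max + grid$dz)
    stop("grid axial extent does not match the geometry")
  zc <- pmin(pmax(grid$z, geom$z_min), geom$z_max)
  R <- radius_at(geom, zc)
  outer(grid$r, R, `<=`)
}

#' Geometry integral of the analytic hemolysis bound
#'
#' Computes \eqn{I = \int R(z)^q \, dz} over the whole conduit, the purely
#' geometric factor entering the closed-form axisymmetric hemolysis lower
#' bound. Closed forms are used on constant and cone segments; adaptive
#' quadrature is available as a cross-check.
#'
#' The exponent demanded by the damage bound is \eqn{q = 2 - 3b/a} with
#' `a`, `b` the power-law damage exponents (see
#' [analytic_lower_bound()]); for the Giersiepen coefficients
#' \eqn{q \approx -7.233}.
#'
#' @param geom a [nozzle_geometry()]
#' @param exponent the radius exponent \eqn{q}
#' @param unit_convention `"m"` (SI) or `"mm"`: lengths and radii are
#'   converted to the stated unit before integrating, so the result has
#'   units of length^(1+q) in that unit.
#' @param method `"closed_form"` (default) or `"quadrature"`
#' @return the scalar integral \eqn{I}
#' @export
geometry_integral <- function(geom, exponent,
                              unit_convention = c("m", "mm"),
                              method = c("closed_form", "quadrature")) {
  stopifnot(inherits(geom, "nozzle_geometry"))
  unit_convention <- match.arg(unit_convention)
  method <- match.arg(method)
  s <- 1
  if (unit_convention == "mm") s <- 1000
  seg <- geom$segments
  q <- exponent
  total <- 0
  for (k in seq_len(nrow(seg))) {
    z0 <- seg$z_start[k] * s; z1 <- seg$z_end[k] * s
    R0 <- seg$R_start[k] * s; R1 <- seg$R_end[k] * s
    if (min(R0, R1) <= 0 && q < 0)
      stop("divergent geometry integral: zero radius with negative exponent")
    if (method == "quadrature") {
      total <- total + stats::integrate(
        function(z) {
          frac <- (z - z0) / (z1 - z0)
          (R0 + frac * (R1 - R0))^q
        }, z0, z1, rel.tol = 1e-12, abs.tol = 0)$value
      next
    }
    if (abs(R1 - R0) < 1e-14) {            # constant radius
      total <- total + (z1 - z0) * R0^q
    } else {                               # linear cone
      slope <- (R1 - R0) / (z1 - z0)
      if (abs(q + 1) < 1e-12) {
        total <- total + (log(R1) - log(R0)) / slope
      } else {
        total <- total + (R1^(q + 1) - R0^(q + 1)) / ((q + 1) * slope)
      }
    }
  }
  total
}

#' Conduit volume of revolution
#'
#' Analytic volume \eqn{\pi \int R(z)^2 dz}, used as the oracle for mask
#' rasterization convergence.
#'
#' @param geom a [nozzle_geometry()]
#' @return volume (m^3)
#' @export
geometry_volume <- function(geom) {
  pi * geometry_integral(geom, 2, "m")
}
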