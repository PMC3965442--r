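#' Regular axisymmetric (r, z) grid
#'
#' Cell-centered regular grid in the (r, z) half-plane. Radial centers sit at
#' \eqn{r_i = (i - 1/2)\,\Delta r}, so no cell center lies on the symmetry
#' axis and the \eqn{1/r} geometric factors of the cylindrical operators stay
#' finite; the axis is handled by reflection ghost cells in the solver.
#'
#' @param geom a [nozzle_geometry()], used for the radial and axial extents;
#'   alternatively pass `z_min`, `z_max`, `r_max` explicitly.
#' @param dr,dz cell spacings (m)
#' @param z_min,z_max,r_max domain extents (m), taken from `geom` when given
#' @param ghost ghost-layer width in cells (must cover half the widest
#'   stencil; 4 suits the 7th-order interior scheme)
#' @return an object of class `axi_grid` with cell counts `nr`, `nz`,
#'   spacings and center coordinate vectors `r`, `z`.
#' @examples
#' g <- axi_grid(straight_tube(0.002, 0.02), dr = 2.5e-4, dz = 5e-4)
#' @export
axi_grid <- function(geom = NULL, dr, dz,
                     z_min = NULL, z_max = NULL, r_max = NULL, ghost = 4L) {
  if (!is.null(geom)) {
    stopifnot(inherits(geom, "nozzle_geometry"))
    z_min <- geom$z_min; z_max <- geom$z_max; r_max <- geom$r_max
  }
  stopifnot(dr > 0, dz > 0, z_max > z_min, r_max > 0, ghost >= 1L)
  nr <- as.integer(ceiling(r_max / dr - 1e-9))
  nz <- as.integer(round((z_max - z_min) / dz))
  if (abs(nz * dz - (z_max - z_min)) > 1e-9 * (z_max - z_min))
    nz <- as.integer(ceiling((z_max - z_min) / dz - 1e-9))
  structure(
    list(nr = nr, nz = nz, dr = dr, dz = dz, ghost = as.integer(ghost),
         r = (seq_len(nr) - 0.5) * dr,
         z = z_min + (seq_len(nz) - 0.5) * dz,
         z_min = z_min, z_max = z_min + nz * dz, r_max = nr * dr),
    class = "axi_grid")
}

#' @export
print.axi_grid <- function(x, ...) {
  cat(sprintf("<axi_grid> %d x %d cells (r x z), dr = %g m, dz = %g m, z in [%g, %g] m\n",
              x$nr, x$nz, x$dr, x$dz, x$z_min, x$z_max))
  invisible(x)
}
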