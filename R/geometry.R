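# Particle geometry: circular (disk) reference cross-section, area-preserving
# elliptical perturbations, and the 1D radial grid used by the finite-volume
# solver.  All user-facing lengths are in micrometres.

#' Core-shell particle geometry
#'
#' Describes a two-layer microparticle: an inner drug-loaded core of diameter
#' `d0` enveloped by a shell extending to total diameter `d1`.  The default
#' geometry is the two-dimensional cross-section of the reference
#' metronidazole-loaded, layer-by-layer-coated particle (core diameter
#' 1.39 um, total diameter 1.52 um); in `"2D"` mode "volume" means
#' cross-sectional area.
#'
#' @param d0 Core diameter in micrometres.
#' @param d1 Total (core + shell) diameter in micrometres; must exceed `d0`.
#' @param shape `"disk"` for the circular reference cross-section or
#'   `"ellipse"` for an area-preserving elliptical perturbation of it
#'   (see [make_ellipse()]).
#' @param eccentricity Ellipse eccentricity in `[0, 1)`; 0 recovers the disk.
#' @param dimension `"2D"` (cross-sectional areas, the reference setting) or
#'   `"3D"` (spherical volumes).
#'
#' @return An object of class `particle_geometry` with fields `d0`, `d1`,
#'   `R0`, `R1` (radii, um), `shape`, `eccentricity` and `dimension`.
#' @examples
#' geom <- particle_geometry()
#' core_volume(geom)   # 1.5175 um^2
#' shell_volume(geom)  # 0.2971 um^2
#' @seealso [core_volume()], [shell_volume()], [make_ellipse()],
#'   [build_radial_grid()]
#' @export
particle_geometry <- function(d0 = 1.39, d1 = 1.52,
                              shape = c("disk", "ellipse"),
                              eccentricity = 0,
                              dimension = c("2D", "3D")) {
  shape <- match.arg(shape)
  dimension <- match.arg(dimension)
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0)
    stop("'d0' must be a single positive number (micrometres)")
  if (!is.numeric(d1) || length(d1) != 1L || !is.finite(d1) || d1 <= d0)
    stop("'d1' must be a single number larger than 'd0'")
  if (!is.numeric(eccentricity) || length(eccentricity) != 1L ||
      eccentricity < 0 || eccentricity >= 1)
    stop("'eccentricity' must lie in [0, 1)")
  if (shape == "disk" && eccentricity != 0)
    stop("a disk has eccentricity 0; use shape = \"ellipse\"")
  if (shape == "ellipse" && dimension == "3D")
    stop("elliptical geometry is only available in 2D mode")
  structure(
    list(d0 = d0, d1 = d1, R0 = d0 / 2, R1 = d1 / 2,
         shape = shape, eccentricity = eccentricity, dimension = dimension),
    class = "particle_geometry")
}

#' @export
print.particle_geometry <- function(x, ...) {
  cat("Core-shell particle geometry (", x$dimension, " ", x$shape, ")\n",
      sep = "")
  cat(sprintf("  core diameter  d0 = %g um\n", x$d0))
  cat(sprintf("  total diameter d1 = %g um\n", x$d1))
  if (x$shape == "ellipse")
    cat(sprintf("  eccentricity    lambda = %g\n", x$eccentricity))
  unit <- if (x$dimension == "2D") "um^2" else "um^3"
  cat(sprintf("  core %s = %.4f, shell %s = %.4f\n",
              unit, core_volume(x), unit, shell_volume(x)))
  invisible(x)
}

#' Core and shell volumes (areas in 2D)
#'
#' `core_volume()` returns the measure of the core domain; `shell_volume()`
#' the measure of the enveloping shell (total minus core).  In `"2D"` mode
#' these are cross-sectional areas in um^2; in `"3D"` mode spherical volumes
#' in um^3.  Elliptical geometries preserve the disk areas by construction.
#'
#' @param geom A [particle_geometry()].
#' @return A single number, um^2 (2D) or um^3 (3D).
#' @export
core_volume <- function(geom) {
  stopifnot(inherits(geom, "particle_geometry"))
  if (geom$dimension == "2D") pi * geom$R0^2 else 4 / 3 * pi * geom$R0^3
}

#' @rdname core_volume
#' @export
shell_volume <- function(geom) {
  stopifnot(inherits(geom, "particle_geometry"))
  if (geom$dimension == "2D") pi * (geom$R1^2 - geom$R0^2)
  else 4 / 3 * pi * (geom$R1^3 - geom$R0^3)
}

#' Area-preserving elliptical perturbation of the reference cross-section
#'
#' Flattens the circular cross-section into a pair of concentric, co-oriented
#' ellipses of common eccentricity `lambda`, keeping the core area and the
#' shell area equal to the reference disk values.  With axis ratio
#' `b/a = sqrt(1 - lambda^2)`, area preservation fixes each boundary to
#' `a = r / (1 - lambda^2)^(1/4)`, `b = r * (1 - lambda^2)^(1/4)` where `r`
#' is the reference radius.  The shell consequently thins at the flat ends
#' of the ellipse, which is the geometric origin of the increased release
#' observed in the shape-sensitivity study.
#'
#' @param geom The circular reference [particle_geometry()] (2D disk).
#' @param eccentricity Eccentricity `lambda` in `[0, 1)`.
#' @return An object of class `ellipse_spec` with semi-axes `a0`, `b0`
#'   (core) and `a1`, `b1` (outer boundary), in micrometres.
#' @examples
#' make_ellipse(particle_geometry(), 0.6)
#' @export
make_ellipse <- function(geom, eccentricity) {
  stopifnot(inherits(geom, "particle_geometry"))
  if (geom$dimension != "2D")
    stop("elliptical perturbations are defined for 2D cross-sections")
  if (!is.numeric(eccentricity) || length(eccentricity) != 1L ||
      !is.finite(eccentricity) || eccentricity < 0 || eccentricity >= 1)
    stop("invalid eccentricity: must lie in [0, 1)")
  s <- (1 - eccentricity^2)^0.25   # b = r*s, a = r/s keeps a*b = r^2
  structure(
    list(a0 = geom$R0 / s, b0 = geom$R0 * s,
         a1 = geom$R1 / s, b1 = geom$R1 * s,
         eccentricity = eccentricity, reference = geom),
    class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf("Ellipse cross-section, eccentricity %g\n", x$eccentricity))
  cat(sprintf("  core  semi-axes a0 = %.4f, b0 = %.4f um (area %.4f um^2)\n",
              x$a0, x$b0, pi * x$a0 * x$b0))
  cat(sprintf("  outer semi-axes a1 = %.4f, b1 = %.4f um (area %.4f um^2)\n",
              x$a1, x$b1, pi * x$a1 * x$b1))
  invisible(x)
}

#' Radial finite-volume grid for the circular particle
#'
#' Builds the node-centred radial grid used by [simulate_particle()]: nodes
#' uniformly spaced within each layer, with one node placed exactly on the
#' core-shell interface (radius `R0`) and one on the outer boundary (`R1`).
#' Because the interface is a shared node, concentration continuity across
#' the interface is automatic, and every finite-volume face lies strictly
#' inside a single material so each face carries a single diffusivity.
#'
#' Each node owns a control volume bounded by the face midpoints; the
#' control-volume measures (`measure`, split into `measure_core` and
#' `measure_shell` for the interface node) sum exactly to the layer areas
#' (2D) or volumes (3D).
#'
#' @param geom A disk [particle_geometry()] (elliptical shapes require the
#'   2D finite-element path, see [build_mesh()]).
#' @param n_core,n_shell Number of intervals in the core and shell
#'   (at least 4 each).
#' @return An object of class `radial_grid`: node radii `r` (um),
#'   `interface_index`, per-node measures (um^2 or um^3) and the geometry.
#' @export
build_radial_grid <- function(geom, n_core = 40, n_shell = 20) {
  stopifnot(inherits(geom, "particle_geometry"))
  if (geom$shape != "disk")
    stop("unsupported shape for the radial grid: use build_mesh() for ellipses")
  if (n_core < 4 || n_shell < 4)
    stop("'n_core' and 'n_shell' must each be at least 4")
  r <- c(seq(0, geom$R0, length.out = n_core + 1),
         seq(geom$R0, geom$R1, length.out = n_shell + 1)[-1])
  n <- length(r)
  istar <- n_core + 1L
  faces <- (r[-1] + r[-n]) / 2          # one face between consecutive nodes
  edges <- c(0, faces, geom$R1)         # control-volume edges, length n + 1
  d <- if (geom$dimension == "2D") 2 else 3
  cd <- if (d == 2) pi else 4 / 3 * pi  # measure of unit ball
  shellv <- function(lo, hi) cd * (hi^d - lo^d)
  measure <- shellv(edges[-(n + 1)], edges[-1])
  measure_core <- shellv(pmin(edges[-(n + 1)], geom$R0),
                         pmin(edges[-1], geom$R0))
  measure_shell <- measure - measure_core
  structure(
    list(r = r, faces = faces, interface_index = istar,
         measure = measure, measure_core = measure_core,
         measure_shell = measure_shell,
         n_core = n_core, n_shell = n_shell, geometry = geom),
    class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf(
    "Radial grid: %d nodes (%d core + %d shell intervals), interface at %g um\n",
    length(x$r), x$n_core, x$n_shell, x$r[x$interface_index]))
  invisible(x)
}
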