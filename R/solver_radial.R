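# Method-of-lines finite-volume solver for the radially symmetric particle.
#
# The dissolved field c is discretized with node-centred finite volumes on
# the radial grid; faces lie halfway between nodes, so with the interface
# placed on a node every face sits strictly inside one material and carries
# that material's diffusivity.  The immobile fields b0 (undissolved, core)
# and b1 (bound, shell) are nodal ODEs without transport.  The r = 0
# singularity never appears because the centre node's control volume has a
# zero-measure inner face.  The perfect sink is imposed strongly at the
# outer node, and the one-sided flux through the last interior face is
# integrated alongside the state to audit global mass conservation.

#' Solver options
#'
#' @param n_core,n_shell Radial grid resolution, see [build_radial_grid()].
#' @param t_end Simulation horizon in hours (default 400; the release time
#'   should be comfortably inside it, see [release_time()]).
#' @param output_times Times (hours) at which the solution is reported;
#'   default: 401 equispaced samples on `[0, t_end]`.
#' @param snapshot_times Times (hours) at which full concentration profiles
#'   are stored in the result.
#' @param rtol,atol Relative/absolute tolerances of the stiff integrator,
#'   applied in internal (CGS, possibly normalized) units.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(n_core = 40, n_shell = 20, t_end = 400,
                           output_times = NULL, snapshot_times = NULL,
                           rtol = 1e-8, atol = 1e-12) {
  if (t_end <= 0) stop("'t_end' must be positive")
  if (rtol <= 0 || atol <= 0) stop("integrator tolerances must be positive")
  if (is.null(output_times))
    output_times <- seq(0, t_end, length.out = 401L)
  output_times <- sort(unique(c(0, output_times, snapshot_times)))
  if (any(output_times < 0) || any(output_times > t_end))
    stop("'output_times' must lie within [0, t_end]")
  structure(
    list(n_core = n_core, n_shell = n_shell, t_end = t_end,
         output_times = output_times, snapshot_times = snapshot_times,
         rtol = rtol, atol = atol),
    class = "solver_options")
}

# Internal dissolution/source scales shared by both solvers.
# Returns S and initial b0 in internal units plus the factor converting
# internal concentration to g/cm^d.
.internal_scales <- function(p, geom) {
  B0 <- initial_core_concentration(p, geom)
  if (p$normalization == "normalized_by_B0")
    list(S = p$S / B0, b0_init = 1, conc_scale = B0)
  else
    list(S = p$S, b0_init = B0, conc_scale = 1)
}

#' Simulate drug release from the radially symmetric particle
#'
#' Integrates the dissolution-diffusion-binding system on the disk (2D) or
#' sphere (3D) using the radial finite-volume discretization and an
#' adaptive implicit (stiff) integrator, and returns the release curve,
#' final concentration fields and conservation diagnostics.
#'
#' @param geom A disk [particle_geometry()].
#' @param p A [model_parameters()] object.
#' @param opts A [solver_options()] object.
#' @param init Optional [initial_state()] override (e.g. fully dissolved
#'   initial drug for comparison with [analytic_disk_release()]).
#' @return An object of class `coreshell_sim` with components
#'   \describe{
#'     \item{release}{data frame `time_h`, `Mtot_ug`, `Mrel_pct`.}
#'     \item{final_state}{nodal fields at `t_end` (`r_um`, `b0`, `c0`,
#'       `c1`, `b1`, in the units implied by `p$normalization`).}
#'     \item{snapshots}{profiles at `opts$snapshot_times`, if requested.}
#'     \item{diagnostics}{`mass_balance_residual` (max over output times of
#'       `|Mtot(t) + outflux(t) - Mtot(0)| / Mtot(0)`) and integrator step
#'       count.}
#'   }
#' @examples
#' \donttest{
#' sim <- simulate_particle(particle_geometry(), reference_parameters(),
#'                          solver_options(t_end = 400))
#' release_summary(sim)
#' }
#' @export
simulate_particle <- function(geom, p, opts = solver_options(), init = NULL) {
  stopifnot(inherits(geom, "particle_geometry"),
            inherits(p, "model_parameters"),
            inherits(opts, "solver_options"))
  grid <- build_radial_grid(geom, opts$n_core, opts$n_shell)
  if (is.null(init)) init <- initial_state(grid, p)
  stopifnot(inherits(init, "particle_state"))

  d <- if (geom$dimension == "2D") 2L else 3L
  sc <- .internal_scales(p, geom)
  n <- length(grid$r)
  istar <- grid$interface_index
  idx_core <- seq_len(istar)
  idx_shell <- istar:n

  r_cm <- grid$r * .um_to_cm
  f_cm <- grid$faces * .um_to_cm
  A  <- grid$measure * .um_to_cm^d        # control-volume measures, cm^d
  Ac <- grid$measure_core * .um_to_cm^d
  As <- grid$measure_shell * .um_to_cm^d
  Aface <- if (d == 2L) 2 * pi * f_cm else 4 * pi * f_cm^2
  Dface <- ifelse(grid$faces < geom$R0, p$D0, p$D1)
  trans <- Dface * Aface / diff(r_cm)     # face transmissibilities
  wc <- Ac[idx_core] / A[idx_core]        # core fraction of each CV
  ws <- As[idx_shell] / A[idx_shell]

  if (length(init$b0) != istar || length(init$c0) != istar ||
      length(init$c1) != n - istar + 1L || length(init$b1) != n - istar + 1L)
    stop("initial state does not match the grid partition")
  cc0 <- numeric(n)
  cc0[idx_core] <- init$c0
  cc0[idx_shell] <- init$c1               # interface node: c0 = c1 required
  if (abs(init$c0[istar] - init$c1[1]) > 1e-12 * max(1, abs(init$c1[1])))
    stop("initial c0 and c1 must agree at the interface node")
  cc0[n] <- 0                             # perfect sink
  y0 <- c(cc0, init$b0, init$b1, 0)

  beta <- p$beta; alpha <- p$alpha; Sint <- sc$S; k <- p$k
  i_b0 <- n + seq_len(istar)
  i_b1 <- n + istar + seq_len(n - istar + 1L)

  rhs <- function(t, y, parms) {
    cc <- y[1:n]
    b0 <- y[i_b0]
    b1 <- y[i_b1]
    q <- -trans * diff(cc)                # outward face fluxes, conc*cm^d/s
    dc <- (c(0, q) - c(q, 0)) / A
    g <- beta * pmax(b0, 0)^alpha * (Sint - cc[idx_core])
    dc[idx_core] <- dc[idx_core] + g * wc
    db1 <- k * cc[idx_shell]
    dc[idx_shell] <- dc[idx_shell] - db1 * ws
    dc[n] <- 0
    list(c(dc, -g, db1, q[n - 1L]))
  }

  times_s <- opts$output_times * .h_to_s
  sol <- deSolve::lsodes(y0, times_s, rhs, parms = NULL,
                         rtol = opts$rtol, atol = opts$atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("stiff integrator failed to converge beyond t = %.3g h",
                 sol[nrow(sol), 1] / .h_to_s))

  cc <- sol[, 1 + (1:n), drop = FALSE]
  b0 <- sol[, 1 + i_b0, drop = FALSE]
  b1 <- sol[, 1 + i_b1, drop = FALSE]
  Q  <- sol[, ncol(sol)]

  mass_g <- (cc %*% A + b0 %*% Ac[idx_core] + b1 %*% As[idx_shell]) *
    sc$conc_scale
  Mtot_ug <- as.numeric(mass_g) / .ug_to_g
  resid <- if (mass_g[1] > 0)
    max(abs(as.numeric(mass_g) + Q * sc$conc_scale - mass_g[1])) / mass_g[1]
  else max(abs(as.numeric(mass_g) + Q * sc$conc_scale - mass_g[1]))

  release <- data.frame(
    time_h = opts$output_times,
    Mtot_ug = Mtot_ug,
    Mrel_pct = if (Mtot_ug[1] > 0) release_profile(Mtot_ug)
               else rep(0, length(Mtot_ug)))

  state_at <- function(i) {
    structure(list(t = times_s[i],
                   r_um = grid$r,
                   b0 = b0[i, ], c0 = cc[i, idx_core],
                   c1 = cc[i, idx_shell], b1 = b1[i, ]),
              class = "particle_state")
  }
  snaps <- NULL
  if (!is.null(opts$snapshot_times)) {
    snaps <- lapply(opts$snapshot_times, function(tt)
      state_at(which.min(abs(opts$output_times - tt))))
    names(snaps) <- sprintf("t=%gh", opts$snapshot_times)
  }

  structure(
    list(release = release,
         final_state = state_at(length(times_s)),
         snapshots = snaps,
         diagnostics = list(
           mass_balance_residual = resid,
           integrator_steps = unname(attr(sol, "istate")[3])),
         grid = grid, geometry = geom, parameters = p, options = opts,
         method = "radial_fv"),
    class = "coreshell_sim")
}

#' @export
print.coreshell_sim <- function(x, ...) {
  fin <- x$release$Mrel_pct[nrow(x$release)]
  cat(sprintf("coreshell simulation (%s): %d output times over %g h\n",
              x$method, nrow(x$release), max(x$release$time_h)))
  cat(sprintf("  final released: %.2f%%   mass-balance residual: %.2e\n",
              fin, x$diagnostics$mass_balance_residual))
  invisible(x)
}

#' @export
plot.coreshell_sim <- function(x, ...) {
  graphics::plot(x$release$time_h, x$release$Mrel_pct, type = "l",
                 xlab = "time [h]", ylab = "cumulative release [%]",
                 ylim = c(0, 100), ...)
  invisible(x)
}

# First `n` positive zeros of the Bessel function J0, bracketed by the
# McMahon asymptotic expansion and polished with uniroot on base R's besselJ.
.j0_zeros <- function(n) {
  vapply(seq_len(n), function(j) {
    g <- (j - 0.25) * pi
    stats::uniroot(function(x) besselJ(x, 0), c(g - 0.6, g + 0.6),
                   tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Closed-form release from a uniformly loaded disk
#'
#' Fraction of an initially uniform dissolved load released from a single
#' homogeneous disk of radius `R` with an absorbing (perfect-sink) boundary:
#' `1 - sum_n (4 / lambda_n^2) exp(-D lambda_n^2 t / R^2)` over the zeros
#' `lambda_n` of the Bessel function J0.  Serves as the independent oracle
#' for the linear-diffusion limit of the numerical solvers (no dissolution
#' kinetics, no binding, equal diffusivities).
#'
#' @param D Diffusivity, in units consistent with `R` and `t` (only the
#'   dimensionless group `D t / R^2` matters).
#' @param R Disk radius.
#' @param t Time (vectorized, nonnegative).
#' @param tail Series truncation: terms are added until the bound on the
#'   remaining tail is below `tail` (subject to `max_terms`).
#' @param max_terms Maximum number of series terms.
#' @return Fraction released in `[0, 1]`, same length as `t`.
#' @examples
#' analytic_disk_release(1, 1, c(0.01, 0.05, 0.2))
#' @export
analytic_disk_release <- function(D, R, t, tail = 1e-10, max_terms = 5000L) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  if (D <= 0 || R <= 0) stop("'D' and 'R' must be positive")
  tau <- D * t / R^2
  out <- numeric(length(t))
  out[tau == 0] <- 0
  pos <- which(tau > 0)
  if (length(pos)) {
    tmin <- min(tau[pos])
    # number of terms so that exp(-z_n^2 tmin) * 4/z_n^2 < tail;
    # z_n ~ (n - 1/4) pi
    nterm <- ceiling(sqrt(max(-log(tail), 1) / tmin) / pi + 0.25)
    nterm <- min(max(nterm, 5L), max_terms)
    z2 <- .j0_zeros(nterm)^2
    for (i in pos)
      out[i] <- 1 - sum(4 / z2 * exp(-z2 * tau[i]))
  }
  pmin(pmax(out, 0), 1)
}
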