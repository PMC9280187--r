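# Release metrics: total drug mass, cumulative release profile and the
# release time t_r.

#' Total drug mass in the particle
#'
#' Integrates `b0 + c0` over the core and `b1 + c1` over the shell for a
#' nodal state on either discretization, and converts to micrograms.
#'
#' @param state A `particle_state` (radial) or `fem_state` (mesh) object.
#' @param disc The discretization the state lives on: a [build_radial_grid()]
#'   grid or a [build_mesh()] mesh.
#' @param p The [model_parameters()] the state was produced with (needed to
#'   undo the concentration normalization).
#' @return Total mass in micrograms.
#' @export
total_mass <- function(state, disc, p) {
  stopifnot(inherits(p, "model_parameters"))
  if (inherits(disc, "radial_grid")) {
    stopifnot(inherits(state, "particle_state"))
    geom <- disc$geometry
    d <- if (geom$dimension == "2D") 2L else 3L
    sc <- .internal_scales(p, geom)
    istar <- disc$interface_index
    n <- length(disc$r)
    Ac <- disc$measure_core * .um_to_cm^d
    As <- disc$measure_shell * .um_to_cm^d
    m_g <- sum((state$b0 + state$c0) * Ac[seq_len(istar)]) +
      sum((state$b1 + state$c1) * As[istar:n])
  } else if (inherits(disc, "mesh2d")) {
    stopifnot(inherits(state, "fem_state"))
    sc <- .internal_scales(p, disc$geometry)
    Ac <- disc$lump_core * .um_to_cm^2
    As <- disc$lump_shell * .um_to_cm^2
    m_g <- sum((state$b0 + state$c) * Ac) + sum((state$b1 + state$c) * As)
  } else stop("'disc' must be a radial_grid or a mesh2d")
  m_g * sc$conc_scale / .ug_to_g
}

#' Cumulative release profile
#'
#' Converts a sequence of total masses `Mtot(t)` into the cumulative
#' percentage released, `100 * (Mtot(0) - Mtot(t)) / Mtot(0)`.
#'
#' @param Mtot Numeric vector of total masses, first element at time zero.
#' @return Percent released, same length as `Mtot`.
#' @export
release_profile <- function(Mtot) {
  if (length(Mtot) < 1L || !all(is.finite(Mtot)))
    stop("'Mtot' must be a finite numeric vector")
  if (Mtot[1] <= 0) stop("initial total mass must be positive")
  100 * (Mtot[1] - Mtot) / Mtot[1]
}

#' Release time
#'
#' The release time `t_r` is the smallest time beyond which the cumulative
#' release varies by less than a small threshold: the first `t` such that
#' `Mrel(t_end) - Mrel(t) < threshold`, located by linear interpolation
#' between samples.  By default the threshold is 0.1 absolute percentage
#' points of cumulative release; `relative = TRUE` instead uses
#' `threshold`% of the final value (the two readings of a "variation below
#' 0.1%" plateau criterion; see the methods vignette).  The horizon must
#' extend comfortably past the plateau for `t_r` to be meaningful: a
#' warning is issued when `t_r` falls in the last 5% of the sampled span.
#'
#' @param x A `coreshell_sim` result, a data frame with columns `time_h`
#'   and `Mrel_pct`, or a numeric vector of release percentages (then
#'   `times` must be given).
#' @param threshold Plateau threshold, percentage points (default 0.1).
#' @param relative If `TRUE`, `threshold` is a percentage of the final
#'   release value rather than absolute points.
#' @param times Sample times in hours when `x` is a bare numeric vector.
#' @return Release time in hours.
#' @examples
#' t <- seq(0, 400, by = 0.5)
#' curve <- data.frame(time_h = t, Mrel_pct = 100 * (1 - exp(-t / 30)))
#' release_time(curve)   # ~ 30 * log(100 / 0.1) = 207.2 h
#' @export
release_time <- function(x, threshold = 0.1, relative = FALSE, times = NULL) {
  if (inherits(x, "coreshell_sim")) {
    times <- x$release$time_h; m <- x$release$Mrel_pct
  } else if (is.data.frame(x)) {
    if (!all(c("time_h", "Mrel_pct") %in% names(x)))
      stop("data frame must have columns 'time_h' and 'Mrel_pct'")
    times <- x$time_h; m <- x$Mrel_pct
  } else {
    m <- as.numeric(x)
    if (is.null(times) || length(times) != length(m))
      stop("'times' must accompany a bare release vector")
  }
  if (threshold <= 0) stop("'threshold' must be positive")
  if (length(m) < 2L) stop("need at least two samples")
  fin <- m[length(m)]
  thr <- if (relative) threshold / 100 * fin else threshold
  target <- fin - thr
  if (m[1] >= target) return(times[1])
  i <- which(m >= target)[1]
  if (is.na(i))
    stop("release curve never reaches its plateau criterion within the horizon")
  tr <- stats::approx(m[(i - 1L):i], times[(i - 1L):i], xout = target,
                      ties = "ordered")$y
  span <- times[length(times)] - times[1]
  if (tr > times[length(times)] - 0.02 * span)
    warning("release time lies in the last 2% of the horizon; ",
            "consider extending 't_end'")
  tr
}

#' Summary of a release simulation
#'
#' @param sim A `coreshell_sim` result.
#' @param threshold Plateau threshold passed to [release_time()].
#' @return A list with `released_pct_final`, `release_time_h`,
#'   `bound_fraction_pct` (drug permanently bound in the shell at the end
#'   of the run, percent of initial load) and `mass_balance_residual`.
#' @export
release_summary <- function(sim, threshold = 0.1) {
  stopifnot(inherits(sim, "coreshell_sim"))
  fs <- sim$final_state
  p <- sim$parameters
  geom <- sim$geometry
  sc <- .internal_scales(p, geom)
  if (sim$method == "radial_fv") {
    d <- if (geom$dimension == "2D") 2L else 3L
    As <- sim$grid$measure_shell * .um_to_cm^d
    istar <- sim$grid$interface_index
    bound_g <- sum(fs$b1 * As[istar:length(sim$grid$r)]) * sc$conc_scale
  } else {
    bound_g <- sum(fs$b1 * sim$mesh$lump_shell * .um_to_cm^2) * sc$conc_scale
  }
  M0 <- sim$release$Mtot_ug[1]
  list(released_pct_final = sim$release$Mrel_pct[nrow(sim$release)],
       release_time_h = release_time(sim, threshold = threshold),
       bound_fraction_pct = 100 * bound_g / .ug_to_g / M0,
       mass_balance_residual = sim$diagnostics$mass_balance_residual)
}
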