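# Calibration of the model parameters against an observed release curve,
# and one-at-a-time parameter sensitivity sweeps.

#' Observed release curve
#'
#' @param time_h Sampling times in hours, strictly increasing.
#' @param release_pct Cumulative percentage released at each time, in
#'   `[0, 100]`.
#' @param sd_pct Optional per-point standard deviation (percentage points),
#'   used as inverse-variance weights in [sse_loss()].
#' @return An object of class `observed_release` (a data frame).
#' @export
observed_release <- function(time_h, release_pct, sd_pct = NULL) {
  if (length(time_h) != length(release_pct))
    stop("'time_h' and 'release_pct' must have equal length")
  if (any(!is.finite(time_h)) || any(diff(time_h) <= 0) || any(time_h < 0))
    stop("'time_h' must be nonnegative and strictly increasing")
  if (any(!is.finite(release_pct)) ||
      any(release_pct < 0) || any(release_pct > 100))
    stop("'release_pct' must lie in [0, 100]")
  df <- data.frame(time_h = time_h, release_pct = release_pct)
  if (!is.null(sd_pct)) {
    if (length(sd_pct) != length(time_h) || any(sd_pct < 0))
      stop("'sd_pct' must be nonnegative and match 'time_h' in length")
    df$sd_pct <- sd_pct
  }
  class(df) <- c("observed_release", "data.frame")
  df
}

#' Weighted sum-of-squares calibration loss
#'
#' Simulates the release curve under parameters `p`, interpolates it at the
#' observation times and returns
#' `sum_i w_i (Mrel_sim(t_i) - obs_i)^2` with `w_i = 1 / sd_i^2` when
#' per-point standard deviations are available and unit weights otherwise.
#'
#' @param p A [model_parameters()] object.
#' @param obs An [observed_release()] curve.
#' @param geom A [particle_geometry()].
#' @param opts A [solver_options()]; its horizon must cover the last
#'   observation.
#' @return Nonnegative scalar loss.
#' @export
sse_loss <- function(p, obs, geom = particle_geometry(),
                     opts = solver_options()) {
  stopifnot(inherits(obs, "observed_release"))
  if (opts$t_end < max(obs$time_h))
    stop("simulation horizon does not cover the observations; raise 't_end'")
  sim <- simulate_particle(geom, p, opts)
  pred <- stats::approx(sim$release$time_h, sim$release$Mrel_pct,
                        xout = obs$time_h, rule = 2, ties = "ordered")$y
  w <- if (!is.null(obs$sd_pct) && all(obs$sd_pct > 0)) 1 / obs$sd_pct^2
  else rep(1, nrow(obs))
  sum(w * (pred - obs$release_pct)^2)
}

#' Calibration specification
#'
#' Declares which parameters are free in a fit, their box bounds and the
#' multistart budget.  All rate- and concentration-like parameters (`D0`,
#' `D1`, `beta`, `S`, `k`) are searched on a log scale; `alpha` linearly.
#' `D0` is excluded from the default free set: the shell is the transport
#' bottleneck, so the release curve carries almost no information about the
#' core diffusivity.
#'
#' @param free Character vector of free parameter names, a subset of
#'   `c("D0", "D1", "alpha", "beta", "S", "k")`.
#' @param lower,upper Named numeric vectors of bounds for (a subset of) the
#'   free parameters; defaults are a factor of 10 around the initial value
#'   (for `alpha`: the initial value +/- 50%, capped to (0, 3]).
#' @param n_starts Number of optimizer starts: the initial parameter vector
#'   plus `n_starts - 1` seeded random starts inside the bounds.
#' @param seed Integer seed making the multistart deterministic.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free = c("beta", "S", "k", "D1"),
                     lower = NULL, upper = NULL,
                     n_starts = 3L, seed = 1L) {
  all_par <- c("D0", "D1", "alpha", "beta", "S", "k")
  if (!all(free %in% all_par))
    stop("'free' must be a subset of ", paste(all_par, collapse = ", "))
  if (n_starts < 1L) stop("'n_starts' must be at least 1")
  structure(list(free = free, lower = lower, upper = upper,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "fit_spec")
}

.fit_bounds <- function(spec, p_init) {
  lo <- hi <- numeric(length(spec$free))
  names(lo) <- names(hi) <- spec$free
  for (nm in spec$free) {
    v <- p_init[[nm]]
    if (nm == "alpha") {
      lo[nm] <- max(v / 1.5, 0.05); hi[nm] <- min(v * 1.5, 3)
    } else {
      lo[nm] <- v / 10; hi[nm] <- v * 10
    }
    if (!is.null(spec$lower) && nm %in% names(spec$lower))
      lo[nm] <- spec$lower[[nm]]
    if (!is.null(spec$upper) && nm %in% names(spec$upper))
      hi[nm] <- spec$upper[[nm]]
  }
  if (any(hi <= lo)) stop("invalid fit bounds: upper must exceed lower")
  if ("alpha" %in% spec$free && (lo["alpha"] <= 0 || hi["alpha"] > 3))
    stop("'alpha' bounds must lie in (0, 3]")
  list(lower = lo, upper = hi)
}

#' Calibrate model parameters to an observed release curve
#'
#' Minimizes [sse_loss()] over the free parameters declared in the
#' [fit_spec()], using box-constrained quasi-Newton search (`L-BFGS-B`) in
#' log-transformed coordinates for the positive rate parameters and linear
#' coordinates for `alpha`, with a deterministic seeded multistart.  Note
#' that a cumulative release curve constrains some parameters only through
#' combinations (notably the product `beta * S` and the ratio `k / D1`);
#' see the methods vignette on identifiability.
#'
#' @param obs An [observed_release()] curve.
#' @param p_init Initial (and fixed, for non-free parameters)
#'   [model_parameters()].
#' @param spec A [fit_spec()].
#' @param geom A [particle_geometry()].
#' @param opts A [solver_options()] used for every loss evaluation.
#' @return An object of class `coreshell_fit`: best-fit `parameters`,
#'   `loss`, a `starts` data frame (per-start loss and convergence code)
#'   and the `spec`.
#' @export
fit_release <- function(obs, p_init = reference_parameters(),
                        spec = fit_spec(), geom = particle_geometry(),
                        opts = solver_options()) {
  stopifnot(inherits(obs, "observed_release"),
            inherits(p_init, "model_parameters"),
            inherits(spec, "fit_spec"))
  if (length(spec$free) == 0L) {
    return(structure(list(parameters = p_init,
                          loss = sse_loss(p_init, obs, geom, opts),
                          starts = data.frame(), spec = spec),
                     class = "coreshell_fit"))
  }
  if (nrow(obs) < length(spec$free))
    stop(sprintf("need at least %d observation points to fit %d parameters",
                 length(spec$free), length(spec$free)))
  bounds <- .fit_bounds(spec, p_init)
  logsc <- spec$free != "alpha"
  tf <- function(v) ifelse(logsc, log10(v), v)
  itf <- function(th) ifelse(logsc, 10^th, th)
  lo_t <- tf(bounds$lower); hi_t <- tf(bounds$upper)

  make_params <- function(th) {
    vals <- itf(th)
    args <- unclass(p_init)
    args[spec$free] <- as.list(vals)
    do.call(model_parameters, args)
  }
  objective <- function(th) {
    val <- try(sse_loss(make_params(th), obs, geom, opts), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e10 else val
  }

  set.seed(spec$seed)
  starts <- matrix(stats::runif(spec$n_starts * length(spec$free)),
                   nrow = spec$n_starts)
  starts <- sweep(sweep(starts, 2, hi_t - lo_t, "*"), 2, lo_t, "+")
  starts[1, ] <- pmin(pmax(tf(unlist(unclass(p_init)[spec$free])), lo_t),
                      hi_t)

  runs <- lapply(seq_len(spec$n_starts), function(i) {
    fit <- try(stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                            lower = lo_t, upper = hi_t,
                            control = list(maxit = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      list(par = starts[i, ], value = Inf, convergence = -1L)
    else fit
  })
  losses <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(losses)))
    stop("calibration failed: no optimizer start converged")
  best <- runs[[which.min(losses)]]
  structure(
    list(parameters = make_params(best$par),
         loss = best$value,
         starts = data.frame(start = seq_len(spec$n_starts),
                             loss = losses,
                             convergence = vapply(runs, function(r)
                               as.integer(r$convergence), integer(1))),
         spec = spec),
    class = "coreshell_fit")
}

#' @export
print.coreshell_fit <- function(x, ...) {
  cat(sprintf("coreshell calibration: loss = %.6g over %d start(s)\n",
              x$loss, max(1L, nrow(x$starts))))
  if (length(x$spec$free))
    for (nm in x$spec$free)
      cat(sprintf("  %-6s = %g\n", nm, x$parameters[[nm]]))
  invisible(x)
}

#' One-at-a-time parameter sweep
#'
#' Rescales a single parameter by each ratio in `ratios` (all other
#' parameters held at their reference values), simulates, and tabulates the
#' release time and final released percentage.
#'
#' @param name One of `"D0"`, `"D1"`, `"alpha"`, `"beta"`, `"S"`, `"k"`.
#' @param ratios Positive multipliers applied to the reference value.
#' @param p_ref Reference [model_parameters()].
#' @param geom A [particle_geometry()].
#' @param opts A [solver_options()].
#' @param threshold Plateau threshold for [release_time()].
#' @return A data frame with columns `parameter`, `ratio`, `t_r_h`,
#'   `released_pct_final`.  The `ratio = 1` row is the reference simulation
#'   itself.
#' @export
sweep_parameter <- function(name, ratios, p_ref = reference_parameters(),
                            geom = particle_geometry(),
                            opts = solver_options(), threshold = 0.1) {
  if (!name %in% c("D0", "D1", "alpha", "beta", "S", "k"))
    stop("'name' must be one of D0, D1, alpha, beta, S, k")
  if (any(ratios <= 0)) stop("'ratios' must be positive")
  rows <- lapply(ratios, function(rat) {
    args <- unclass(p_ref)
    args[[name]] <- args[[name]] * rat
    sim <- simulate_particle(geom, do.call(model_parameters, args), opts)
    data.frame(parameter = name, ratio = rat,
               t_r_h = release_time(sim, threshold = threshold),
               released_pct_final = sim$release$Mrel_pct[nrow(sim$release)])
  })
  do.call(rbind, rows)
}
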