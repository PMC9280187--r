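# 2D P1 finite-element solver on triangulated disk / ellipse cross-sections.
#
# Meshes are built from concentric rings of nodes placed exactly on scaled
# copies of the core and outer boundary curves, triangulated ring-to-ring
# with a zipper walk, so the interface and the outer boundary are resolved
# by mesh edges and every triangle lies wholly in one subdomain.  The weak
# form with piecewise-constant diffusivity makes interface flux continuity
# natural; the mass matrix is lumped so that the immobile phases reduce to
# nodal ODEs, and the same stiff integrator as the radial solver is used.

# Ramanujan's approximation to the ellipse perimeter.
.ellipse_perimeter <- function(a, b)
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))

# n parameter angles giving (approximately) equal arc-length spacing on an
# ellipse of aspect ratio b/a.  All rings of one mesh are scaled copies of
# a single shape, so one theta set per count serves the whole mesh.
.ellipse_theta <- function(n, aspect) {
  if (abs(aspect - 1) < 1e-12) return(2 * pi * (seq_len(n) - 1L) / n)
  tg <- seq(0, 2 * pi, length.out = 4096L)
  ds <- sqrt(sin(tg)^2 + aspect^2 * cos(tg)^2)
  s <- c(0, cumsum((ds[-1] + ds[-length(ds)]) / 2 * diff(tg)))
  stats::approx(s, tg, xout = s[length(s)] * (seq_len(n) - 1L) / n,
                ties = "ordered")$y
}

# Triangulate the annulus between two concentric rings of node indices,
# given their angular positions (ascending, in [0, 2pi)).  Returns a matrix
# of index triples; orientation is fixed later.
.zipper <- function(idxA, thA, idxB, thB) {
  nA <- length(idxA); nB <- length(idxB)
  iA <- c(seq_len(nA), 1L); iB <- c(seq_len(nB), 1L)
  aA <- c(thA, thA[1] + 2 * pi); aB <- c(thB, thB[1] + 2 * pi)
  tri <- matrix(0L, nA + nB, 3)
  i <- 1L; j <- 1L
  for (s in seq_len(nA + nB)) {
    advanceA <- (i < nA + 1L) && (j == nB + 1L || aA[i + 1L] <= aB[j + 1L])
    if (advanceA) {
      tri[s, ] <- c(idxA[iA[i]], idxA[iA[i + 1L]], idxB[iB[j]])
      i <- i + 1L
    } else {
      tri[s, ] <- c(idxA[iA[i]], idxB[iB[j]], idxB[iB[j + 1L]])
      j <- j + 1L
    }
  }
  tri
}

#' Triangular mesh of the particle cross-section
#'
#' Builds a conforming triangulation of the two-layer disk or ellipse
#' cross-section with nodes placed exactly on the core-shell interface and
#' on the outer boundary.  The maximum edge length is controlled by
#' `h_max`; the angular node spacing is kept at 0.7 `h_max` so that the
#' polygonal subdomain areas match the analytic areas to better than 0.5%
#' at the default `h_max = 0.16` um, and the shell is always resolved by at
#' least three element layers across its thickness regardless of `h_max`
#' (the binding reaction develops a boundary layer there).
#'
#' @param x A disk [particle_geometry()] or an [make_ellipse()]
#'   `ellipse_spec`.
#' @param h_max Target maximum element size in micrometres (default 0.16).
#' @return An object of class `mesh2d`: node coordinates `nodes` (um),
#'   `triangles` (index triples, positively oriented), per-triangle
#'   `region` (`"core"`/`"shell"`), logical `boundary` per node, per-node
#'   lumped measures `lump_core`/`lump_shell` (um^2), the achieved minimum
#'   triangle angle `min_angle_deg` and subdomain polygon areas.
#' @export
build_mesh <- function(x, h_max = 0.16) {
  if (inherits(x, "particle_geometry")) {
    if (x$dimension != "2D") stop("2D meshes require a 2D geometry")
    ell <- make_ellipse(
      if (x$shape == "ellipse")
        particle_geometry(x$d0, x$d1, dimension = "2D") else x,
      x$eccentricity)
    geom <- if (x$shape == "ellipse")
      particle_geometry(x$d0, x$d1, dimension = "2D") else x
  } else if (inherits(x, "ellipse_spec")) {
    ell <- x
    geom <- x$reference
  } else stop("'x' must be a particle_geometry or an ellipse_spec")
  if (h_max <= 0) stop("'h_max' must be positive")
  if (h_max > geom$R0)
    stop("mesh resolution error: 'h_max' exceeds the core radius")

  h_arc <- 0.7 * h_max
  h_rad <- 0.87 * h_max
  aspect <- ell$b0 / ell$a0             # common to every ring
  mc <- max(3L, ceiling(ell$a0 / h_rad))
  ms <- max(3L, ceiling((ell$a1 - ell$a0) / h_rad))

  nodes <- matrix(0, 1, 2)              # centre node
  ring_idx <- list(); ring_th <- list()
  theta_cache <- list()
  add_ring <- function(a, b, n) {
    key <- as.character(n)
    if (is.null(theta_cache[[key]]))
      theta_cache[[key]] <<- .ellipse_theta(n, aspect)
    th <- theta_cache[[key]]
    xy <- cbind(a * cos(th), b * sin(th))
    i0 <- nrow(nodes)
    nodes <<- rbind(nodes, xy)
    list(idx = i0 + seq_len(n), th = th)
  }
  # angular counts: h_arc spacing in the core; at the interface and in the
  # thin shell, additionally cap the arc/thickness aspect ratio so the
  # zipper triangles keep a minimum angle of ~11 degrees
  n_of <- function(a, b) max(6L, ceiling(.ellipse_perimeter(a, b) / h_arc))
  dr_shell <- (ell$b1 - ell$b0) / ms    # thinnest shell layer
  n_if <- max(n_of(ell$a0, ell$b0),
              ceiling(.ellipse_perimeter(ell$a1, ell$b1) *
                        tan(11 * pi / 180) / dr_shell))
  nring <- integer(0)
  for (j in seq_len(mc)) {
    f <- j / mc
    n <- if (j == mc) n_if else n_of(ell$a0 * f, ell$b0 * f)
    if (length(nring)) n <- max(n, nring[length(nring)])
    rg <- add_ring(ell$a0 * f, ell$b0 * f, n)
    ring_idx[[j]] <- rg$idx; ring_th[[j]] <- rg$th; nring <- c(nring, n)
  }
  n_if <- nring[mc]
  for (i in seq_len(ms)) {
    f <- i / ms
    rg <- add_ring(ell$a0 + f * (ell$a1 - ell$a0),
                   ell$b0 + f * (ell$b1 - ell$b0), n_if)
    ring_idx[[mc + i]] <- rg$idx; ring_th[[mc + i]] <- rg$th
  }

  # centre fan + ring-to-ring zippers
  tri <- cbind(1L, ring_idx[[1]], c(ring_idx[[1]][-1], ring_idx[[1]][1]))
  for (j in seq_len(mc + ms - 1L))
    tri <- rbind(tri, .zipper(ring_idx[[j]], ring_th[[j]],
                              ring_idx[[j + 1L]], ring_th[[j + 1L]]))

  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- area2 < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  area <- abs(area2) / 2
  if (any(area <= 0)) stop("degenerate triangle in mesh construction")

  # minimum angle over all triangles
  edge <- function(i, j) sqrt(rowSums((nodes[tri[, i], , drop = FALSE] -
                                       nodes[tri[, j], , drop = FALSE])^2))
  e1 <- edge(2, 3); e2 <- edge(1, 3); e3 <- edge(1, 2)
  angs <- cbind(acos(pmin(pmax((e2^2 + e3^2 - e1^2) / (2 * e2 * e3), -1), 1)),
                acos(pmin(pmax((e1^2 + e3^2 - e2^2) / (2 * e1 * e3), -1), 1)),
                acos(pmin(pmax((e1^2 + e2^2 - e3^2) / (2 * e1 * e2), -1), 1)))
  min_angle <- min(angs) * 180 / pi

  cx <- (x1 + x2 + x3) / 3; cy <- (y1 + y2 + y3) / 3
  incore <- (cx / ell$a0)^2 + (cy / ell$b0)^2 <= 1
  region <- factor(ifelse(incore, "core", "shell"),
                   levels = c("core", "shell"))

  nnode <- nrow(nodes)
  lump_core <- lump_shell <- numeric(nnode)
  w <- area / 3
  for (v in 1:3) {
    lump_core <- lump_core +
      tapply2(tri[incore, v], w[incore], nnode)
    lump_shell <- lump_shell +
      tapply2(tri[!incore, v], w[!incore], nnode)
  }
  boundary <- logical(nnode)
  boundary[ring_idx[[mc + ms]]] <- TRUE

  structure(
    list(nodes = nodes, triangles = tri, region = region,
         boundary = boundary, lump_core = lump_core,
         lump_shell = lump_shell, h_max = h_max,
         min_angle_deg = min_angle,
         core_area = sum(area[incore]), shell_area = sum(area[!incore]),
         interface_index = ring_idx[[mc]],
         geometry = geom, ellipse = ell),
    class = "mesh2d")
}

# sum weights w into bins idx over 1..n (rowsum-based accumulation)
tapply2 <- function(idx, w, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(w, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("mesh2d: %d nodes, %d triangles (h_max = %g um, min angle %.1f deg)\n",
              nrow(x$nodes), nrow(x$triangles), x$h_max, x$min_angle_deg))
  cat(sprintf("  core area %.4f um^2, shell area %.4f um^2\n",
              x$core_area, x$shell_area))
  invisible(x)
}

#' Export a mesh as a pair of CSV files
#'
#' Writes `<prefix>_nodes.csv` (columns `x_um`, `y_um`, `boundary`) and
#' `<prefix>_triangles.csv` (columns `v1`, `v2`, `v3`, `region`).
#'
#' @param mesh A [build_mesh()] mesh.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_mesh_csv <- function(mesh, prefix) {
  stopifnot(inherits(mesh, "mesh2d"))
  fn <- paste0(prefix, c("_nodes.csv", "_triangles.csv"))
  utils::write.csv(data.frame(x_um = mesh$nodes[, 1], y_um = mesh$nodes[, 2],
                              boundary = mesh$boundary),
                   fn[1], row.names = FALSE)
  utils::write.csv(data.frame(v1 = mesh$triangles[, 1],
                              v2 = mesh$triangles[, 2],
                              v3 = mesh$triangles[, 3],
                              region = mesh$region),
                   fn[2], row.names = FALSE)
  invisible(fn)
}

# P1 stiffness matrix with per-triangle diffusivity, coordinates in cm.
.assemble_stiffness <- function(mesh, Dtri) {
  nd <- mesh$nodes * .um_to_cm
  tri <- mesh$triangles
  x1 <- nd[tri[, 1], 1]; y1 <- nd[tri[, 1], 2]
  x2 <- nd[tri[, 2], 1]; y2 <- nd[tri[, 2], 2]
  x3 <- nd[tri[, 3], 1]; y3 <- nd[tri[, 3], 2]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2)   # gradient numerators
  by <- cbind(x3 - x2, x1 - x3, x2 - x1)
  ii <- jj <- vv <- vector("list", 9)
  s <- 1L
  for (a in 1:3) for (b in 1:3) {
    ii[[s]] <- tri[, a]; jj[[s]] <- tri[, b]
    vv[[s]] <- Dtri * (bx[, a] * bx[, b] + by[, a] * by[, b]) / (4 * area)
    s <- s + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = rep(nrow(mesh$nodes), 2))
}

#' Simulate drug release on a 2D finite-element mesh
#'
#' Solves the same dissolution-diffusion-binding system as
#' [simulate_particle()] with P1 finite elements and a lumped mass matrix
#' on a triangulated (possibly elliptical) cross-section.  The perfect sink
#' is imposed strongly on the outer-boundary nodes.
#'
#' @param mesh A [build_mesh()] mesh.
#' @param p A [model_parameters()] object.
#' @param opts A [solver_options()] object (grid fields are ignored).
#' @param c_init,b0_init,b1_init Optional scalar overrides of the initial
#'   fields (in the units implied by `p$normalization`); defaults are the
#'   standard initial data `b0 = B0`, `c = 0`, `b1 = B1`.
#' @return A `coreshell_sim` object (see [simulate_particle()]) with
#'   `method = "fem2d"` and the mesh in `$mesh`; its `final_state` is an
#'   `fem_state` with full-length nodal fields `c`, `b0`, `b1`.
#' @export
simulate_particle_fem <- function(mesh, p, opts = solver_options(),
                                  c_init = 0, b0_init = NULL, b1_init = NULL) {
  stopifnot(inherits(mesh, "mesh2d"), inherits(p, "model_parameters"),
            inherits(opts, "solver_options"))
  geom <- mesh$geometry
  sc <- .internal_scales(p, geom)
  if (is.null(b0_init)) b0_init <- sc$b0_init
  if (is.null(b1_init)) b1_init <- p$B1

  n <- nrow(mesh$nodes)
  Dtri <- ifelse(mesh$region == "core", p$D0, p$D1)
  K <- .assemble_stiffness(mesh, Dtri)
  lc <- mesh$lump_core * .um_to_cm^2
  ls <- mesh$lump_shell * .um_to_cm^2
  m <- lc + ls
  idxc <- which(lc > 0)                  # nodes carrying undissolved drug
  idxs <- which(ls > 0)                  # nodes carrying bound drug
  dir <- which(mesh$boundary)
  free <- which(!mesh$boundary)

  cc0 <- rep(c_init, n); cc0[dir] <- 0
  b00 <- numeric(n); b00[idxc] <- b0_init
  b10 <- numeric(n); b10[idxs] <- b1_init
  y0 <- c(cc0, b00[idxc], b10[idxs], 0)
  i_b0 <- n + seq_along(idxc)
  i_b1 <- n + length(idxc) + seq_along(idxs)

  beta <- p$beta; alpha <- p$alpha; Sint <- sc$S; k <- p$k
  wc <- lc[idxc] / m[idxc]
  ws <- ls[idxs] / m[idxs]

  rhs <- function(t, y, parms) {
    cc <- y[1:n]
    b0 <- y[i_b0]
    b1 <- y[i_b1]
    Kc <- as.numeric(K %*% cc)
    dc <- -Kc / m
    g <- beta * pmax(b0, 0)^alpha * (Sint - cc[idxc])
    dc[idxc] <- dc[idxc] + g * wc
    db1 <- k * cc[idxs]
    dc[idxs] <- dc[idxs] - db1 * ws
    dc[dir] <- 0
    list(c(dc, -g, db1, -sum(Kc[dir])))
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
  Q <- sol[, ncol(sol)]

  mass_g <- (cc %*% m + b0 %*% lc[idxc] + b1 %*% ls[idxs]) * sc$conc_scale
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
    b0f <- numeric(n); b0f[idxc] <- b0[i, ]
    b1f <- numeric(n); b1f[idxs] <- b1[i, ]
    structure(list(t = times_s[i], c = cc[i, ], b0 = b0f, b1 = b1f),
              class = "fem_state")
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
         mesh = mesh, geometry = geom, parameters = p, options = opts,
         method = "fem2d"),
    class = "coreshell_sim")
}

#' Eccentricity sweep of the shape-sensitivity study
#'
#' Simulates area-preserving elliptical perturbations of the reference
#' cross-section over a sequence of eccentricities and tabulates the final
#' released percentage and the release time.  Flattening the particle at
#' constant core and shell area thins the shell at the flat ends, reduces
#' the permanently bound fraction, and therefore increases the released
#' percentage while leaving the (dissolution-controlled) release time
#' essentially unchanged.
#'
#' @param lambdas Eccentricities in `[0, 0.95]` (0 = circle).
#' @param p A [model_parameters()] object.
#' @param geom The circular reference [particle_geometry()].
#' @param opts A [solver_options()] object.
#' @param h_max Mesh size passed to [build_mesh()].
#' @param threshold Plateau threshold for [release_time()].
#' @return A data frame with columns `lambda`, `released_pct_final`,
#'   `t_r_h`.
#' @export
eccentricity_sweep <- function(lambdas, p, geom = particle_geometry(),
                               opts = solver_options(), h_max = 0.16,
                               threshold = 0.1) {
  if (any(lambdas < 0 | lambdas > 0.95))
    stop("'lambdas' must lie in [0, 0.95]")
  rows <- lapply(lambdas, function(lam) {
    mesh <- build_mesh(make_ellipse(geom, lam), h_max = h_max)
    sim <- simulate_particle_fem(mesh, p, opts)
    data.frame(lambda = lam,
               released_pct_final = sim$release$Mrel_pct[nrow(sim$release)],
               t_r_h = release_time(sim, threshold = threshold))
  })
  do.call(rbind, rows)
}
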