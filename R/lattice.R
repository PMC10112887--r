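#' Lattice specification
#'
#' Defines the rectangular simulation box: `nx * ny * nz` grid points with
#' spacing `a0`, periodic in x and y, bounded in z (no-flux boundaries).
#'
#' @param nx,ny,nz Grid points per axis. Defaults follow the production box
#'   (320 x 320 x 64).
#' @param a0 Grid spacing (dimensionless length unit, default 1).
#' @return An object of class `lattice_spec` with fields `nx`, `ny`, `nz`,
#'   `a0` and derived box lengths `Lx`, `Ly`, `Lz`.
#' @export
lattice_spec <- function(nx = 320L, ny = 320L, nz = 64L, a0 = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 8L)) stop("lattice must have at least 8 grid points per axis")
  if (!is.numeric(a0) || a0 <= 0) stop("grid spacing a0 must be positive")
  structure(list(nx = nx, ny = ny, nz = nz, a0 = a0,
                 Lx = nx * a0, Ly = ny * a0, Lz = nz * a0),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d x %d, a0 = %g (periodic x/y, bounded z)\n",
              x$nx, x$ny, x$nz, x$a0))
  invisible(x)
}

gdim <- function(lattice) c(lattice$nx, lattice$ny, lattice$nz)

#' Minimum-image displacement on a periodic axis
#'
#' @param dx Raw coordinate difference(s).
#' @param L Box length of the periodic axis.
#' @return Wrapped displacement in `(-L/2, L/2]`.
#' @export
wrap_delta <- function(dx, L) dx - L * round(dx / L)

#' Periodic in-plane (or 3D) distance
#'
#' Distance with minimum-image convention in x and y; z (if given) is treated
#' as a bounded axis.
#'
#' @param p,q Numeric vectors of length 2 or 3 (or matrices with points in rows).
#' @param lattice A [lattice_spec()].
#' @return Euclidean distance(s).
#' @export
periodic_distance <- function(p, q, lattice) {
  p <- rbind(p); q <- rbind(q)
  dx <- wrap_delta(p[, 1] - q[, 1], lattice$Lx)
  dy <- wrap_delta(p[, 2] - q[, 2], lattice$Ly)
  d2 <- dx^2 + dy^2
  if (ncol(p) >= 3) d2 <- d2 + (p[, 3] - q[, 3])^2
  sqrt(d2)
}

#' Static substrate field
#'
#' The substrate is a static phase field occupying the bottom of the box,
#' with the diffuse-interface profile
#' `phi_w(z) = (1 - tanh(2 (z - z_surface) / width)) / 2`,
#' so the midpoint `phi_w = 0.5` sits on the surface plane `z_surface`. The
#' field depends on z only and never changes in time.
#'
#' @param lattice A [lattice_spec()].
#' @param interface_width Diffuse interface width (length units, >= 2 a0).
#' @param z_surface Height of the substrate surface plane; default `4 * a0`
#'   keeps cell fields clear of the box floor.
#' @return An object of class `substrate_field` holding the z profile and the
#'   discrete derivative vectors used by the energy and its variation.
#' @export
make_substrate <- function(lattice, interface_width = 2 * lattice$a0,
                           z_surface = 4 * lattice$a0) {
  a0 <- lattice$a0
  if (interface_width < 2 * a0) stop("substrate interface_width must be >= 2 * a0")
  if (interface_width > lattice$nz * a0 / 4)
    stop("invalid geometry: substrate interface_width exceeds nz * a0 / 4")
  nz <- lattice$nz
  z_ext <- (-1:nz) * a0  # analytic extension one plane beyond each boundary
  p_ext <- 0.5 * (1 - tanh(2 * (z_ext - z_surface) / interface_width))
  profile <- p_ext[2:(nz + 1)]
  # discrete forward differences (length nz + 1, first entry below the box)
  # and second differences of the extended profile: exactly what the discrete
  # energy and its adjoint variation use
  dz_fwd <- p_ext[2:(nz + 2)] - p_ext[1:(nz + 1)]
  d2 <- p_ext[3:(nz + 2)] + p_ext[1:nz] - 2 * profile
  structure(list(profile = profile, phiw2 = profile^2, dz_fwd = dz_fwd, d2z = d2,
                 width = interface_width, z_surface = z_surface),
            class = "substrate_field")
}

#' Evaluate the substrate profile at arbitrary heights
#'
#' @param substrate A [make_substrate()] result.
#' @param z Heights (length units).
#' @return `phi_w(z)`.
#' @export
substrate_profile <- function(substrate, z) {
  0.5 * (1 - tanh(2 * (z - substrate$z_surface) / substrate$width))
}

# ---- cell subdomain bookkeeping ---------------------------------------------

# support threshold below which a cell field is treated as exactly zero
.support_thr <- 1e-5

new_cell_field <- function(id, lattice, center, R0, lambda, theta = 0) {
  a0 <- lattice$a0
  pad <- subdomain_pad(lambda, a0)
  # support radius where the seeded tanh profile falls below the threshold
  rsup <- R0 + lambda * atanh(1 - 2 * .support_thr)
  half <- min(ceiling((rsup + pad * a0) / a0), subdomain_cap(R0, lambda, a0))
  hx <- min(half, (lattice$nx - 3L) %/% 2L)
  hy <- min(half, (lattice$ny - 3L) %/% 2L)
  cx <- round(center[1] / a0); cy <- round(center[2] / a0); cz <- round(center[3] / a0)
  off <- c(cx - hx, cy - hy, max(0L, cz - half))
  sdim <- c(2L * hx + 1L, 2L * hy + 1L,
            min(lattice$nz, cz + half + 1L) - off[3])
  xs <- (off[1] + 0:(sdim[1] - 1)) * a0
  ys <- (off[2] + 0:(sdim[2] - 1)) * a0
  zs <- (off[3] + 0:(sdim[3] - 1)) * a0
  r <- sqrt(outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
                  (zs - center[3])^2, `+`))
  phi <- 0.5 * (1 - tanh((r - R0) / lambda))
  phi[phi < .support_thr] <- 0
  cell <- list(id = as.integer(id), phi = array(phi, dim = sdim),
               offset = as.integer(off), theta = theta,
               com = center, extruded = FALSE, removed = FALSE)
  class(cell) <- "cell_field"
  cell
}

subdomain_pad <- function(lambda, a0) as.integer(ceiling(2 * lambda / a0)) + 1L

# Half-extent cap of a cell subdomain.  The linear substrate-adhesion coupling
# induces a thin wetting film on the whole substrate plane; fields are evolved
# on moving boxes of bounded size, truncating that film far from the cell
# body.  The cap leaves room for a fully spread cell (footprint ~ 2^(1/3) R0)
# plus its diffuse tails down to the support threshold (~ 6 lambda).
subdomain_cap <- function(R0, lambda, a0) {
  as.integer(ceiling((1.3 * R0 + 6 * lambda) / a0))
}

# Re-box a cell field.  The box is sized from the support bounding box plus
# padding (up to the cap, and always strictly smaller than the periodic axes
# so the zero halo stays exact), and is centered on the cell BODY
# (phi >= 0.5) since the diffuse tails and the substrate wetting film pin the
# support at the box faces once the cap is reached.  Re-boxing is hysteretic
# (recenter only on a drift of >= 2 grid points, shrink only when clearly
# oversized) so quasi-static cells keep a fixed box and the evolution stays a
# consistent finite-dimensional gradient flow between re-boxing events.
regrow_cell <- function(cell, lattice, pad, cap = NULL, stats = NULL) {
  sdim <- as.integer(dim(cell$phi))
  gd <- gdim(lattice)
  if (is.null(stats)) stats <- cpp_field_stats(cell$phi, sdim, .support_thr)
  sup <- as.integer(stats[5:10])
  if (sup[2] < 0) return(cell)  # empty field: leave as is
  want <- sup[c(2, 4, 6)] - sup[c(1, 3, 5)] + 1L + 2L * pad
  if (!is.null(cap)) want <- pmin(want, 2L * cap + 1L)
  want <- pmin(want, c(gd[1] - 3L, gd[2] - 3L, gd[3]))
  # center the box on the cell's center of mass
  ctr <- cell$offset + stats[1:3] / stats[4]
  cur_ctr <- cell$offset + (sdim - 1) / 2
  new_off <- cell$offset
  new_dim <- sdim
  for (ax in 1:3) {
    resize <- want[ax] > sdim[ax] || want[ax] < sdim[ax] - 4L
    recenter <- abs(ctr[ax] - cur_ctr[ax]) >= 2
    if (resize || recenter) {
      new_dim[ax] <- if (resize) want[ax] else sdim[ax]
      new_off[ax] <- as.integer(round(ctr[ax] - (new_dim[ax] - 1) / 2))
    }
  }
  # clamp z to the lattice, wrap x/y offsets into the box
  new_off[3] <- max(0L, min(new_off[3], gd[3] - new_dim[3]))
  new_off[1] <- new_off[1] %% gd[1]
  new_off[2] <- new_off[2] %% gd[2]
  if (identical(new_off, cell$offset) && identical(new_dim, sdim)) return(cell)
  phi <- cpp_crop_pad(cell$phi, sdim, cell$offset, new_off, new_dim, gd)
  cell$phi <- array(phi, dim = new_dim)
  cell$offset <- new_off
  cell
}

#' Center of mass of a cell field
#'
#' The phi-weighted mean position. The subdomain is contiguous, so the mean is
#' computed in subdomain coordinates and shifted by the (possibly wrapped)
#' offset, which unwraps the periodic seam in x/y automatically; the result is
#' wrapped back into the box.
#'
#' @param cell A cell field (element of `state$cells`).
#' @param lattice A [lattice_spec()].
#' @return Numeric length-3 center of mass, x/y in `[0, L)`.
#' @export
center_of_mass <- function(cell, lattice) {
  m <- cpp_com(cell$phi, dim(cell$phi))
  if (m[4] <= 0) stop("degenerate cell: field has no mass")
  pos <- (m[1:3] / m[4] + cell$offset) * lattice$a0
  pos[1] <- pos[1] %% lattice$Lx
  pos[2] <- pos[2] %% lattice$Ly
  pos
}

#' Expand a cell field onto the full lattice
#'
#' Mostly a testing/export aid: subdomain storage is an implementation detail
#' and this reconstructs the equivalent full-lattice array.
#'
#' @inheritParams center_of_mass
#' @return A `nx x ny x nz` array.
#' @export
field_on_lattice <- function(cell, lattice) {
  g <- numeric(prod(gdim(lattice)))
  cpp_scatter_add(g, gdim(lattice), cell$phi, dim(cell$phi), cell$offset, 1L)
  array(g, dim = gdim(lattice))
}

# Sum fields over live (non-removed) cells: S = sum phi_j, S2 = sum phi_j^2.
state_sum_fields <- function(state) {
  gd <- gdim(state$lattice)
  S <- numeric(prod(gd)); S2 <- numeric(prod(gd))
  for (cell in state$cells) {
    if (cell$removed) next
    cpp_scatter_add2(S, S2, gd, cell$phi, dim(cell$phi), cell$offset)
  }
  list(S = S, S2 = S2)
}

#' Initialize a monolayer of spherical droplets on the substrate
#'
#' Cells are seeded on a square lattice in the plane, as diffuse spheres of
#' radius `R0` tangent to the substrate surface, with polarity angles drawn
#' uniformly from `[-pi, pi]`. A short passive relaxation (see
#' [run_simulation()]) lets the droplets spread into their equilibrium shape.
#'
#' @param lattice A [lattice_spec()].
#' @param n_cells Number of cells; must fit on a square lattice with spacing
#'   >= 2 R0.
#' @param R0 Initial cell radius (>= 4 a0).
#' @param seed Integer seed for the polarity angles and jitter.
#' @param lambda Interface width used for the seeded profile (and substrate).
#' @param jitter Uniform in-plane jitter half-width applied to seed positions.
#' @param substrate Optional pre-built [make_substrate()]; default built with
#'   width `lambda`.
#' @return A `monolayer_state` object.
#' @export
initialize_monolayer <- function(lattice, n_cells, R0, seed = NULL,
                                 lambda = 2 * lattice$a0, jitter = 0,
                                 substrate = NULL) {
  if (R0 < 4 * lattice$a0) stop("R0 must be at least 4 * a0")
  if (!is.null(seed)) set.seed(seed)
  kx <- ceiling(sqrt(n_cells))
  ky <- ceiling(n_cells / kx)
  sx <- lattice$Lx / kx; sy <- lattice$Ly / ky
  if (min(sx, sy) < 2 * R0)
    stop("invalid geometry: ", n_cells, " cells do not fit with spacing >= 2 R0")
  if (is.null(substrate)) substrate <- make_substrate(lattice, interface_width = lambda)
  z0 <- substrate$z_surface + R0
  idx <- seq_len(n_cells) - 1L
  cx <- (idx %% kx + 0.5) * sx
  cy <- (idx %/% kx + 0.5) * sy
  if (jitter > 0) {
    cx <- cx + stats::runif(n_cells, -jitter, jitter)
    cy <- cy + stats::runif(n_cells, -jitter, jitter)
  }
  thetas <- stats::runif(n_cells, -pi, pi)
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cells[[i]] <- new_cell_field(i, lattice, c(cx[i], cy[i], z0), R0, lambda, thetas[i])
    cells[[i]]$com <- center_of_mass(cells[[i]], lattice)
  }
  structure(list(lattice = lattice, cells = cells, substrate = substrate,
                 R0 = R0, lambda = lambda, step = 0L, time = 0,
                 rng_state = .Random.seed),
            class = "monolayer_state")
}

#' @export
print.monolayer_state <- function(x, ...) {
  n_ex <- sum(vapply(x$cells, function(c) isTRUE(c$extruded), logical(1)))
  cat(sprintf("<monolayer_state> %d cells (%d extruded), step %d, box %g x %g x %g\n",
              length(x$cells), n_ex, x$step, x$lattice$Lx, x$lattice$Ly, x$lattice$Lz))
  invisible(x)
}

# positions of live cells as a matrix (rows = cells), NA for removed ones
state_coms <- function(state) {
  t(vapply(state$cells, function(c) if (c$removed) rep(NA_real_, 3) else c$com,
           numeric(3)))
}
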