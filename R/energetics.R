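#' Energetic parameters of the multi-phase-field free energy
#'
#' The free energy of the monolayer is, per cell i,
#' \deqn{F = \sum_i \frac{\gamma}{\lambda}\int 4\phi_i^2(1-\phi_i)^2 +
#'   \lambda^2|\nabla\phi_i|^2 \, dx + \sum_i \mu\Big(1 -
#'   \frac{1}{V_0}\int\phi_i^2\,dx\Big)^2 + \sum_i\sum_{j\ne i}
#'   \frac{\kappa_{cc}}{\lambda}\int \phi_i^2\phi_j^2\,dx +
#'   \sum_i\sum_{j\ne i} \omega_{cc}\lambda^2 \int
#'   \nabla\phi_i\cdot\nabla\phi_j\,dx + \sum_i \frac{\kappa_{cw}}{\lambda}
#'   \int\phi_i^2\phi_w^2\,dx + \sum_i \omega_{cw}\lambda^2\int
#'   \nabla\phi_i\cdot\nabla\phi_w\,dx,}
#' a Cahn-Hilliard interface term (stiffness `gamma`, width `lambda`), a soft
#' volume constraint (compressibility `mu`, target `V0 = 4/3 pi R0^3`),
#' quadratic overlap repulsion (`kappa_cc`, `kappa_cw`) and gradient-coupling
#' adhesion (`omega_cc`, `omega_cw`) against the other cells and the static
#' substrate field. The gradient coupling is attractive as written: where two
#' diffuse interfaces overlap their gradients are anti-parallel, so the term
#' is negative and deepens with overlap.
#'
#' `Omega = omega_cc / omega_cw` is the key control ratio; if `Omega` is
#' supplied, `omega_cc` is derived from it.
#'
#' @param gamma Interface stiffness (> 0).
#' @param lambda Interface width (length, >= 2 a0 for resolvability).
#' @param mu Compressibility modulus (> 0).
#' @param R0 Cell radius defining the target volume.
#' @param V0 Target volume; default `4/3 pi R0^3`.
#' @param kappa_cc,kappa_cw Cell-cell and cell-wall repulsion strengths (> 0).
#' @param omega_cc,omega_cw Cell-cell and cell-wall adhesion strengths (>= 0).
#' @param Omega Optional adhesion ratio `omega_cc/omega_cw`; overrides
#'   `omega_cc`.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(gamma = 0.08, lambda = 2, mu = 300, R0 = 8,
                          V0 = 4 / 3 * pi * R0^3,
                          kappa_cc = 0.1, kappa_cw = 0.05,
                          omega_cw = 0.0025, omega_cc = 0.4 * omega_cw,
                          Omega = NULL) {
  if (!is.null(Omega)) omega_cc <- Omega * omega_cw
  stopifnot(gamma > 0, lambda > 0, mu > 0, V0 > 0, kappa_cc > 0, kappa_cw > 0)
  if (omega_cc < 0 || omega_cw < 0) stop("adhesion strengths must be >= 0")
  structure(list(gamma = gamma, lambda = lambda, mu = mu, R0 = R0, V0 = V0,
                 kappa_cc = kappa_cc, kappa_cw = kappa_cw,
                 omega_cc = omega_cc, omega_cw = omega_cw),
            class = "energy_params")
}

#' Adhesion ratio Omega
#'
#' @param params An [energy_params()].
#' @return `omega_cc / omega_cw` (Inf if `omega_cw` is 0 and `omega_cc` > 0).
#' @export
adhesion_ratio <- function(params) {
  if (params$omega_cw == 0) return(if (params$omega_cc == 0) NaN else Inf)
  params$omega_cc / params$omega_cw
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(paste0("<energy_params> gamma=%g lambda=%g mu=%g V0=%.1f ",
                     "kcc=%g occ=%g kcw=%g ocw=%g (Omega=%.3g)\n"),
              x$gamma, x$lambda, x$mu, x$V0, x$kappa_cc, x$omega_cc,
              x$kappa_cw, x$omega_cw, adhesion_ratio(x)))
  invisible(x)
}

#' Volume measure of a cell
#'
#' The squared-field integral `int phi^2 dx` that enters the soft volume
#' constraint; for a relaxed droplet it approximates the sharp-interface
#' volume.
#'
#' @param cell A cell field.
#' @param lattice A [lattice_spec()].
#' @return Scalar volume proxy.
#' @export
cell_volume_proxy <- function(cell, lattice) {
  sum(cell$phi^2) * lattice$a0^3
}

#' Free energy of a monolayer state, term by term
#'
#' Evaluates every term of the free energy by midpoint quadrature on the
#' lattice. Gradient-squared terms use forward differences, making the
#' 7-point-Laplacian functional derivative their exact discrete adjoint.
#'
#' @param state A `monolayer_state`.
#' @param params An [energy_params()].
#' @return A list of class `energy_breakdown` with the six terms and `total`.
#' @export
free_energy <- function(state, params) {
  lat <- state$lattice; a0 <- lat$a0
  if (params$lambda < 2 * a0) stop("lambda must be >= 2 * a0 for resolvability")
  sums <- state_sum_fields(state)
  gd <- gdim(lat)
  lam <- params$lambda / a0  # interface width in grid units
  quad <- a0^3
  e <- c(cahn_hilliard = 0, volume = 0, cc_repulsion = 0, cc_adhesion = 0,
         cw_repulsion = 0, cw_adhesion = 0)
  for (cell in state$cells) {
    if (cell$removed) next
    if (any(!is.finite(cell$phi))) stop("numerical state error: non-finite field values")
    sdim <- dim(cell$phi)
    S2sub <- cpp_gather(sums$S2, gd, cell$offset, sdim)
    Shalo <- cpp_gather(sums$S, gd, cell$offset - 1L, sdim + 2L)
    raw <- cpp_energy_sums(cell$phi, sdim, cell$offset[3],
                           S2sub, Shalo,
                           state$substrate$phiw2, state$substrate$dz_fwd)
    Vi <- cell_volume_proxy(cell, lat)
    e["cahn_hilliard"] <- e["cahn_hilliard"] +
      params$gamma / params$lambda * (raw[1] + lam^2 * raw[2]) * quad
    e["volume"] <- e["volume"] + params$mu * (1 - Vi / params$V0)^2
    e["cc_repulsion"] <- e["cc_repulsion"] +
      params$kappa_cc / params$lambda * raw[3] * quad
    e["cc_adhesion"] <- e["cc_adhesion"] +
      params$omega_cc * lam^2 * raw[4] * quad
    e["cw_repulsion"] <- e["cw_repulsion"] +
      params$kappa_cw / params$lambda * raw[5] * quad
    e["cw_adhesion"] <- e["cw_adhesion"] +
      params$omega_cw * lam^2 * raw[6] * quad
  }
  out <- as.list(e)
  out$total <- sum(e)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown>\n")
  for (nm in setdiff(names(x), "total"))
    cat(sprintf("  %-14s %+.6g\n", nm, x[[nm]]))
  cat(sprintf("  %-14s %+.6g\n", "total", x$total))
  invisible(x)
}

# Precompute the per-step global fields every functional derivative needs.
energy_cache <- function(state) {
  sums <- state_sum_fields(state)
  gd <- gdim(state$lattice)
  list(S = sums$S, S2 = sums$S2, lapS = cpp_lap_global(sums$S, gd))
}

#' Functional derivative of the free energy for one cell
#'
#' Returns `dF/dphi_i` evaluated on the cell's subdomain: the analytic
#' variation of every term of the free energy (double-well + interface
#' Laplacian, volume constraint, overlap repulsion against cells and wall,
#' Laplacian adhesion couplings against the other cells and the substrate).
#' It is the exact discrete adjoint of [free_energy()], which a
#' finite-difference variation test pins down.
#'
#' @param state A `monolayer_state`.
#' @param params An [energy_params()].
#' @param cell_id Integer id of the cell.
#' @param cache Optional precomputed global-field cache (internal use).
#' @return A subdomain-shaped array with attributes `offset` (0-based global
#'   offset) and `cell_id`.
#' @export
functional_derivative <- function(state, params, cell_id, cache = NULL) {
  ids <- vapply(state$cells, `[[`, integer(1), "id")
  pos <- match(as.integer(cell_id), ids)
  if (is.na(pos)) stop("unknown cell id: ", cell_id)
  cell <- state$cells[[pos]]
  if (cell$removed) stop("cell ", cell_id, " has been removed from the dynamics")
  if (is.null(cache)) cache <- energy_cache(state)
  lat <- state$lattice; a0 <- lat$a0; gd <- gdim(lat)
  sdim <- dim(cell$phi)
  S2sub <- cpp_gather(cache$S2, gd, cell$offset, sdim)
  lapSsub <- cpp_gather(cache$lapS, gd, cell$offset, sdim)
  lapphi <- cpp_lap_sub(cell$phi, sdim)
  Vi <- cell_volume_proxy(cell, lat)
  p <- params
  out <- cpp_func_deriv(cell$phi, lapphi, sdim, cell$offset[3],
                        S2sub, lapSsub,
                        state$substrate$phiw2, state$substrate$d2z,
                        8 * p$gamma / p$lambda,
                        2 * p$gamma * p$lambda / a0^2,
                        4 * p$mu / p$V0 * (1 - Vi / p$V0),
                        4 * p$kappa_cc / p$lambda,
                        2 * p$omega_cc * p$lambda^2 / a0^2,
                        2 * p$kappa_cw / p$lambda,
                        p$omega_cw * p$lambda^2 / a0^2)
  out <- array(out, dim = sdim)
  attr(out, "offset") <- cell$offset
  attr(out, "cell_id") <- cell$id
  out
}
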