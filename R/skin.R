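#' Build the 1-D finite-volume grid for one application site
#'
#' The patch-skin stack is laterally uniform with no-flux lateral
#' boundaries, so the transport problem is exactly one-dimensional. The
#' grid covers patch + stratum corneum + viable epidermis + equivalent
#' dermis (top to bottom); every layer interface coincides with a cell
#' face, and cell widths are geometrically graded towards both ends of each
#' layer so that the steep potential gradients at the interfaces are
#' resolved.
#'
#' @param geometry An `ft_skin_geometry` list (see [derive_skin_geometry()]).
#' @param n_cells Cells per layer (>= 4).
#' @param interface_refinement Geometric width ratio away from each
#'   interface; 1 gives uniform cells within each layer.
#' @param include_patch If `FALSE`, builds the grid of a site whose patch
#'   has been removed (stratum corneum face becomes the top).
#' @return A list of class `ft_grid` with `layer` (per-cell id), `width`,
#'   `center`, `face` (length n+1) in metres.
#' @export
build_grid <- function(geometry, n_cells = 25, interface_refinement = 1.15,
                       include_patch = TRUE) {
  stopifnot(n_cells >= 4)
  layers <- c(patch = geometry$d_patch, sc = geometry$d_sc,
              vep = geometry$d_vep, edm = geometry$d_edm)
  if (!include_patch) layers <- layers[-1]
  if (any(!is.finite(layers)) || any(layers <= 0)) {
    stop("Degenerate layer thickness: all layers must be > 0.")
  }
  width <- numeric(0)
  layer <- character(0)
  for (nm in names(layers)) {
    w <- graded_widths(layers[[nm]], n_cells, interface_refinement)
    width <- c(width, w)
    layer <- c(layer, rep(nm, length(w)))
  }
  face <- c(0, cumsum(width))
  # guard against accumulation error: faces must hit the interfaces exactly
  face[length(face)] <- sum(layers)
  structure(
    list(layer = layer, width = width,
         center = (face[-1] + face[-length(face)]) / 2, face = face),
    class = "ft_grid"
  )
}

# symmetric two-sided geometric grading: smallest cells at both layer ends
graded_widths <- function(thickness, n, ratio) {
  half <- n %/% 2
  left <- ratio^(0:(half - 1))
  w <- if (n %% 2 == 0) c(left, rev(left)) else c(left, ratio^half, rev(left))
  thickness * w / sum(w)
}

# per-cell diffusivity and capacity from the transport constants
cell_transport <- function(grid, transport) {
  d <- c(patch = transport$d_patch_m2_s,
         sc = transport$d_epidermis_m2_s,
         vep = transport$d_epidermis_m2_s,
         edm = transport$d_dermis_m2_s)
  k <- c(patch = transport$k_patch,
         sc = transport$k_epidermis,
         vep = transport$k_epidermis,
         edm = transport$k_dermis)
  list(d = unname(d[grid$layer]), k = unname(k[grid$layer]))
}

#' Initialize the drug state of a site
#'
#' The patch cells carry the uniform loading concentration
#' `load / (area x thickness)` expressed as drug potential (`psi = c / K`);
#' all skin cells start at zero, reflecting application at a fresh location.
#'
#' @param grid An `ft_grid` from [build_grid()].
#' @param transport Transport constants (`config$transport`).
#' @param patch_load_ng Fentanyl load in ng (printed: 12.6 mg).
#' @param patch_area_m2 Patch area in m^2.
#' @return Numeric vector `psi` (ng/ml potential), one entry per cell.
#' @export
initialize_site <- function(grid, transport, patch_load_ng, patch_area_m2) {
  psi <- numeric(length(grid$width))
  in_patch <- grid$layer == "patch"
  if (any(in_patch)) {
    d_patch <- sum(grid$width[in_patch])
    conc_ng_m3 <- patch_load_ng / (patch_area_m2 * d_patch)
    psi[in_patch] <- conc_ng_m3 * 1e-6 / transport$k_patch  # ng/ml potential
  }
  psi
}

# face conductances G [m/s]: interior faces by series-harmonic composition of
# D*K over the adjoining half-cells (this enforces flux continuity and the
# partition jump in concentration); top face no-flux; bottom face couples the
# half-cell of the last dermis cell to the Dirichlet plasma potential
face_conductance <- function(grid, transport) {
  tr <- cell_transport(grid, transport)
  n <- length(grid$width)
  half <- grid$width / 2
  g_int <- 1 / (half[-n] / (tr$d[-n] * tr$k[-n]) + half[-1] / (tr$d[-1] * tr$k[-1]))
  g_bottom <- tr$d[n] * tr$k[n] / half[n]
  list(interior = g_int, bottom = g_bottom, k = tr$k)
}

#' Finite-volume right-hand side of the potential diffusion equation
#'
#' Semi-discrete form of `d(K psi)/dt = d/dx (D K dpsi/dx)` on the site
#' grid: no-flux at the top face, Dirichlet potential `bottom_psi`
#' (= plasma concentration / dermis capacity) at the bottom face.
#'
#' @param psi Potential per cell (ng/ml).
#' @param grid An `ft_grid`.
#' @param transport Transport constants.
#' @param bottom_psi Potential imposed at the bottom boundary (ng/ml).
#' @return `dpsi/dt` per cell (ng/ml/s).
#' @export
diffusion_rhs <- function(psi, grid, transport, bottom_psi = 0) {
  op <- site_operator(grid, transport)
  drop(op$m %*% psi) + op$b * bottom_psi
}

# sparse operator: dpsi/dt = m psi + b * bottom_psi; flux (ng m^-2 s^-1,
# positive into blood) = fq %*% psi - f0 * bottom_psi
site_operator <- function(grid, transport) {
  fc <- face_conductance(grid, transport)
  n <- length(grid$width)
  cap <- fc$k * grid$width  # cell capacity per unit area
  g <- fc$interior
  lower <- g / cap[-1]
  upper <- g / cap[-n]
  diag_main <- numeric(n)
  diag_main[-n] <- diag_main[-n] - g / cap[-n]
  diag_main[-1] <- diag_main[-1] - g / cap[-1]
  diag_main[n] <- diag_main[n] - fc$bottom / cap[n]
  m <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(lower, diag_main, upper))
  b <- numeric(n)
  b[n] <- fc$bottom / cap[n]
  fq <- numeric(n)
  fq[n] <- fc$bottom * 1e6  # psi in ng/ml -> flux in ng m^-2 s^-1
  list(m = m, b = b, fq = fq, f0 = fc$bottom * 1e6, cap = cap)
}

#' Diffusive flux delivered to blood at the bottom boundary
#'
#' @inheritParams diffusion_rhs
#' @return Flux density in ng m^-2 s^-1, positive into blood (may be
#'   transiently negative if plasma exceeds the dermal boundary potential).
#' @export
flux_out <- function(psi, grid, transport, bottom_psi = 0) {
  op <- site_operator(grid, transport)
  drop(op$fq %*% psi) - op$f0 * bottom_psi
}

#' Total drug mass on the site
#'
#' @inheritParams diffusion_rhs
#' @param patch_area_m2 Site area in m^2.
#' @return Mass in ng, split by layer.
#' @export
site_mass <- function(psi, grid, transport, patch_area_m2) {
  tr <- cell_transport(grid, transport)
  cell_ng <- tr$k * psi * 1e6 * grid$width * patch_area_m2
  c(patch = sum(cell_ng[grid$layer == "patch"]),
    skin = sum(cell_ng[grid$layer != "patch"]),
    total = sum(cell_ng))
}

#' Solve the isolated-site diffusion problem
#'
#' Integrates the site in isolation with a *fixed* bottom potential, either
#' by backward-Euler time stepping (the production scheme) or by the matrix
#' exponential of the semi-discrete operator (`method = "expm"`), which is
#' exact in time and isolates the spatial discretization error.
#'
#' @inheritParams diffusion_rhs
#' @param times Output times (s).
#' @param method `"expm"` (default) or `"be"`.
#' @param dt_s Backward-Euler step (s), for `method = "be"`.
#' @return Matrix of psi, one row per output time.
#' @export
solve_site <- function(psi, grid, transport, bottom_psi = 0, times,
                       method = c("expm", "be"), dt_s = 60) {
  method <- match.arg(method)
  op <- site_operator(grid, transport)
  n <- length(psi)
  out <- matrix(NA_real_, length(times), n)
  if (method == "expm") {
    # affine system: steady state psi_inf solves m psi_inf = -b psi_b
    psi_inf <- if (bottom_psi == 0) numeric(n) else
      as.numeric(Matrix::solve(op$m, -op$b * bottom_psi))
    for (i in seq_along(times)) {
      e <- Matrix::expm(op$m * times[i])
      out[i, ] <- psi_inf + as.numeric(e %*% (psi - psi_inf))
    }
  } else {
    t_now <- 0
    x <- psi
    cum <- 0  # ng m^-2 through the bottom face (discretely exact for BE)
    cum_out <- numeric(length(times))
    lu <- Matrix::lu(Matrix::Diagonal(n) - dt_s * op$m)
    rhs_b <- dt_s * op$b * bottom_psi
    for (i in seq_along(times)) {
      while (t_now < times[i] - 1e-9) {
        x <- as.numeric(Matrix::solve(lu, x + rhs_b))
        cum <- cum + dt_s * (drop(op$fq %*% x) - op$f0 * bottom_psi)
        t_now <- t_now + dt_s
      }
      out[i, ] <- x
      cum_out[i] <- cum
    }
    attr(out, "cumulative_outflux_ng_m2") <- cum_out
  }
  out
}

#' Grid-convergence study by Richardson extrapolation
#'
#' Solves the bottom-flux functional of the default initial-value problem
#' (loaded patch, virgin skin, zero plasma) on a sequence of nested grids
#' (refinement ratio 2 in cells per layer) at a fixed evaluation time, and
#' estimates the observed convergence order and the extrapolated flux.
#' Grids whose error against the extrapolated value exceeds `tol` are
#' flagged.
#'
#' @param geometry An `ft_skin_geometry`.
#' @param transport Transport constants.
#' @param levels Number of nested grids (>= 3).
#' @param base_cells Cells per layer of the coarsest grid.
#' @param t_eval_h Evaluation time (h).
#' @param interface_refinement Grading factor passed to [build_grid()].
#' @param tol Relative error tolerance for the flag (default 0.001 = 0.1%).
#' @return A list: `table` (tibble with cells, flux, rel. error vs
#'   extrapolate, flag), `order` (observed), `extrapolated` flux. If the
#'   flux differences are not monotone the order is `NA` and no
#'   extrapolation is attempted.
#' @export
richardson_convergence <- function(geometry, transport, levels = 3,
                                   base_cells = 6, t_eval_h = 24,
                                   interface_refinement = 1.15,
                                   tol = 1e-3) {
  stopifnot(levels >= 3)
  cells <- base_cells * 2^(0:(levels - 1))
  if (length(unique(cells)) != levels) stop("Grid levels must be distinct.")
  t_eval <- t_eval_h * 3600
  flux <- vapply(cells, function(nc) {
    grid <- build_grid(geometry, n_cells = nc,
                       interface_refinement = interface_refinement)
    psi0 <- initialize_site(grid, transport, geometry$patch_load_ng,
                            geometry$patch_area_m2)
    psi_t <- solve_site(psi0, grid, transport, bottom_psi = 0,
                        times = t_eval, method = "expm")
    flux_out(psi_t[1, ], grid, transport, bottom_psi = 0)
  }, 0)
  nl <- levels
  d1 <- flux[nl - 2] - flux[nl - 1]
  d2 <- flux[nl - 1] - flux[nl]
  if (!is.finite(d1 / d2) || d1 / d2 <= 1) {
    return(list(
      table = tibble::tibble(cells_per_layer = cells, flux_ng_m2_s = flux,
                             rel_error = NA_real_, exceeds_tol = NA),
      order = NA_real_, extrapolated = NA_real_
    ))
  }
  order <- log2(d1 / d2)
  extrap <- flux[nl] + d2 / (d1 / d2 - 1)
  rel_err <- abs(flux - extrap) / abs(extrap)
  list(
    table = tibble::tibble(cells_per_layer = cells, flux_ng_m2_s = flux,
                           rel_error = rel_err, exceeds_tol = rel_err > tol),
    order = order, extrapolated = extrap
  )
}
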