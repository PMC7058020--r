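#' Discretized membrane deformation field
#'
#' A deformation state of the bilayer on a uniform grid: director
#' x-projections `n_u`, `n_l`, neutral-surface heights `H_u`, `H_l` and the
#' monolayer-interface height `M`, all as functions of the lateral
#' coordinate `x`.  Directors and surface normals of both leaflets point
#' towards the monolayer interface, so the linearized tilt is
#' `t_u = n_u - dH_u/dx` for the upper and `t_l = n_l + dH_l/dx` for the
#' lower leaflet; splay is `dn/dx`; the local
#' stretching `alpha` is eliminated through the volumetric
#' incompressibility condition
#' `alpha_u = (h_u - (H_u - M) - h_u^2/2 * dn_u/dx) / h_u` (and its mirror
#' for the lower leaflet).
#'
#' @param x uniform grid of lateral coordinates, nm.
#' @param n_u,n_l director x-projections per node, dimensionless.
#' @param H_u,H_l neutral-surface heights per node, nm.
#' @param M monolayer-interface height per node, nm.
#' @param layout the [region_layout()] the field belongs to.
#' @param excl_cells_u,excl_cells_l logical masks over grid cells that are
#'   occupied by a non-lipid inclusion in the respective leaflet; excluded
#'   cells never contribute elastic energy.
#' @return an object of class `deformation_field`.
#' @export
deformation_field <- function(x, n_u, n_l, H_u, H_l, M, layout,
                              excl_cells_u = logical(length(x) - 1),
                              excl_cells_l = logical(length(x) - 1)) {
  N <- length(x)
  stopifnot(length(n_u) == N, length(n_l) == N, length(H_u) == N,
            length(H_l) == N, length(M) == N,
            length(excl_cells_u) == N - 1, length(excl_cells_l) == N - 1)
  dxs <- diff(x)
  if (max(abs(dxs - dxs[1])) > 1e-9 * dxs[1]) stop("grid must be uniform")
  f <- list(x = x, dx = dxs[1], n_u = n_u, n_l = n_l,
            H_u = H_u, H_l = H_l, M = M, layout = layout,
            excl_cells_u = excl_cells_u, excl_cells_l = excl_cells_l)
  class(f) <- "deformation_field"
  f
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %d nodes, x in [%g, %g] nm, dx = %g nm\n",
              length(x$x), min(x$x), max(x$x), x$dx))
  invisible(x)
}

#' @export
as.data.frame.deformation_field <- function(x, ...) {
  data.frame(x = x$x, n_u = x$n_u, n_l = x$n_l,
             H_u = x$H_u, H_l = x$H_l, M = x$M,
             thickness = x$H_u - x$H_l)
}

# Ground-state (flat, tension-equilibrated) field of a layout without
# deformations: used as solver reference and in tests.
flat_field <- function(layout, grid) {
  x <- grid$x
  up <- layout_cell_params(layout, x, "upper")
  lo <- layout_cell_params(layout, x, "lower")
  deformation_field(x,
                    n_u = numeric(length(x)), n_l = numeric(length(x)),
                    H_u = up$h * (1 - up$alpha0),
                    H_l = -lo$h * (1 - lo$alpha0),
                    M = numeric(length(x)), layout = layout)
}

#' Renormalized elastic energy density of one monolayer
#'
#' Evaluates the quadratic monolayer energy density from the deformation
#' invariants: splay `dn/dx`, tilt, stretching deviation `alpha - alpha0`
#' and neutral-surface gradient.  The flat-state density of the phase
#' (`B/2 * J0^2`) is subtracted, so a uniform undeformed monolayer has
#' density zero and bulk phases do not contribute to integrated energies.
#'
#' @param splay director divergence, 1/nm.
#' @param tilt tilt-vector x-component, dimensionless.
#' @param dalpha stretching deviation `alpha - alpha0`, dimensionless.
#' @param dH neutral-surface slope `dH/dx`, dimensionless.
#' @param params a [monolayer_parameters()] object (or a list of vectors
#'   with the same fields).
#' @return energy per unit area, \eqn{k_B T/\mathrm{nm}^2}.
#' @export
monolayer_energy_density <- function(splay, tilt, dalpha, dH, params) {
  params$B / 2 * ((splay + params$J0)^2 - params$J0^2) +
    params$Kt / 2 * tilt^2 +
    params$Ka / 2 * dalpha^2 +
    params$sigma0 / 2 * dH^2
}

# Deformation invariants of one leaflet at cell midpoints.
# Returns list(splay, tilt, dalpha, dH, xmid, pars, active).
cell_invariants <- function(field, leaflet) {
  x <- field$x; N <- length(x); dx <- field$dx
  xmid <- (x[-1] + x[-N]) / 2
  pars <- layout_cell_params(field$layout, xmid, leaflet)
  if (leaflet == "upper") {
    n <- field$n_u; H <- field$H_u; sgn <- 1
    active <- !field$excl_cells_u
  } else {
    n <- field$n_l; H <- field$H_l; sgn <- -1
    active <- !field$excl_cells_l
  }
  M <- field$M
  s <- diff(n) / dx
  nbar <- (n[-1] + n[-N]) / 2
  dH <- diff(H) / dx
  Hbar <- (H[-1] + H[-N]) / 2
  Mbar <- (M[-1] + M[-N]) / 2
  tilt <- nbar - sgn * dH
  # alpha - alpha0 from the incompressibility condition
  dalpha <- (1 - pars$alpha0) - sgn * (Hbar - Mbar) / pars$h -
    (pars$h / 2) * s
  list(splay = s, tilt = tilt, dalpha = dalpha, dH = dH,
       xmid = xmid, pars = pars, active = active)
}

#' Elastic energy density at a grid node
#'
#' Diagnostic evaluation of the renormalized energy density of one leaflet
#' at a single node, using centered (one-sided at the box edges) finite
#' differences for the derivatives.  Integrated energies are computed by
#' [total_energy()] from midpoint-rule cell quadrature instead.
#'
#' @param field a [deformation_field()].
#' @param layout the [region_layout()]; defaults to the field's own.
#' @param node node index.
#' @param leaflet `"upper"` or `"lower"`.
#' @return energy per unit area, \eqn{k_B T/\mathrm{nm}^2}.
#' @export
energy_density <- function(field, layout = field$layout, node,
                           leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  x <- field$x; N <- length(x); dx <- field$dx
  stopifnot(node >= 1, node <= N)
  excl <- if (leaflet == "upper") field$excl_cells_u else field$excl_cells_l
  touching <- c(if (node > 1) excl[node - 1], if (node < N) excl[node])
  if (any(touching))
    stop("node ", node, " lies inside a span excluded for the ", leaflet,
         " leaflet")
  if (leaflet == "upper") {
    n <- field$n_u; H <- field$H_u; sgn <- 1
  } else {
    n <- field$n_l; H <- field$H_l; sgn <- -1
  }
  d1 <- function(v) {
    if (node == 1) (v[2] - v[1]) / dx
    else if (node == N) (v[N] - v[N - 1]) / dx
    else (v[node + 1] - v[node - 1]) / (2 * dx)
  }
  pars <- layout_cell_params(layout, x[node], leaflet)
  s <- d1(n)
  dH <- d1(H)
  tilt <- n[node] - sgn * dH
  dalpha <- (1 - pars$alpha0) -
    sgn * (H[node] - field$M[node]) / pars$h - (pars$h / 2) * s
  monolayer_energy_density(s, tilt, dalpha, dH, pars)
}

#' Total elastic energy per unit boundary length
#'
#' Integrates the renormalized energy density of both leaflets over the
#' lateral coordinate by the midpoint rule on grid cells (exact for the
#' piecewise-linear fields the solver works with), skipping cells occupied
#' by a non-lipid inclusion.  Because bulk-phase densities are
#' renormalized to zero, the integral is finite for decaying deformation
#' fields and measures the excess (boundary plus inclusion) energy.
#'
#' @param field a [deformation_field()].
#' @param layout the [region_layout()]; defaults to the field's own.
#' @return energy per unit length of the domain boundary,
#'   \eqn{k_B T/\mathrm{nm}}.
#' @export
total_energy <- function(field, layout = field$layout) {
  field$layout <- layout
  W <- 0
  for (leaflet in c("upper", "lower")) {
    iv <- cell_invariants(field, leaflet)
    dens <- monolayer_energy_density(iv$splay, iv$tilt, iv$dalpha, iv$dH,
                                     iv$pars)
    W <- W + field$dx * sum(dens[iv$active])
  }
  check_field_decay(field)
  W
}

# Warn when deformations have not decayed at the box edges.
check_field_decay <- function(field, tol = 1e-3) {
  N <- length(field$x)
  up <- layout_cell_params(field$layout, field$x[c(1, N)], "upper")
  lo <- layout_cell_params(field$layout, field$x[c(1, N)], "lower")
  dev <- max(abs(field$n_u[c(1, N)]), abs(field$n_l[c(1, N)]),
             abs((field$H_u - field$M)[c(1, N)] - up$h * (1 - up$alpha0)),
             abs((field$M - field$H_l)[c(1, N)] - lo$h * (1 - lo$alpha0)))
  if (dev > tol)
    warning(sprintf(paste0("deformations have not decayed at the box ",
                           "edges (max deviation %.2e); enlarge half_width"),
                    dev))
  invisible(dev)
}
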