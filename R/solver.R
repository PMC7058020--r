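#' Solver settings
#'
#' Discretization and convergence controls for the constrained quadratic
#' minimization.  `dx` is the grid spacing (nm); `half_width` the distance
#' (nm) the simulation box extends beyond the outermost structural feature
#' (phase boundaries, inclusion edges) on each side — deformations decay
#' over 1-2 nm, so the default leaves ample room; `rel_tol` and
#' `max_refinements` control [refine_until_converged()].
#'
#' @param dx grid spacing, nm.
#' @param half_width box margin beyond the outermost structure, nm.
#' @param rel_tol relative energy tolerance of the refinement ladder.
#' @param max_refinements maximum number of refinement levels.
#' @return a list of class `solver_settings`.
#' @export
solver_settings <- function(dx = 0.025, half_width = 20,
                            rel_tol = 1e-3, max_refinements = 6) {
  if (dx <= 0 || dx > 0.05)
    stop("dx must be positive and at most 0.05 nm")
  if (half_width < 10) stop("half_width must be at least 10 nm")
  s <- list(dx = dx, half_width = half_width, rel_tol = rel_tol,
            max_refinements = max_refinements)
  class(s) <- "solver_settings"
  s
}

# Build the uniform grid for a layout.  The box spans half_width beyond
# the outermost structure on each side; x = 0 is always a node and dx is
# chosen so phase boundaries and inclusion edges land on (or within dx/2
# of) nodes.
build_grid <- function(layout, dx = 0.025, half_width = 20) {
  feats <- c(0, layout$L)
  inc <- layout$inclusion
  if (!is.null(inc) && is.finite(inc$X0))
    feats <- c(feats, inc$X0 - inc$deltaL / 2, inc$X0 + inc$deltaL / 2)
  lo <- dx * floor((min(feats) - half_width) / dx)
  hi <- dx * ceiling((max(feats) + half_width) / dx)
  x <- seq(lo, hi, by = dx)
  N <- length(x)
  index <- list(n_u = function(j) j,
                n_l = function(j) N + j,
                H_u = function(j) 2L * N + j,
                H_l = function(j) 3L * N + j,
                M  = function(j) 4L * N + j)
  list(x = x, dx = dx, N = N, m = 5L * N, index = index)
}

# Box-edge (far-field) conditions and the vertical-translation gauge:
# directors vanish and each leaflet sits at its asymptotic tension-
# equilibrated thickness relative to the interface; M is pinned to zero at
# the left edge to remove the rigid vertical-translation mode.
boundary_conditions <- function(layout, grid) {
  ix <- grid$index; N <- grid$N
  cons <- list()
  for (side in c("left", "right")) {
    e <- if (side == "left") 1L else N
    pu <- edge_params(layout, "upper", side)
    pl <- edge_params(layout, "lower", side)
    cons <- c(cons, list(
      constraint_row(ix$n_u(e), 1, 0,
                     paste("far-field director decay, upper", side)),
      constraint_row(ix$n_l(e), 1, 0,
                     paste("far-field director decay, lower", side)),
      constraint_row(c(ix$H_u(e), ix$M(e)), c(1, -1),
                     pu$h * (1 - pu$alpha0),
                     paste("far-field asymptotic thickness, upper", side)),
      constraint_row(c(ix$M(e), ix$H_l(e)), c(1, -1),
                     pl$h * (1 - pl$alpha0),
                     paste("far-field asymptotic thickness, lower", side))))
  }
  cons <- c(cons, list(constraint_row(ix$M(1L), 1, 0,
                                      "gauge: pin interface height at left edge")))
  cons
}

#' Assemble the discretized constrained quadratic problem
#'
#' Discretizes the total elastic energy as a quadratic form
#' \eqn{E(u) = u^T A u / 2 + b^T u + c} in the stacked unknowns
#' (`n_u`, `n_l`, `H_u`, `H_l`, `M` at every node; midpoint-rule cell
#' quadrature, first-order differences on cells — the discrete analogue of
#' linear finite elements) and collects all linear equality constraints:
#' far-field/gauge conditions, inclusion boundary conditions and pins of
#' unknowns inside excluded spans.  Continuity of directors and neutral
#' surfaces across region joins is automatic on the shared grid and is
#' broken only where an inclusion constraint says so.
#'
#' @param layout a [region_layout()].
#' @param grid a grid from `build_grid()` (or a [solver_settings()]
#'   object, in which case the grid is built internally).
#' @param extra_constraints optional list of additional constraint rows.
#' @return an object of class `quadratic_problem`.
#' @export
assemble <- function(layout, grid = solver_settings(),
                     extra_constraints = list()) {
  if (inherits(grid, "solver_settings"))
    grid <- build_grid(layout, grid$dx, grid$half_width)
  x <- grid$x; N <- grid$N; dx <- grid$dx; m <- grid$m
  ix <- grid$index
  xmid <- (x[-1] + x[-N]) / 2

  bc <- build_constraints(layout$inclusion, layout, grid)

  ti <- vector("list", 64L); tj <- ti; tx <- ti; nt <- 0L
  bi <- vector("list", 16L); bv <- bi; nb <- 0L
  cconst <- 0
  add_quad <- function(IDX, CF, w, d = 0, add_const = TRUE) {
    k <- ncol(IDX)
    for (a in seq_len(k)) {
      for (b2 in seq_len(k)) {
        nt <<- nt + 1L
        ti[[nt]] <<- IDX[, a]; tj[[nt]] <<- IDX[, b2]
        tx[[nt]] <<- w * CF[, a] * CF[, b2]
      }
      if (any(d != 0)) {
        nb <<- nb + 1L
        bi[[nb]] <<- IDX[, a]; bv[[nb]] <<- w * d * CF[, a]
      }
    }
    if (add_const) cconst <<- cconst + sum(w * d^2) / 2
  }

  for (leaflet in c("upper", "lower")) {
    if (leaflet == "upper") {
      act <- which(!bc$excl_cells_u)
      nn <- ix$n_u; HH <- ix$H_u; sgn <- 1
    } else {
      act <- which(!bc$excl_cells_l)
      nn <- ix$n_l; HH <- ix$H_l; sgn <- -1
    }
    if (!length(act)) next
    p <- layout_cell_params(layout, xmid[act], leaflet)
    i1 <- act; i2 <- act + 1L
    one <- rep(1, length(act))
    # splay: B/2 (s + J0)^2 - B/2 J0^2  (flat-state reference subtracted)
    add_quad(cbind(nn(i1), nn(i2)),
             cbind(-one / dx, one / dx),
             w = p$B * dx, d = p$J0, add_const = FALSE)
    # tilt: Kt/2 (nbar - sgn * dH)^2
    add_quad(cbind(nn(i1), nn(i2), HH(i1), HH(i2)),
             cbind(one / 2, one / 2, sgn * one / dx, -sgn * one / dx),
             w = p$Kt * dx)
    # stretching: Ka/2 (alpha - alpha0)^2 with alpha eliminated through
    # volumetric incompressibility
    add_quad(cbind(nn(i1), nn(i2), HH(i1), HH(i2), ix$M(i1), ix$M(i2)),
             cbind(p$h / (2 * dx), -p$h / (2 * dx),
                   -sgn / (2 * p$h), -sgn / (2 * p$h),
                   sgn / (2 * p$h), sgn / (2 * p$h)),
             w = p$Ka * dx, d = 1 - p$alpha0)
    # lateral tension: sigma0/2 (dH)^2
    add_quad(cbind(HH(i1), HH(i2)),
             cbind(-one / dx, one / dx),
             w = p$sigma0 * dx)
  }

  A <- Matrix::sparseMatrix(i = unlist(ti[seq_len(nt)]),
                            j = unlist(tj[seq_len(nt)]),
                            x = unlist(tx[seq_len(nt)]),
                            dims = c(m, m), symmetric = FALSE)
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  b <- numeric(m)
  if (nb > 0) {
    bacc <- Matrix::sparseMatrix(i = unlist(bi[seq_len(nb)]),
                                 j = rep(1L, length(unlist(bi[seq_len(nb)]))),
                                 x = unlist(bv[seq_len(nb)]),
                                 dims = c(m, 1L))
    b <- as.numeric(bacc)
  }

  cons <- c(bc$pins, bc$constraints, boundary_conditions(layout, grid),
            extra_constraints)
  k <- length(cons)
  Ci <- unlist(lapply(seq_len(k), function(r) rep(r, length(cons[[r]]$idx))))
  Cj <- unlist(lapply(cons, `[[`, "idx"))
  Cx <- unlist(lapply(cons, `[[`, "coef"))
  C <- Matrix::sparseMatrix(i = Ci, j = Cj, x = Cx, dims = c(k, m))
  d <- vapply(cons, `[[`, numeric(1), "rhs")
  tags <- vapply(cons, `[[`, character(1), "tag")

  prob <- list(A = A, b = b, cconst = cconst, C = C, d = d, tags = tags,
               grid = grid, layout = layout,
               excl_cells_u = bc$excl_cells_u,
               excl_cells_l = bc$excl_cells_l)
  class(prob) <- "quadratic_problem"
  prob
}

#' @export
print.quadratic_problem <- function(x, ...) {
  cat(sprintf("<quadratic_problem> %d unknowns (%d nodes), %d constraints\n",
              x$grid$m, x$grid$N, length(x$d)))
  invisible(x)
}

#' Solve for the equilibrium deformation field
#'
#' Finds the unique minimizer of the assembled quadratic energy subject to
#' its linear equality constraints by a sparse solve of the stationarity
#' (KKT) system.  The reported energy `W` is recomputed from the minimizer
#' with [total_energy()]; the quadratic-form value is kept alongside as a
#' cross-check of the assembly.
#'
#' @param problem a `quadratic_problem` from [assemble()].
#' @return a list with elements `field` (a [deformation_field()]), `W`
#'   (energy per unit boundary length, \eqn{k_B T/\mathrm{nm}}), `W_quad`
#'   (quadratic-form value) and `residual` (relative KKT residual).
#' @export
solve_equilibrium <- function(problem) {
  A <- problem$A; b <- problem$b; C <- problem$C; d <- problem$d
  m <- ncol(A); k <- nrow(C)
  # the energy is invariant under a rigid vertical translation of all
  # heights; refuse to proceed if no constraint pins that mode
  N <- problem$grid$N
  trans <- numeric(m)
  trans[(2L * N + 1L):(5L * N)] <- 1
  if (max(abs(as.numeric(C %*% trans))) < 1e-12)
    stop("stationarity system is singular: the global vertical ",
         "translation mode (H_u, H_l, M shifted together) is ",
         "unconstrained; add a gauge-fixing constraint")
  KKT <- rbind(cbind(A, Matrix::t(C)),
               cbind(C, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0),
                                             dims = c(k, k))))
  rhs <- c(-b, d)
  sol <- tryCatch(
    as.numeric(Matrix::solve(KKT, rhs)),
    error = function(e)
      stop("stationarity system is singular; the energy has an ",
           "unconstrained rigid mode (e.g. the global vertical ",
           "translation) -- check the gauge-fixing constraints\n  ",
           conditionMessage(e)))
  if (!all(is.finite(sol)))
    stop("stationarity system is singular; the energy has an ",
         "unconstrained rigid mode (e.g. the global vertical ",
         "translation) -- check the gauge-fixing constraints")
  resid <- sqrt(sum((as.numeric(KKT %*% sol) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), 1e-300)
  if (resid > 1e-8)
    warning(sprintf("KKT residual %.2e exceeds 1e-8", resid))
  u <- sol[seq_len(m)]
  N <- problem$grid$N
  field <- deformation_field(
    x = problem$grid$x,
    n_u = u[seq_len(N)], n_l = u[N + seq_len(N)],
    H_u = u[2 * N + seq_len(N)], H_l = u[3 * N + seq_len(N)],
    M = u[4 * N + seq_len(N)],
    layout = problem$layout,
    excl_cells_u = problem$excl_cells_u,
    excl_cells_l = problem$excl_cells_l)
  W_quad <- as.numeric(0.5 * (u %*% (A %*% u)) + sum(b * u)) + problem$cconst
  W <- total_energy(field)
  list(field = field, W = W, W_quad = W_quad, residual = resid)
}

#' Equilibrium solution for a layout in one call
#'
#' Convenience wrapper chaining grid construction, [assemble()] and
#' [solve_equilibrium()].
#'
#' @param layout a [region_layout()].
#' @param settings [solver_settings()].
#' @param extra_constraints optional list of additional linear constraint
#'   rows (advanced use, e.g. probing the response to a pinned director).
#' @return as [solve_equilibrium()].
#' @examples
#' \donttest{
#' sol <- solve_layout(region_layout(default_membrane(), L = 3))
#' sol$W  # ~0.28 kBT/nm
#' }
#' @export
solve_layout <- function(layout, settings = solver_settings(),
                         extra_constraints = list()) {
  grid <- build_grid(layout, settings$dx, settings$half_width)
  solve_equilibrium(assemble(layout, grid, extra_constraints))
}

#' Solve with grid refinement until the energy converges
#'
#' Repeats [solve_equilibrium()] on successively finer and wider grids
#' (halving `dx` and enlarging `half_width` by 50\% per level) until the
#' energy changes by less than `rel_tol` in relative terms between
#' consecutive levels.
#'
#' @param layout a [region_layout()].
#' @param settings starting [solver_settings()]; its `rel_tol` and
#'   `max_refinements` control the ladder.
#' @return a list with `field`, `W` (finest level) and `diagnostics`, a
#'   data frame recording the convergence ladder.
#' @export
refine_until_converged <- function(layout, settings = solver_settings()) {
  if (settings$rel_tol <= 0) stop("rel_tol must be positive")
  dx <- settings$dx; hw <- settings$half_width
  ladder <- data.frame(level = integer(0), dx = numeric(0),
                       half_width = numeric(0), W = numeric(0))
  prev <- NULL; sol <- NULL
  for (lev in seq_len(settings$max_refinements)) {
    sol <- solve_layout(layout, solver_settings(dx, hw,
                                                settings$rel_tol,
                                                settings$max_refinements))
    ladder <- rbind(ladder, data.frame(level = lev, dx = dx,
                                       half_width = hw, W = sol$W))
    if (!is.null(prev) &&
        abs(sol$W - prev) <= settings$rel_tol * max(abs(sol$W), 1e-12)) {
      return(list(field = sol$field, W = sol$W, diagnostics = ladder))
    }
    prev <- sol$W
    dx <- dx / 2; hw <- hw * 1.5
  }
  stop("energy did not converge within ", settings$max_refinements,
       " refinement levels; ladder:\n",
       paste(utils::capture.output(print(ladder)), collapse = "\n"))
}
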