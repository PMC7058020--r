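#' Membrane inclusion specifications
#'
#' Constructors for the five supported inclusion families.  An inclusion is
#' described by its width `deltaL` (nm), the lateral position `X0` of its
#' center (nm, usually set by the scanning routines), and family-specific
#' boundary-condition parameters:
#'
#' * `amphipathic_peptide()` — a shallowly inserted amphipathic helix lying
#'   in the upper-leaflet headgroup region.  It pushes lipid heads apart,
#'   imposing a director jump of negative x-projection across its span
#'   whose magnitude follows from the peptide geometry
#'   ([director_jump_bulk()], [director_jump_boundary()]); rotation of the
#'   helix couples the neutral-surface offset at its edges to the mean
#'   boundary director.  The opposing leaflet is unconstrained.
#' * `hydrophobic_peptide()` — a hydrophobic helix buried near the lipid
#'   tails, either within the upper monolayer (`where = "upper"`) or
#'   symmetrically at the monolayer interface (`where = "midplane"`).  It
#'   pushes tails apart: a director jump of positive x-projection and
#'   magnitude `dn_mag` is applied point-like at `X0` (in one or both
#'   leaflets) while the neutral surfaces stay continuous.
#' * `transmembrane_protein()` — an undeformable spanning inclusion of
#'   hydrophobic length `h0` with fixed boundary directors; `dnx_u` and
#'   `dnx_l` give the across-inclusion director jumps per leaflet
#'   (cylinder 0, hourglass-like negative, barrel-like positive).  Its
#'   vertical position is free and resolved by energy minimization.
#' * `lipid_stripe()` — a deformable monolayer stripe in the upper leaflet
#'   with its own splay modulus `B0`, spontaneous curvature `J0` and
#'   equilibrium thickness `h0`; directors and neutral surfaces are
#'   continuous at its edges.
#'
#' @param deltaL inclusion width (diameter), nm.
#' @param X0 lateral position of the inclusion center, nm.
#' @param dn_mag magnitude of the boundary director jump (hydrophobic
#'   peptides), dimensionless.
#' @param where `"upper"` or `"midplane"` insertion of a hydrophobic
#'   peptide.
#' @param h0 hydrophobic length (transmembrane protein) or equilibrium
#'   monolayer thickness (lipid stripe), nm.
#' @param dnx_u,dnx_l boundary director x-jumps per leaflet for a
#'   transmembrane protein, dimensionless.
#' @param J0 spontaneous curvature of the stripe monolayer, 1/nm.
#' @param B0 splay modulus of the stripe monolayer, \eqn{k_B T}.
#' @return an object of class `inclusion_spec`.
#' @name inclusion_spec
NULL

new_inclusion <- function(family, deltaL, X0, ...) {
  if (deltaL <= 0) stop("inclusion width deltaL must be positive")
  sp <- c(list(family = family, deltaL = deltaL, X0 = X0), list(...))
  class(sp) <- "inclusion_spec"
  sp
}

#' @rdname inclusion_spec
#' @export
amphipathic_peptide <- function(deltaL = 1.3, X0 = NA_real_) {
  new_inclusion("amphipathic_shallow", deltaL, X0)
}

#' @rdname inclusion_spec
#' @export
hydrophobic_peptide <- function(dn_mag, deltaL = 1.3, X0 = NA_real_,
                                where = c("upper", "midplane")) {
  where <- match.arg(where)
  if (abs(dn_mag) > 2) stop("|dn_mag| must not exceed 2")
  fam <- if (where == "upper") "hydrophobic_deep_upper" else
    "hydrophobic_midplane"
  new_inclusion(fam, deltaL, X0, dn_mag = abs(dn_mag))
}

#' @rdname inclusion_spec
#' @export
transmembrane_protein <- function(h0, dnx_u = 0, dnx_l = dnx_u,
                                  deltaL = 1.3, X0 = NA_real_) {
  if (h0 <= 0) stop("transmembrane hydrophobic length h0 must be positive")
  if (abs(dnx_u) > 2 || abs(dnx_l) > 2) stop("|dnx| must not exceed 2")
  new_inclusion("transmembrane", deltaL, X0, h0 = h0,
                dnx_u = dnx_u, dnx_l = dnx_l)
}

#' @rdname inclusion_spec
#' @export
lipid_stripe <- function(h0, J0 = 0, B0 = 10, deltaL = 1.3, X0 = NA_real_) {
  if (h0 <= 0) stop("stripe thickness h0 must be positive")
  if (B0 <= 0) stop("stripe splay modulus B0 must be positive")
  new_inclusion("lipid_stripe", deltaL, X0,
                stripe = list(B = B0, J0 = J0, h = h0))
}

#' @export
print.inclusion_spec <- function(x, ...) {
  cat(sprintf("<inclusion_spec> %s, deltaL = %g nm, X0 = %g nm\n",
              x$family, x$deltaL, x$X0))
  invisible(x)
}

set_position <- function(spec, X0) {
  spec$X0 <- X0
  spec
}

#' Director jump induced by a peptide in a uniform phase
#'
#' Geometric estimate of the magnitude of the boundary-director
#' discontinuity induced by an undeformable peptide of width `deltaL`
#' inserted into a monolayer of hydrophobic thickness `h`:
#' \deqn{|\Delta n| = \Delta L / \sqrt{(\Delta L/2)^2 + (h/2)^2}.}
#'
#' @param deltaL peptide width (diameter), nm.
#' @param h monolayer hydrophobic thickness, nm.
#' @return dimensionless jump magnitude.
#' @examples
#' director_jump_bulk(1.3, 1.3)  # sqrt(2)
#' @export
director_jump_bulk <- function(deltaL, h) {
  if (any(deltaL <= 0)) stop("deltaL must be positive")
  if (any(h <= 0)) stop("h must be positive")
  deltaL / sqrt((deltaL / 2)^2 + (h / 2)^2)
}

#' Director jump for a peptide straddling the phase boundary
#'
#' Interpolates the geometric director-jump estimate between the two
#' phases by the fraction `delta` of the peptide width embedded in the
#' liquid-ordered monolayer (thickness `h_r`); the remainder sits in the
#' liquid-disordered monolayer (thickness `h_s`).
#'
#' @param deltaL peptide width, nm.
#' @param h_r,h_s monolayer thicknesses of the ordered and disordered
#'   phase, nm.
#' @param delta fraction of the peptide width embedded in the ordered
#'   phase, in `[0, 1]`.
#' @return dimensionless jump magnitude.
#' @export
director_jump_boundary <- function(deltaL, h_r, h_s, delta) {
  if (any(delta < 0) || any(delta > 1))
    stop("delta must lie in [0, 1]")
  delta * director_jump_bulk(deltaL, h_r) +
    (1 - delta) * director_jump_bulk(deltaL, h_s)
}

# Fraction of the span [X0 - dL/2, X0 + dL/2] lying in the ordered region
# (x >= xb) of the host leaflet, clipped to [0, 1].
ordered_overlap_fraction <- function(X0, deltaL, xb) {
  min(max((X0 + deltaL / 2 - xb) / deltaL, 0), 1)
}

constraint_row <- function(idx, coef, rhs, tag) {
  list(idx = as.integer(idx), coef = as.numeric(coef),
       rhs = as.numeric(rhs), tag = tag)
}

# Translate an inclusion specification into excluded spans and linear
# boundary conditions on the discretized unknowns.
#
# Returns list(excl_cells_u, excl_cells_l (logical over cells),
#              pins, constraints (lists of constraint_row)).
build_constraints <- function(spec, layout, grid) {
  x <- grid$x; dx <- grid$dx; N <- length(x)
  ix <- grid$index
  excl_u <- logical(N - 1); excl_l <- logical(N - 1)
  pins <- list(); cons <- list()
  if (is.null(spec)) {
    return(list(excl_cells_u = excl_u, excl_cells_l = excl_l,
                pins = pins, constraints = cons))
  }
  if (!is.finite(spec$X0)) stop("inclusion position X0 is not set")

  snap <- function(target) {
    i <- which.min(abs(x - target))
    if (abs(x[i] - target) > dx / 2 + 1e-9)
      stop("inclusion edge falls outside the grid")
    i
  }
  xmid <- (x[-1] + x[-N]) / 2

  if (spec$family %in% c("amphipathic_shallow", "transmembrane")) {
    if (spec$deltaL < 2 * dx)
      stop("inclusion width deltaL below 2*dx cannot be resolved; ",
           "refine the grid or widen the inclusion")
    iL <- snap(spec$X0 - spec$deltaL / 2)
    iR <- snap(spec$X0 + spec$deltaL / 2)
    if (iL <= 1 || iR >= N)
      stop("inclusion span is not strictly inside the simulation box")
    span_cells <- seq(iL, iR - 1L)
    inner_nodes <- if (iR - iL >= 2) seq(iL + 1L, iR - 1L) else integer(0)
  }

  if (spec$family == "amphipathic_shallow") {
    excl_u[span_cells] <- TRUE
    for (j in inner_nodes) {
      pins <- c(pins,
                list(constraint_row(ix$n_u(j), 1, 0, "excluded-span pin"),
                     constraint_row(ix$H_u(j), 1, 0, "excluded-span pin")))
    }
    ph <- layout$upper
    dn <- director_jump_boundary(
      spec$deltaL, ph$r$h, ph$s$h,
      ordered_overlap_fraction(spec$X0, spec$deltaL,
                               leaflet_boundary(layout, "upper")))
    cons <- c(cons, list(
      constraint_row(c(ix$n_u(iR), ix$n_u(iL)), c(1, -1), -dn,
                     "shallow peptide director jump (heads apart)"),
      constraint_row(c(ix$H_u(iR), ix$H_u(iL), ix$n_u(iL), ix$n_u(iR)),
                     c(1, -1, -spec$deltaL / 2, -spec$deltaL / 2), 0,
                     "peptide rotation: edge height offset = deltaL * mean director")))
  } else if (spec$family == "transmembrane") {
    excl_u[span_cells] <- TRUE
    excl_l[span_cells] <- TRUE
    for (j in inner_nodes) {
      pins <- c(pins, lapply(
        c(ix$n_u(j), ix$n_l(j), ix$H_u(j), ix$H_l(j), ix$M(j)),
        function(k) constraint_row(k, 1, 0, "excluded-span pin")))
    }
    cons <- c(cons, list(
      constraint_row(c(ix$H_u(iL), ix$H_l(iL)), c(1, -1), spec$h0,
                     "fixed hydrophobic thickness (left edge)"),
      constraint_row(c(ix$H_u(iR), ix$H_l(iR)), c(1, -1), spec$h0,
                     "fixed hydrophobic thickness (right edge)"),
      constraint_row(c(ix$H_u(iL), ix$H_u(iR)), c(1, -1), 0,
                     "rigid body: equal edge heights (free vertical offset)"),
      constraint_row(ix$n_u(iL), 1, -spec$dnx_u / 2,
                     "fixed boundary director, upper left"),
      constraint_row(ix$n_u(iR), 1, spec$dnx_u / 2,
                     "fixed boundary director, upper right"),
      constraint_row(ix$n_l(iL), 1, -spec$dnx_l / 2,
                     "fixed boundary director, lower left"),
      constraint_row(ix$n_l(iR), 1, spec$dnx_l / 2,
                     "fixed boundary director, lower right")))
  } else if (spec$family %in% c("hydrophobic_deep_upper",
                                "hydrophobic_midplane")) {
    # point-like director discontinuity applied across one grid cell
    i <- min(max(findInterval(spec$X0, x), 1L), N - 1L)
    if (i <= 1 || i >= N - 1)
      stop("inclusion position is not strictly inside the simulation box")
    excl_u[i] <- TRUE
    cons <- c(cons, list(
      constraint_row(c(ix$n_u(i + 1L), ix$n_u(i)), c(1, -1), spec$dn_mag,
                     "deep peptide director jump, upper (tails apart)"),
      constraint_row(c(ix$H_u(i + 1L), ix$H_u(i)), c(1, -1), 0,
                     "continuous neutral surface, upper")))
    if (spec$family == "hydrophobic_midplane") {
      excl_l[i] <- TRUE
      cons <- c(cons, list(
        constraint_row(c(ix$n_l(i + 1L), ix$n_l(i)), c(1, -1), spec$dn_mag,
                       "deep peptide director jump, lower (tails apart)"),
        constraint_row(c(ix$H_l(i + 1L), ix$H_l(i)), c(1, -1), 0,
                       "continuous neutral surface, lower")))
    }
  } else if (spec$family == "lipid_stripe") {
    if (spec$deltaL < 2 * dx)
      stop("stripe width deltaL below 2*dx cannot be resolved")
    # deformable stripe: parameter substitution only, handled by
    # layout_cell_params(); directors and neutral surfaces continuous
  } else {
    stop("unknown inclusion family: ", spec$family)
  }
  list(excl_cells_u = excl_u, excl_cells_l = excl_l,
       pins = pins, constraints = cons)
}
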