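#' Piecewise description of the membrane along the boundary normal
#'
#' The membrane is described along the coordinate `x` perpendicular to the
#' (straight) domain boundary.  The lower-leaflet phase boundary is fixed
#' at `x = 0`; the upper-leaflet boundary sits at `x = L`, where `L` is the
#' signed interleaflet boundary shift.  Each leaflet is in the
#' liquid-disordered state (`s`) for `x` below its boundary and in the
#' liquid-ordered state (`r`) above it, so bilayer thickness grows from
#' `2*h_s` at \eqn{x \to -\infty} to `2*h_r` at \eqn{x \to +\infty}.
#' An optional membrane inclusion (see [lipid_stripe()],
#' [amphipathic_peptide()], [hydrophobic_peptide()],
#' [transmembrane_protein()]) adds a fourth region and/or extra boundary
#' conditions.
#'
#' @param phases list with components `r` and `s`, each a
#'   [monolayer_parameters()] object; used for both leaflets unless
#'   `upper_phases`/`lower_phases` override it.
#' @param L signed interleaflet boundary shift, nm.
#' @param inclusion an `inclusion_spec` or `NULL`.
#' @param upper_phases,lower_phases per-leaflet phase overrides.
#' @return an object of class `region_layout`.
#' @examples
#' lay <- region_layout(default_membrane(), L = 3)
#' @export
region_layout <- function(phases = default_membrane(), L = 0,
                          inclusion = NULL,
                          upper_phases = phases, lower_phases = phases) {
  chk <- function(p, nm) {
    if (!is.list(p) || !inherits(p$r, "monolayer_parameters") ||
        !inherits(p$s, "monolayer_parameters"))
      stop(nm, " must be a list with monolayer_parameters 'r' and 's'")
  }
  chk(upper_phases, "upper_phases"); chk(lower_phases, "lower_phases")
  if (!is.null(inclusion) && !inherits(inclusion, "inclusion_spec"))
    stop("inclusion must be an inclusion_spec or NULL")
  lay <- list(upper = upper_phases, lower = lower_phases,
              L = L, inclusion = inclusion)
  class(lay) <- "region_layout"
  lay
}

#' @export
print.region_layout <- function(x, ...) {
  cat("<region_layout>\n")
  cat(sprintf("  upper-leaflet Lo/Ld boundary at x = %g nm\n", x$L))
  cat("  lower-leaflet Lo/Ld boundary at x = 0 nm\n")
  if (is.null(x$inclusion)) cat("  no inclusion\n")
  else cat(sprintf("  inclusion: %s at X0 = %g nm (width %g nm)\n",
                   x$inclusion$family, x$inclusion$X0, x$inclusion$deltaL))
  invisible(x)
}

# Phase boundary position of one leaflet.
leaflet_boundary <- function(layout, leaflet) {
  if (leaflet == "upper") layout$L else 0
}

# Parameters of the asymptotic phase of one leaflet on one side of the box.
edge_params <- function(layout, leaflet, side) {
  ph <- if (leaflet == "upper") layout$upper else layout$lower
  if (side == "left") ph$s else ph$r
}

# Per-cell elastic parameters for one leaflet, vectorized over cell
# midpoints.  Applies the lipid-stripe parameter override where relevant.
# Returns a list of numeric vectors (B, Kt, Ka, J0, h, sigma0, alpha0).
layout_cell_params <- function(layout, xmid, leaflet) {
  ph <- if (leaflet == "upper") layout$upper else layout$lower
  xb <- leaflet_boundary(layout, leaflet)
  in_r <- xmid >= xb
  pick <- function(fld) ifelse(in_r, ph$r[[fld]], ph$s[[fld]])
  out <- list(B = pick("B"), Kt = pick("Kt"), Ka = pick("Ka"),
              J0 = pick("J0"), h = pick("h"), sigma0 = pick("sigma0"))
  inc <- layout$inclusion
  if (!is.null(inc) && inc$family == "lipid_stripe" && leaflet == "upper") {
    in_stripe <- abs(xmid - inc$X0) < inc$deltaL / 2
    out$B[in_stripe] <- inc$stripe$B
    out$J0[in_stripe] <- inc$stripe$J0
    out$h[in_stripe] <- inc$stripe$h
    # tilt/stretching moduli and tension follow the host cell values
  }
  out$alpha0 <- out$sigma0 / out$Ka
  out
}
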