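#' Energy profile container
#'
#' Result of an energy scan: the abscissa (boundary shift `L` or inclusion
#' position `X0`, nm), the equilibrium elastic energy per unit boundary
#' length `W` at each abscissa value, the asymptotic plateau levels (for
#' position scans) and the refined local minima.
#'
#' @param abscissa abscissa grid, nm.
#' @param W energies, \eqn{k_B T/\mathrm{nm}}.
#' @param kind `"boundary_shift"` or `"inclusion_position"`.
#' @param plateau_left,plateau_right asymptotic plateau energies (position
#'   scans), \eqn{k_B T/\mathrm{nm}}.
#' @param minima data frame of refined minima (see [minima_analysis()]).
#' @param meta free-form list of scan metadata.
#' @return an object of class `energy_profile`.
#' @export
energy_profile <- function(abscissa, W, kind,
                           plateau_left = NA_real_,
                           plateau_right = NA_real_,
                           minima = NULL, meta = list()) {
  stopifnot(length(abscissa) == length(W), !is.unsorted(abscissa))
  p <- list(abscissa = abscissa, W = W, kind = kind,
            plateau_left = plateau_left, plateau_right = plateau_right,
            minima = minima, meta = meta)
  class(p) <- "energy_profile"
  p
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("<energy_profile> %s, %d points on [%g, %g] nm\n",
              x$kind, length(x$W), min(x$abscissa), max(x$abscissa)))
  if (is.finite(x$plateau_left))
    cat(sprintf("  plateaus: left %.4f, right %.4f kBT/nm\n",
                x$plateau_left, x$plateau_right))
  if (!is.null(x$minima) && nrow(x$minima) > 0) {
    cat("  minima:\n")
    print(x$minima, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.energy_profile <- function(x, ...) {
  data.frame(abscissa = x$abscissa, W = x$W)
}

#' @export
plot.energy_profile <- function(x, ...) {
  xl <- if (x$kind == "boundary_shift") "boundary shift L (nm)" else
    "inclusion position X0 (nm)"
  graphics::plot(x$abscissa, x$W, type = "l", xlab = xl,
                 ylab = "W (kBT/nm)", ...)
  if (!is.null(x$minima) && nrow(x$minima) > 0)
    graphics::points(x$minima$position, x$minima$W, pch = 19)
  invisible(x)
}

#' Elastic energy of the bare domain boundary versus interleaflet shift
#'
#' Computes the equilibrium boundary energy `W(L)` for a range of signed
#' shifts `L` between the upper- and lower-leaflet phase boundaries.  The
#' profile is symmetric, `W(L) = W(-L)`, by the mirror symmetry of the
#' functional.
#'
#' @param phases list with [monolayer_parameters()] components `r` and
#'   `s` (see [default_membrane()]).
#' @param L_values boundary shifts to scan, nm.
#' @param settings [solver_settings()].
#' @return an [energy_profile()] of kind `"boundary_shift"`.
#' @export
boundary_energy_profile <- function(phases = default_membrane(),
                                    L_values = seq(-6, 6, by = 0.25),
                                    settings = solver_settings()) {
  L_values <- sort(L_values)
  W <- vapply(L_values, function(L) {
    tryCatch(solve_layout(region_layout(phases, L = L), settings)$W,
             error = function(e)
               stop("solver failed at L = ", L, ": ",
                    conditionMessage(e)))
  }, numeric(1))
  energy_profile(L_values, W, "boundary_shift",
                 meta = list(settings = settings))
}

#' Equilibrium interleaflet boundary shift
#'
#' Locates the energy-minimal relative shift `L0` of the two leaflet phase
#' boundaries from a `W(L)` scan, with parabolic refinement of the grid
#' minimum.  The profile is symmetric in `L`, so the positive root of the
#' degenerate pair is returned by convention.
#'
#' @param phases phase parameter list (see [default_membrane()]).
#' @param L_values shifts to scan, nm.
#' @param settings [solver_settings()].
#' @return list with `L0` (nm), `W0` (\eqn{k_B T/\mathrm{nm}}) and the
#'   scanned `profile`.
#' @export
find_equilibrium_shift <- function(phases = default_membrane(),
                                   L_values = seq(0, 6, by = 0.25),
                                   settings = solver_settings()) {
  prof <- boundary_energy_profile(phases, L_values, settings)
  W <- prof$W; L <- prof$abscissa
  if (max(W) - min(W) < 1e-10) {
    return(list(L0 = 0, W0 = W[1], profile = prof))
  }
  pos <- which(L >= 0)
  mins <- local_minima(L[pos], W[pos], include_edges = TRUE)
  if (nrow(mins) > 1)
    warning("W(L) is not unimodal on the positive half-axis; ",
            "returning the global minimum of ", nrow(mins), " local minima")
  best <- mins[which.min(mins$W), ]
  list(L0 = abs(best$position), W0 = best$W, profile = prof)
}

#' Elastic energy versus lateral inclusion position
#'
#' Solves the constrained equilibrium for an inclusion centered at each
#' requested position `X0` at fixed interleaflet boundary shift `L`, and
#' reports the resulting energy profile with bulk plateau estimates and
#' refined minima.  Plateaus are the mean energy over the outer 10\% of
#' each tail; the scan range must be wide enough for both tails to be
#' flat.
#'
#' @param spec an `inclusion_spec` (see [lipid_stripe()] and friends).
#' @param phases phase parameter list (see [default_membrane()]).
#' @param L fixed interleaflet boundary shift, nm.
#' @param X0_values inclusion center positions to scan, nm.
#' @param settings [solver_settings()].
#' @param flatness_tol maximal admissible |dW/dX0| inside a plateau
#'   window, \eqn{k_B T/\mathrm{nm}^2}.  The default tolerates the weak
#'   tension-mediated tail (decay scale \eqn{\sqrt{\sum B/2\sigma_0}}
#'   of a few tens of nm) that curvature-active inclusions excite; the
#'   plateau is an operational reading of the scan window, exactly as the
#'   profiles are read off a finite plot range.
#' @return an [energy_profile()] of kind `"inclusion_position"`.
#' @export
inclusion_energy_profile <- function(spec, phases = default_membrane(),
                                     L = 3,
                                     X0_values = seq(-12, 12, by = 0.25),
                                     settings = solver_settings(),
                                     flatness_tol = 1e-2) {
  stopifnot(inherits(spec, "inclusion_spec"))
  X0_values <- sort(X0_values)
  W <- vapply(X0_values, function(X0) {
    lay <- region_layout(phases, L = L, inclusion = set_position(spec, X0))
    tryCatch(solve_layout(lay, settings)$W,
             error = function(e)
               stop("solver failed at X0 = ", X0, ": ",
                    conditionMessage(e)))
  }, numeric(1))
  n <- length(W)
  ntail <- max(2L, ceiling(0.1 * n))
  lw <- seq_len(ntail); rw <- seq(n - ntail + 1L, n)
  # regression slope over the outer 1.5 nm of each tail (robust to the
  # sub-grid ripple of scans stepped finer than the solver grid)
  edge_slope <- function(idx) {
    xe <- X0_values[idx]; we <- W[idx]
    if (length(idx) < 2) return(0)
    abs(stats::coef(stats::lm(we ~ xe))[2])
  }
  sl <- edge_slope(which(X0_values <= X0_values[1] + 1.5))
  sr <- edge_slope(which(X0_values >= X0_values[n] - 1.5))
  if (max(sl, sr) > flatness_tol)
    stop("energy has not reached a flat plateau at the scan edges; ",
         "widen the X0 range")
  pl <- mean(W[lw]); pr <- mean(W[rw])
  prof <- energy_profile(X0_values, W, "inclusion_position",
                         plateau_left = pl, plateau_right = pr,
                         meta = list(spec = spec, L = L,
                                     settings = settings))
  prof$minima <- minima_analysis(prof)
  prof
}

# Interior local minima of a sampled curve with parabolic refinement.
local_minima <- function(x, y, include_edges = FALSE) {
  n <- length(y)
  out <- data.frame(position = numeric(0), W = numeric(0))
  idx <- which(diff(sign(diff(y))) > 0) + 1L   # y[i] < both neighbours
  # flat-bottomed minima: fall back to strict comparison with tolerance
  for (i in idx) {
    # parabola through (x[i-1], y[i-1]), (x[i], y[i]), (x[i+1], y[i+1])
    d1 <- (y[i + 1] - y[i - 1]) / 2
    d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
    if (d2 > 0) {
      tt <- -d1 / d2
      xm <- x[i] + tt * (x[i + 1] - x[i])
      ym <- y[i] - d1^2 / (2 * d2)
    } else {
      xm <- x[i]; ym <- y[i]
    }
    out <- rbind(out, data.frame(position = xm, W = ym))
  }
  if (include_edges) {
    if (y[1] < y[2] && !(1L %in% (idx - 1L)))
      out <- rbind(data.frame(position = x[1], W = y[1]), out)
    if (y[n] < y[n - 1])
      out <- rbind(out, data.frame(position = x[n], W = y[n]))
  }
  out[order(out$position), , drop = FALSE]
}

#' Locate and quantify the minima of an energy profile
#'
#' Finds the interior local minima of a scanned profile on the grid,
#' refines each by a local parabola, and reports several depth measures
#' per minimum: relative to the plateau on the nearer side of the scan
#' (`depth`), relative to each plateau explicitly (`depth_left`,
#' `depth_right`), and relative to the higher of the two plateaus
#' (`depth_vs_max_plateau`).  Figure-style statements about minima quote
#' different references depending on context, so all are kept.
#'
#' @param profile an [energy_profile()] with plateau estimates, or a
#'   two-column data frame `(abscissa, W)` plus explicit plateaus.
#' @param plateau_left,plateau_right plateau overrides.
#' @param min_depth minima shallower than this (vs the nearer plateau)
#'   are discarded as numerical ripple, \eqn{k_B T/\mathrm{nm}}.
#' @param merge_within minima closer than this distance (nm) are treated
#'   as one ripple-split minimum and only the deepest is kept.
#' @return data frame with columns `position`, `W`, `depth`,
#'   `depth_left`, `depth_right`, `depth_vs_max_plateau`, `is_global`.
#' @export
minima_analysis <- function(profile,
                            plateau_left = profile$plateau_left,
                            plateau_right = profile$plateau_right,
                            min_depth = 5e-3, merge_within = 0.5) {
  x <- profile$abscissa; y <- profile$W
  mins <- local_minima(x, y)
  if (nrow(mins) > 1 && merge_within > 0) {
    grp <- cumsum(c(TRUE, diff(mins$position) > merge_within))
    mins <- do.call(rbind, lapply(split(mins, grp), function(g)
      g[which.min(g$W), , drop = FALSE]))
  }
  if (nrow(mins) == 0) {
    return(data.frame(position = numeric(0), W = numeric(0),
                      depth = numeric(0), depth_left = numeric(0),
                      depth_right = numeric(0),
                      depth_vs_max_plateau = numeric(0),
                      is_global = logical(0)))
  }
  nearer <- ifelse(mins$position - min(x) <= max(x) - mins$position,
                   plateau_left, plateau_right)
  mins$depth <- nearer - mins$W
  mins$depth_left <- plateau_left - mins$W
  mins$depth_right <- plateau_right - mins$W
  mins$depth_vs_max_plateau <- max(plateau_left, plateau_right) - mins$W
  mins <- mins[mins$depth >= min_depth, , drop = FALSE]
  mins$is_global <- seq_len(nrow(mins)) == which.min(mins$W)
  rownames(mins) <- NULL
  mins
}

#' Convert a line energy to piconewtons
#'
#' An energy per unit length in \eqn{k_B T/\mathrm{nm}} is a line tension;
#' multiplying by the thermal energy in joules and dividing by
#' \eqn{10^{-9}} m gives the force unit.
#'
#' @param W energy per unit length, \eqn{k_B T/\mathrm{nm}}.
#' @param kBT_joules thermal energy, joules.
#' @return line tension in pN.
#' @examples
#' line_tension_pN(0.27)  # ~1.1 pN
#' @export
line_tension_pN <- function(W, kBT_joules = 4e-21) {
  W * kBT_joules * 1e21
}

#' Boltzmann enrichment factor from a line-energy difference
#'
#' Converts an energy difference per unit boundary length into the
#' equilibrium concentration ratio of inclusions between the two
#' locations, given the effective lateral length of the inclusion along
#' the boundary: `exp(delta_W * effective_length)` (energies in
#' \eqn{k_B T/\mathrm{nm}}, lengths in nm).
#'
#' @param delta_W_per_length energy difference, \eqn{k_B T/\mathrm{nm}}.
#' @param effective_length effective inclusion length along the boundary,
#'   nm.
#' @return dimensionless enrichment (or depletion) factor.
#' @examples
#' boltzmann_factor(2, 1)    # ~7.4
#' boltzmann_factor(0.4, 1)  # ~1.5
#' @export
boltzmann_factor <- function(delta_W_per_length, effective_length) {
  if (any(effective_length <= 0)) stop("effective_length must be positive")
  exp(delta_W_per_length * effective_length)
}
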