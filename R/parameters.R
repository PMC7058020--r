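#' Unit conversions between surface-elastic units
#'
#' Internally all energies are measured in units of the thermal energy
#' \eqn{k_B T} and all lengths in nanometres, so that moduli with dimensions
#' of a surface tension (tilt modulus, stretching modulus, lateral tension)
#' carry units of \eqn{k_B T/\mathrm{nm}^2}.  Literature values are usually
#' quoted in mN/m; with \eqn{k_B T = 4\times 10^{-21}} J one has
#' 1 mN/m = 0.25 \eqn{k_B T/\mathrm{nm}^2}.
#'
#' @param x numeric value(s) in mN/m.
#' @param kBT_joules thermal energy in joules (default `4e-21`).
#' @return numeric value(s) in \eqn{k_B T/\mathrm{nm}^2}.
#' @export
mN_per_m_to_kBT_per_nm2 <- function(x, kBT_joules = 4e-21) {
  # 1 mN/m = 1e-3 J/m^2 = 1e-3 * 1e-18 J/nm^2
  x * 1e-21 / kBT_joules
}

#' Elastic description of one lipid monolayer
#'
#' Bundles the elastic constants and reference geometry of a single
#' monolayer (leaflet) in a given phase state.  The set matches the
#' quadratic monolayer functional with splay, tilt, lateral
#' compression/stretching and lateral-tension contributions.
#'
#' @param B splay (bending) modulus, \eqn{k_B T}.
#' @param Kt tilt modulus, \eqn{k_B T/\mathrm{nm}^2}. Use
#'   [mN_per_m_to_kBT_per_nm2()] for literature values in mN/m.
#' @param Ka lateral compression/stretching modulus,
#'   \eqn{k_B T/\mathrm{nm}^2}.
#' @param J0 spontaneous curvature of the monolayer, 1/nm.  Positive values
#'   correspond to inverted-cone (lysolipid/GM1-like) molecular shapes.
#' @param h hydrophobic thickness of the undeformed monolayer, nm.
#' @param sigma0 lateral tension per monolayer, \eqn{k_B T/\mathrm{nm}^2}.
#' @return an object of class `monolayer_parameters`: a list with fields
#'   `B`, `Kt`, `Ka`, `J0`, `h`, `sigma0` and the derived equilibrium
#'   stretching `alpha0 = sigma0/Ka`.
#' @examples
#' lo <- monolayer_parameters(B = 20, Kt = 10, Ka = 30, J0 = 0, h = 1.8)
#' ld <- monolayer_parameters(B = 10, Kt = 10, Ka = 30, J0 = 0, h = 1.3)
#' @export
monolayer_parameters <- function(B, Kt, Ka, J0 = 0, h, sigma0 = 0.025) {
  stopifnot(is.numeric(B), is.numeric(Kt), is.numeric(Ka),
            is.numeric(J0), is.numeric(h), is.numeric(sigma0))
  if (B <= 0) stop("splay modulus B must be positive")
  if (Kt <= 0) stop("tilt modulus Kt must be positive")
  if (Ka <= 0) stop("stretching modulus Ka must be positive")
  if (h <= 0) stop("monolayer thickness h must be positive")
  p <- list(B = B, Kt = Kt, Ka = Ka, J0 = J0, h = h,
            sigma0 = sigma0, alpha0 = sigma0 / Ka)
  class(p) <- "monolayer_parameters"
  p
}

#' @export
print.monolayer_parameters <- function(x, ...) {
  cat("<monolayer_parameters>\n")
  cat(sprintf("  B      = %g kBT      (splay)\n", x$B))
  cat(sprintf("  Kt     = %g kBT/nm^2 (tilt)\n", x$Kt))
  cat(sprintf("  Ka     = %g kBT/nm^2 (stretching)\n", x$Ka))
  cat(sprintf("  J0     = %g 1/nm     (spontaneous curvature)\n", x$J0))
  cat(sprintf("  h      = %g nm       (hydrophobic thickness)\n", x$h))
  cat(sprintf("  sigma0 = %g kBT/nm^2 (tension); alpha0 = %.3g\n",
              x$sigma0, x$alpha0))
  invisible(x)
}

#' Default membrane parameter set
#'
#' The reference parameterization of a liquid-ordered (`r`) / liquid-
#' disordered (`s`) phase pair: splay moduli 20 and 10 \eqn{k_B T},
#' monolayer hydrophobic thicknesses 1.8 and 1.3 nm, a common tilt modulus
#' of 40 mN/m and stretching modulus of 120 mN/m, zero spontaneous
#' curvatures, and a lateral tension of 0.025 \eqn{k_B T/\mathrm{nm}^2}
#' per monolayer.
#'
#' @param kBT_joules thermal energy in joules used for mN/m conversion.
#' @return a list with components `r` (liquid-ordered) and `s`
#'   (liquid-disordered), each a [monolayer_parameters()] object.
#' @export
default_membrane <- function(kBT_joules = 4e-21) {
  Kt <- mN_per_m_to_kBT_per_nm2(40, kBT_joules)
  Ka <- mN_per_m_to_kBT_per_nm2(120, kBT_joules)
  list(
    r = monolayer_parameters(B = 20, Kt = Kt, Ka = Ka, J0 = 0, h = 1.8,
                             sigma0 = 0.025),
    s = monolayer_parameters(B = 10, Kt = Kt, Ka = Ka, J0 = 0, h = 1.3,
                             sigma0 = 0.025)
  )
}

#' Read membrane phase parameters from a configuration list or file
#'
#' Accepts either a YAML/JSON file path or an already-parsed list with
#' entries `phase_r` and `phase_s`, each holding `B` (kBT), `Kt_mN_per_m`
#' or `Kt` (kBT/nm^2), `Ka_mN_per_m` or `Ka`, `J0` (1/nm) and `h` (nm),
#' plus optional top-level `sigma0` (kBT/nm^2) and `kBT_joules`.
#'
#' @param config file path or list.
#' @return a list with components `r` and `s` as in [default_membrane()].
#' @export
read_membrane_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  kBT <- config$kBT_joules %||% 4e-21
  sigma0 <- config$sigma0 %||% 0.025
  one <- function(ph) {
    if (is.null(ph)) stop("configuration must define phase_r and phase_s")
    Kt <- if (!is.null(ph$Kt_mN_per_m)) {
      mN_per_m_to_kBT_per_nm2(ph$Kt_mN_per_m, kBT)
    } else ph$Kt
    Ka <- if (!is.null(ph$Ka_mN_per_m)) {
      mN_per_m_to_kBT_per_nm2(ph$Ka_mN_per_m, kBT)
    } else ph$Ka
    monolayer_parameters(B = ph$B, Kt = Kt, Ka = Ka, J0 = ph$J0 %||% 0,
                         h = ph$h, sigma0 = ph$sigma0 %||% sigma0)
  }
  list(r = one(config$phase_r), s = one(config$phase_s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
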