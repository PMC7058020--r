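#' Characteristic decay lengths of bulk membrane deformations
#'
#' Deformations of a uniform bilayer relax exponentially away from a
#' perturbation.  The decay lengths follow from the characteristic roots
#' of the linearized bulk Euler-Lagrange system of the coupled two-leaflet
#' energy functional: with the interface height eliminated pointwise (it
#' enters the energy without derivatives), the functional reduces to
#' \eqn{f = v'^T P v'/2 + v'^T R v + v^T S v/2} in
#' \eqn{v = (n_u, n_l, H_u, H_l)}, whose exponential solutions
#' \eqn{v \propto e^{kx}} solve the quadratic eigenvalue problem
#' \eqn{(k^2 P + k(R - R^T) - S) w = 0}.  Decay lengths are
#' \eqn{1/|\mathrm{Re}\,k|} over roots with nonzero real part (roots come
#' in \eqn{\pm} pairs; the zero pair is the rigid vertical translation).
#' The lateral-tension term is omitted here: it only stiffens the soft
#' whole-bilayer bending branch, whose long relaxation scale is
#' energetically irrelevant to boundary and inclusion energetics; with it
#' omitted that branch sits exactly at \eqn{k = 0} and is filtered out,
#' leaving the thickness and tilt relaxation lengths.
#'
#' The result is symmetric under swapping the two leaflet parameter sets,
#' and is used to size the simulation box: the default box margin of
#' 20 nm is an order of magnitude above the slowest decay length of
#' typical parameters (1-2 nm).
#'
#' @param params_u,params_l [monolayer_parameters()] of the upper and
#'   lower leaflet.
#' @return sorted numeric vector of distinct decay lengths, nm.
#' @export
lambda_decay <- function(params_u, params_l) {
  stopifnot(inherits(params_u, "monolayer_parameters"),
            inherits(params_l, "monolayer_parameters"))
  pu <- params_u; pl <- params_l
  # pure quadratic part of the bulk density in perturbation variables
  # z = (n_u, n_l, H_u, H_l, n_u', n_l', H_u', H_l'), with the interface
  # height M minimized out in closed form
  dens <- function(z) {
    n_u <- z[1]; n_l <- z[2]; H_u <- z[3]; H_l <- z[4]
    np_u <- z[5]; np_l <- z[6]; Hp_u <- z[7]; Hp_l <- z[8]
    E_u <- -H_u / pu$h - (pu$h / 2) * np_u
    E_l <- H_l / pl$h - (pl$h / 2) * np_l
    p <- pu$Ka / pu$h; q <- pl$Ka / pl$h
    M <- (q * E_l - p * E_u) / (p / pu$h + q / pl$h)
    e_u <- E_u + M / pu$h
    e_l <- E_l - M / pl$h
    pu$B / 2 * np_u^2 + pu$Kt / 2 * (n_u - Hp_u)^2 +
      pu$Ka / 2 * e_u^2 +
      pl$B / 2 * np_l^2 + pl$Kt / 2 * (n_l + Hp_l)^2 +
      pl$Ka / 2 * e_l^2
  }
  # polarization identity: dens is exactly quadratic, so
  # Q[i, j] = dens(e_i + e_j) - dens(e_i) - dens(e_j)
  Q <- matrix(0, 8, 8)
  ee <- diag(8)
  di <- vapply(seq_len(8), function(i) dens(ee[i, ]), numeric(1))
  for (i in seq_len(8)) {
    for (j in i:8) {
      Q[i, j] <- Q[j, i] <- dens(ee[i, ] + ee[j, ]) - di[i] - di[j]
    }
  }
  S <- Q[1:4, 1:4]; P <- Q[5:8, 5:8]; R <- Q[5:8, 1:4]
  # companion linearization of (k^2 P + k (R - R^T) - S) w = 0
  comp <- rbind(cbind(matrix(0, 4, 4), diag(4)),
                cbind(solve(P, S), -solve(P, R - t(R))))
  k <- eigen(comp, only.values = TRUE)$values
  re <- abs(Re(k))
  # the soft whole-bilayer branch sits at k = 0 up to numerical splitting;
  # genuine thickness/tilt relaxation lengths are of order nanometres
  lam <- 1 / re[re > 1e-2]
  sort(unique(round(lam, 6)))
}
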