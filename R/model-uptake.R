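#' Critical film radius at which the leading row saturates
#'
#' Particle conservation over the first row of cells gives
#' \eqn{R_c \varphi_S = 3 \phi_{is} (d_{cell}/d)(V_{cell}/A_{cell})}: the
#' radius at which the internal particle concentration of the leading cells
#' reaches its saturation value. With the reference geometry (d = 1 um,
#' d_cell = 22 um, V_cell = 1600 um^3, A_cell = 770 um^2) the right-hand
#' coefficient is 137 um.
#'
#' @param phi_S Substrate surface fraction (> 0; `Inf` is returned at 0 —
#'   on a bare substrate the leading row never saturates).
#' @param up An [uptake_params()] (uses `phi_is`).
#' @param g A [cell_geometry()].
#' @param p A [particle_spec()].
#' @return Critical radius in um.
#' @export
critical_radius <- function(phi_S, up, g, p) {
  stopifnot(inherits(up, "uptake_params"), inherits(g, "cell_geometry"),
            inherits(p, "particle_spec"), phi_S >= 0, up$phi_is > 0)
  if (phi_S == 0) return(Inf)
  3 * up$phi_is * (g$d_cell / p$diameter) * (g$V_cell / g$A_cell) / phi_S
}

#' Aureole width from particle conservation
#'
#' For `R <= R_c` the aureole is the first row of cells, of constant width
#' `d_cell`. Beyond the critical radius, conservation of the particles
#' cleared from the substrate gives
#' \deqn{\Delta \left(3\frac{\phi_{is}}{d}\frac{V_{cell}}{A_{cell}} +
#'   4\phi_s\right) = R\,\varphi_S,}
#' so the width grows linearly with the film radius. The two branches are
#' continuous at `R = R_c` when no particles adsorb on the membrane
#' (`phi_s = 0`).
#'
#' @param R Film radius(es) in um (vectorized, > 0).
#' @param phi_S Substrate surface fraction.
#' @param up An [uptake_params()] (uses `phi_is` and `phi_s`).
#' @param g A [cell_geometry()].
#' @param p A [particle_spec()].
#' @return Aureole width(s) in um.
#' @export
aureole_width <- function(R, phi_S, up, g, p) {
  stopifnot(inherits(up, "uptake_params"), inherits(g, "cell_geometry"),
            inherits(p, "particle_spec"), all(R > 0), phi_S >= 0)
  if (phi_S == 0) return(rep(0, length(R)))
  if (up$phi_is == 0 && up$phi_s == 0) {
    stop("phi_is and phi_s are both zero with particles on the substrate: ",
         "cleared particles have nowhere to go")
  }
  Rc <- critical_radius(phi_S, up, g, p)
  denom <- 3 * up$phi_is * g$V_cell / (p$diameter * g$A_cell) + 4 * up$phi_s
  ifelse(R <= Rc, g$d_cell, R * phi_S / denom)
}

#' Membrane-adsorbed surface fraction
#'
#' Above a substrate-coverage threshold \eqn{\varphi_{S0}} the adsorbed
#' fraction grows linearly: \eqn{\phi_s = a(\varphi_S - \varphi_{S0})},
#' clipped at zero below the threshold.
#'
#' @param phi_S Substrate surface fraction(s) (vectorized).
#' @param up An [uptake_params()] (uses `a`, `phi_S0`).
#' @return Membrane surface fraction(s).
#' @export
membrane_fraction <- function(phi_S, up) {
  stopifnot(inherits(up, "uptake_params"), !is.na(up$a), !is.na(up$phi_S0),
            up$a >= 0)
  pmax(0, up$a * (phi_S - up$phi_S0))
}

#' Residual of the particle-conservation balance
#'
#' The number of particles stored in the aureole annulus (internalized at
#' concentration `C_i`, adsorbed on both membrane faces at surface
#' concentration `C_S`) must equal the number cleared from the substrate:
#' \deqn{\frac{2\pi R \Delta}{A_{cell}} (C_i V_{cell} + 2 C_S A_{cell}) =
#'   \pi R^2 \nu.}
#' Returns left minus right, normalized by the right-hand side when `nu > 0`.
#'
#' @param R Film radius in um.
#' @param Delta Aureole width in um.
#' @param C_i Internal particle concentration (particles/um^3).
#' @param C_S Membrane surface concentration (particles/um^2).
#' @param g A [cell_geometry()].
#' @param nu Substrate areal density (particles/um^2).
#' @return Dimensionless residual (raw residual in particles when `nu = 0`).
#' @export
conservation_residual <- function(R, Delta, C_i, C_S, g, nu) {
  stopifnot(inherits(g, "cell_geometry"),
            R >= 0, Delta >= 0, C_i >= 0, C_S >= 0, nu >= 0)
  lhs <- (2 * pi * R * Delta / g$A_cell) * (C_i * g$V_cell + 2 * C_S * g$A_cell)
  rhs <- pi * R^2 * nu
  res <- lhs - rhs
  if (nu > 0 && R > 0) res / rhs else res
}

#' Per-cell particle counts in the aureole
#'
#' Converts the fitted volume and surface fractions into particle numbers per
#' cell: internalized \eqn{n_i = \phi_{is} V_{cell} / v_p} and adsorbed
#' \eqn{n_s = 2 \phi_s A_{cell} / (\pi d^2/4)} (both membrane faces carry
#' particles, hence the factor 2). For flocculating particles the counts are
#' divided by the cluster factor and refer to clusters.
#'
#' @param up An [uptake_params()].
#' @param g A [cell_geometry()].
#' @param p A [particle_spec()].
#' @return A list with integer `n_i`, `n_s`, `n_tot`.
#' @export
particle_counts <- function(up, g, p) {
  stopifnot(inherits(up, "uptake_params"), inherits(g, "cell_geometry"),
            inherits(p, "particle_spec"))
  n_i <- up$phi_is * g$V_cell / particle_volume(p)
  n_s <- 2 * up$phi_s * g$A_cell / (pi * p$diameter^2 / 4)
  n_i <- round(n_i / p$cluster_factor)
  n_s <- round(n_s / p$cluster_factor)
  list(n_i = n_i, n_s = n_s, n_tot = n_i + n_s)
}
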