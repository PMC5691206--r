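#' Gravitational sedimentation length of a microparticle
#'
#' \eqn{l_S = k_B T / (v_p (\rho - \rho_{H_2O}) g)}. When `l_S` is smaller
#' than the particle diameter all particles fall to the substrate and the
#' areal density can be predicted from the suspension concentration; when it
#' is larger, sedimentation is partial and the coating must be measured
#' optically. Neutrally buoyant or buoyant particles (`rho <= medium
#' density`) do not sediment and the length is reported as `Inf`.
#'
#' @param p A [particle_spec()].
#' @param const A [physical_constants()].
#' @return A list with `length_um` (the sedimentation length, `Inf` if the
#'   particle does not sink), `sediments_fully` (`l_S < d`), and `sinks`
#'   (density exceeds the medium's).
#' @export
sedimentation_length <- function(p, const = physical_constants()) {
  stopifnot(inherits(p, "particle_spec"), inherits(const, "physical_constants"))
  delta_rho <- p$density - const$medium_density          # kg/m^3
  v_p_m3 <- particle_volume(p) * 1e-18                   # um^3 -> m^3
  if (delta_rho <= 0) {
    return(list(length_um = Inf, sediments_fully = FALSE, sinks = FALSE))
  }
  l_m <- const$thermal_energy / (v_p_m3 * delta_rho * const$gravity)
  l_um <- l_m * 1e6
  list(length_um = l_um, sediments_fully = l_um < p$diameter, sinks = TRUE)
}

#' Coating predicted from the suspension
#'
#' For fully sedimenting particles the areal density on the substrate is
#' \eqn{\nu = C H} (all particles in the column of height `H` end up on the
#' surface), and the surface fraction is \eqn{\varphi_S = \nu \pi d^2 / 4}.
#' When sedimentation is partial the areal density cannot be predicted and
#' must be supplied from an optical measurement.
#'
#' @param C Suspension concentration in particles/um^3.
#' @param H Chamber height in um.
#' @param p A [particle_spec()].
#' @param fully_sedimented Logical; whether all particles reach the substrate
#'   (`sedimentation_length(p)$sediments_fully` for heavy particles).
#' @param nu_measured Optically measured areal density (particles/um^2),
#'   required when `fully_sedimented` is `FALSE`.
#' @return A [coating_spec()].
#' @export
coating_from_suspension <- function(C, H, p, fully_sedimented = TRUE,
                                    nu_measured = NULL) {
  stopifnot(C >= 0, H > 0, inherits(p, "particle_spec"))
  if (fully_sedimented) {
    nu <- C * H
  } else {
    if (is.null(nu_measured)) {
      stop("partial sedimentation: the areal density cannot be predicted ",
           "from C*H and must be measured optically (supply `nu_measured`)")
    }
    nu <- nu_measured
  }
  coating_spec(nu, p, concentration = C, chamber_height = H)
}

#' Spread area of the precursor film
#'
#' The diffusive spreading law \eqn{A(t) = A_0 + R_0 V^* t}.
#'
#' @param t Time(s) in s (vectorized).
#' @param sp A [spreading_params()].
#' @return Area(s) in um^2.
#' @seealso [spread_radius()]
#' @export
spread_area <- function(t, sp) {
  stopifnot(inherits(sp, "spreading_params"), all(t >= 0))
  sp$A0 + sp$R0 * sp$V_star * t
}

#' Film radius at time t
#'
#' Equivalent-circle radius \eqn{R = \sqrt{A/\pi}} of the spread area.
#'
#' @inheritParams spread_area
#' @return Radius(es) in um.
#' @export
spread_radius <- function(t, sp) {
  sqrt(spread_area(t, sp) / pi)
}

#' Dissipation terms of the spreading balance
#'
#' The two friction contributions opposing the driving force: permeation of
#' cells from the aggregate into the film, \eqn{2\pi\eta R\dot{R}^2/R_L}, and
#' slippage of the expanding film on the substrate,
#' \eqn{2\pi k R^2 \dot{R}^2 \ln(R/R_L)}.
#'
#' @param R Film radius (um), `R >= R_L`.
#' @param R_dot Film front velocity (um/s).
#' @param fp A [friction_params()] (uses `viscosity`, `friction_coeff`,
#'   `contact_radius`).
#' @param R_L Contact-line radius; defaults to `fp$contact_radius`.
#' @return Named numeric vector `c(permeation =, slippage =)`.
#' @export
dissipation_terms <- function(R, R_dot, fp, R_L = fp$contact_radius) {
  stopifnot(inherits(fp, "friction_params"), is.finite(R_L), R_L > 0)
  if (R < R_L) stop("R must be >= the contact-line radius R_L")
  c(permeation = 2 * pi * fp$viscosity * R * R_dot^2 / R_L,
    slippage = 2 * pi * fp$friction_coeff * R^2 * R_dot^2 * log(R / R_L))
}

#' Is the permeation term dominant?
#'
#' Permeation dominates slippage when \eqn{\eta/R_L > k \ln(R/R_L)}, the
#' regime in which the diffusive spreading law holds (bulk tissue viscosity
#' much larger than the sliding friction).
#'
#' @inheritParams dissipation_terms
#' @return `TRUE` if permeation dominates.
#' @export
permeation_dominant <- function(fp, R, R_L = fp$contact_radius) {
  stopifnot(inherits(fp, "friction_params"), is.finite(R_L), R_L > 0)
  if (R < R_L) stop("R must be >= the contact-line radius R_L")
  fp$viscosity / R_L > fp$friction_coeff * log(R / R_L)
}

#' Spreading velocity on a particle-coated substrate
#'
#' \eqn{V^*(\varphi_S) = V^*(0)(1 + \alpha \varphi_S)} for
#' \eqn{\varphi_S \le \varphi_S^P}, constant above the plateau coverage
#' (hard clamp: the velocity remains constant upon further increase of
#' coverage once the spheres are densely packed).
#'
#' @param phi_S Substrate surface fraction(s), >= 0 (vectorized).
#' @param ep An [enhancement_params()].
#' @return Velocity(ies) in um/s.
#' @export
enhanced_velocity <- function(phi_S, ep) {
  stopifnot(inherits(ep, "enhancement_params"), all(phi_S >= 0))
  ep$V0 * (1 + ep$alpha * pmin(phi_S, ep$phi_plateau))
}

#' Passage time of a leading cell
#'
#' The time a first-row cell spends over fresh substrate before the front has
#' advanced by one cell diameter: \eqn{\tau_p = d_{cell} / V^*}. Substrate
#' clearing requires internalization to complete within this window.
#'
#' @param g A [cell_geometry()].
#' @param V_star Spreading velocity in um/s.
#' @return Time in s (`Inf` for a stalled front).
#' @export
passage_time <- function(g, V_star) {
  stopifnot(inherits(g, "cell_geometry"), V_star >= 0)
  if (V_star == 0) return(Inf)
  g$d_cell / V_star
}

#' Can the front clear the substrate?
#'
#' `TRUE` iff the internalization time is strictly smaller than the passage
#' time, so a leading cell finishes engulfing the particles under it before
#' the front moves on. Particles larger than a few um violate this and are
#' pushed ahead of the film instead.
#'
#' @param ct A [clearing_times()].
#' @return Logical.
#' @export
clearing_feasible <- function(ct) {
  stopifnot(inherits(ct, "clearing_times"))
  ct$tau_i < ct$tau_p
}
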