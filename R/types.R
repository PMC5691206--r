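#' Physical constants for sedimentation calculations
#'
#' Bundles the thermal energy, gravitational acceleration and medium (water)
#' density used by [sedimentation_length()]. Defaults correspond to room
#' temperature aqueous medium.
#'
#' @param thermal_energy Thermal energy \eqn{k_B T} in joules.
#' @param gravity Gravitational acceleration in m/s^2.
#' @param medium_density Density of the suspending medium in kg/m^3.
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(thermal_energy = 4.11e-21,
                               gravity = 9.81,
                               medium_density = 1000) {
  stopifnot(thermal_energy > 0, gravity > 0, medium_density > 0)
  structure(list(thermal_energy = thermal_energy, gravity = gravity,
                 medium_density = medium_density),
            class = "physical_constants")
}

#' Microparticle specification
#'
#' @param diameter Particle diameter in um. For flocculating particles this is
#'   the hydrodynamic diameter of the primary particle.
#' @param density Particle mass density in kg/m^3.
#' @param cluster_factor Effective number of primary particles per internalized
#'   unit (>= 1); relevant for flocculating suspensions where counts refer to
#'   clusters rather than single beads.
#' @param label Free-text label.
#' @return An object of class `particle_spec`.
#' @seealso [particle_volume()]
#' @export
particle_spec <- function(diameter, density = 1050, cluster_factor = 1,
                          label = "") {
  stopifnot(diameter > 0, density > 0, cluster_factor >= 1)
  structure(list(diameter = diameter, density = density,
                 cluster_factor = cluster_factor, label = label),
            class = "particle_spec")
}

#' Particle volume
#'
#' Volume of a single spherical particle, \eqn{v_p = (\pi/6) d^3}.
#'
#' @param p A [particle_spec()].
#' @return Volume in um^3.
#' @export
particle_volume <- function(p) {
  stopifnot(inherits(p, "particle_spec"))
  pi / 6 * p$diameter^3
}

#' Substrate coating specification
#'
#' Areal number density and surface fraction of microparticles sedimented on
#' the substrate. The surface fraction \eqn{\varphi_S = \nu \pi d^2/4} may
#' exceed 1 when several particle layers are deposited.
#'
#' @param areal_density Particles per um^2 on the substrate.
#' @param particle A [particle_spec()].
#' @param concentration Optional suspension concentration (particles/um^3)
#'   the coating was derived from.
#' @param chamber_height Optional chamber height in um.
#' @return An object of class `coating_spec` with fields `areal_density` and
#'   `surface_fraction`.
#' @export
coating_spec <- function(areal_density, particle, concentration = NA_real_,
                         chamber_height = NA_real_) {
  stopifnot(areal_density >= 0, inherits(particle, "particle_spec"))
  structure(list(
    areal_density = areal_density,
    surface_fraction = areal_density * pi * particle$diameter^2 / 4,
    concentration = concentration,
    chamber_height = chamber_height,
    particle = particle
  ), class = "coating_spec")
}

#' Cell geometry of the spreading monolayer
#'
#' Independent measurements: the diameter of first-row cells, the cell volume
#' (measured on spherical cells in suspension) and the projected area of a
#' spread cell. `(pi/6) d_cell^3` need not equal `V_cell`.
#'
#' @param d_cell First-row cell diameter in um.
#' @param V_cell Cell volume in um^3. The default 1600 is the value used in
#'   the conservation-model worked example; 1620 is the direct measurement on
#'   suspended cells and can be supplied instead.
#' @param A_cell Projected area of a spread cell in um^2.
#' @param nucleus_fraction Volume fraction of the cell occupied by the nucleus.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(d_cell = 22, V_cell = 1600, A_cell = 770,
                          nucleus_fraction = 0.25) {
  stopifnot(d_cell >= 0, V_cell > 0, A_cell > 0,
            nucleus_fraction >= 0, nucleus_fraction < 1)
  structure(list(d_cell = d_cell, V_cell = V_cell, A_cell = A_cell,
                 nucleus_fraction = nucleus_fraction),
            class = "cell_geometry")
}

#' Friction parameters of the spreading film
#'
#' Parameters of the dissipation balance: tissue viscosity, film-substrate
#' friction coefficient, permeation-region width, spreading parameter, and the
#' contact-line radius between aggregate and film.
#'
#' @param viscosity Tissue viscosity (consistent units).
#' @param friction_coeff Film-substrate friction coefficient (>= 0).
#' @param permeation_width Width of the permeation region (length > 0).
#' @param spreading_parameter Net driving force per unit length of contact
#'   line exerted by the motile peripheral cells.
#' @param contact_radius Radius of the aggregate-film contact line, close to
#'   the aggregate radius.
#' @return An object of class `friction_params`.
#' @export
friction_params <- function(viscosity, friction_coeff = 0,
                            permeation_width = 1, spreading_parameter = NA_real_,
                            contact_radius = NA_real_) {
  stopifnot(viscosity > 0, friction_coeff >= 0, permeation_width > 0)
  structure(list(viscosity = viscosity, friction_coeff = friction_coeff,
                 permeation_width = permeation_width,
                 spreading_parameter = spreading_parameter,
                 contact_radius = contact_radius),
            class = "friction_params")
}

#' Spreading-law parameters
#'
#' The precursor film spreads diffusively: \eqn{(A - A_0)/R_0 = V^* t} with
#' diffusion coefficient \eqn{D = V^* R_0}.
#'
#' @param V_star Spreading velocity in um/s.
#' @param R0 Initial aggregate radius in um.
#' @param A0 Initial contact area in um^2; defaults to `pi * R0^2` (spherical
#'   aggregate).
#' @return An object of class `spreading_params` with derived `D = V_star*R0`.
#' @export
spreading_params <- function(V_star, R0, A0 = pi * R0^2) {
  stopifnot(R0 > 0, A0 >= 0)
  structure(list(V_star = V_star, R0 = R0, A0 = A0, D = V_star * R0),
            class = "spreading_params")
}

#' Velocity-enhancement parameters
#'
#' Substrate roughness due to deposited particles increases the spreading
#' parameter: \eqn{V^*(\varphi_S) = V^*(0)(1 + \alpha \varphi_S)} up to a
#' plateau coverage \eqn{\varphi_S^P}, above which the velocity is constant.
#'
#' @param V0 Bare-substrate spreading velocity \eqn{V^*(0)} in um/s.
#' @param alpha Dimensionless enhancement slope.
#' @param phi_plateau Coverage \eqn{\varphi_S^P} at which the velocity
#'   plateaus (dense sphere packing).
#' @return An object of class `enhancement_params`.
#' @export
enhancement_params <- function(V0, alpha = 0, phi_plateau = Inf) {
  stopifnot(V0 > 0, is.finite(alpha), phi_plateau > 0)
  structure(list(V0 = V0, alpha = alpha, phi_plateau = phi_plateau),
            class = "enhancement_params")
}

#' Uptake parameters of the particle-conservation model
#'
#' @param phi_is Saturation volume fraction of internalized particles in a
#'   cell (0 <= phi_is < 1).
#' @param phi_s Surface fraction of the cell membrane covered by adsorbed
#'   particles (>= 0); zero below the substrate-coverage threshold `phi_S0`.
#' @param a Dimensionless slope of the adsorption law
#'   \eqn{\phi_s = a(\varphi_S - \varphi_{S0})}.
#' @param phi_S0 Substrate-coverage threshold above which membrane adsorption
#'   sets in.
#' @return An object of class `uptake_params`.
#' @export
uptake_params <- function(phi_is, phi_s = 0, a = NA_real_, phi_S0 = NA_real_) {
  stopifnot(phi_is >= 0, phi_is < 1, phi_s >= 0)
  if (!is.na(a)) stopifnot(a >= 0)
  structure(list(phi_is = phi_is, phi_s = phi_s, a = a, phi_S0 = phi_S0),
            class = "uptake_params")
}

#' Clearing time scales
#'
#' @param tau_i Particle internalization time in s.
#' @param tau_p Passage time in s: the time a leading cell spends over fresh
#'   substrate, `d_cell / V_star`.
#' @return An object of class `clearing_times`.
#' @export
clearing_times <- function(tau_i, tau_p) {
  stopifnot(tau_i >= 0, tau_p >= 0)
  structure(list(tau_i = tau_i, tau_p = tau_p), class = "clearing_times")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s: d = %g um, rho = %g kg/m^3, v_p = %.4g um^3",
              if (nzchar(x$label)) x$label else "unnamed",
              x$diameter, x$density, particle_volume(x)))
  if (x$cluster_factor != 1)
    cat(sprintf(", cluster_factor = %g", x$cluster_factor))
  cat("\n")
  invisible(x)
}

#' @export
print.coating_spec <- function(x, ...) {
  cat(sprintf("<coating_spec> nu = %.4g /um^2, phi_S = %.4g\n",
              x$areal_density, x$surface_fraction))
  invisible(x)
}
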