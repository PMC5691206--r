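# Preset parameter sets for the three studied particle types plus the bare
# substrate. Velocities in um/s; phi_is/phi_S0 from the uptake analysis;
# velocity_sd is the across-aggregate standard deviation of fitted V*.
.presets <- function() {
  list(
    bare = list(
      particle = list(d_um = 1, rho_kg_m3 = 1050, cluster_factor = 1,
                      label = "none"),
      coating = list(phi_S = 0),
      uptake = list(phi_is = 0.11, a = 0.9, phi_S0 = 0.2),
      enhancement = list(V_star0_um_s = 4.9e-2, alpha = 1.3,
                         phi_S_plateau = 0.6),
      velocity_sd_um_s = 0.9e-2
    ),
    SiO2Carbo1000 = list(
      particle = list(d_um = 1, rho_kg_m3 = 2000, cluster_factor = 1,
                      label = "SiO2Carbo1000"),
      coating = list(phi_S = 0.22),
      uptake = list(phi_is = 0.21, a = 0.9, phi_S0 = 0.46),
      enhancement = list(V_star0_um_s = 4.9e-2, alpha = 1.3,
                         phi_S_plateau = 0.6),
      velocity_sd_um_s = 1.1e-2
    ),
    PsCarbo1000 = list(
      particle = list(d_um = 1, rho_kg_m3 = 1050, cluster_factor = 1,
                      label = "PsCarbo1000"),
      coating = list(phi_S = 0.2),
      uptake = list(phi_is = 0.11, a = 0.9, phi_S0 = 0.2),
      enhancement = list(V_star0_um_s = 4.9e-2, alpha = 1.3,
                         phi_S_plateau = 0.6),
      velocity_sd_um_s = 1.7e-2
    ),
    PsAmine200 = list(
      particle = list(d_um = 0.8, rho_kg_m3 = 1050, cluster_factor = 1,
                      label = "PsAmine200"),
      coating = list(phi_S = 0.2),
      uptake = list(phi_is = 0.23, a = 0.9, phi_S0 = 0.5),
      # flocculating suspension: no coverage trend, flat velocity
      enhancement = list(V_star0_um_s = 5.9e-2, alpha = 0,
                         phi_S_plateau = Inf),
      velocity_sd_um_s = 2.0e-2
    )
  )
}

.config_keys <- c("preset", "particle", "coating", "uptake", "enhancement",
                  "geometry", "sim", "optics", "zstack", "velocity_sd_um_s")

#' Load a named preset configuration
#'
#' Returns a fully populated pipeline configuration for one of the studied
#' particle types (`"SiO2Carbo1000"`, `"PsCarbo1000"`, `"PsAmine200"`) or the
#' bare substrate (`"bare"`). The preset encodes the particle geometry and
#' density, the uptake parameters (`phi_is`, `a`, `phi_S0`), the velocity
#' enhancement law, and the simulation/rendering defaults (aggregate radius
#' 75 um, one frame every 10 min over 15 h, 5% multiplicative area noise).
#'
#' @param name Preset name.
#' @param ... Named overrides merged into the configuration, e.g.
#'   `coating = list(phi_S = 0.44)` or `sim = list(duration_s = 7200)`.
#' @return An object of class `pipeline_config` (a named nested list with
#'   plain scalar leaves, serializable with [write_config()]).
#' @export
load_preset <- function(name, ...) {
  presets <- .presets()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available presets: ",
         paste(names(presets), collapse = ", "))
  }
  cfg <- presets[[name]]
  cfg$preset <- name
  cfg$geometry <- list(d_cell_um = 22, V_cell_um3 = 1600, A_cell_um2 = 770,
                       nucleus_fraction = 0.25)
  cfg$sim <- list(R0_um = 75, duration_s = 54000, dt_s = 600,
                  area_noise = 0.05, n_aggregates = 20)
  cfg$optics <- list(pixel_size_um = 2, fov_um = 1100, noise_sd = 0.01)
  cfg$zstack <- list(pixel_size_um = 0.25, z_step_um = 0.25)
  cfg <- .merge_config(cfg, list(...))
  validate_config(cfg)
}

# recursive merge of override lists into a base config
.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Rejects unknown top-level or nested keys and checks basic value sanity
#' (non-negative noise, positive pixel size, ...).
#'
#' @param cfg A configuration list.
#' @return The validated config, classed `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  sub_keys <- list(
    particle = c("d_um", "rho_kg_m3", "cluster_factor", "label"),
    coating = c("phi_S", "nu_um2", "C_um3", "H_um"),
    uptake = c("phi_is", "a", "phi_S0"),
    enhancement = c("V_star0_um_s", "alpha", "phi_S_plateau"),
    geometry = c("d_cell_um", "V_cell_um3", "A_cell_um2", "nucleus_fraction"),
    sim = c("R0_um", "duration_s", "dt_s", "area_noise", "n_aggregates"),
    optics = c("pixel_size_um", "fov_um", "noise_sd"),
    zstack = c("pixel_size_um", "z_step_um")
  )
  for (section in names(sub_keys)) {
    if (is.null(cfg[[section]])) next
    bad <- setdiff(names(cfg[[section]]), sub_keys[[section]])
    if (length(bad) > 0) {
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "))
    }
  }
  if (!is.null(cfg$sim$area_noise) && any(cfg$sim$area_noise < 0)) {
    stop("area_noise must be >= 0")
  }
  if (!is.null(cfg$optics$pixel_size_um) && cfg$optics$pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> preset:", x$preset %||% "(custom)",
      "| phi_S:", paste(x$coating$phi_S, collapse = ", "),
      "| V*(0):", x$enhancement$V_star0_um_s, "um/s\n")
  invisible(x)
}

#' Write / read a configuration as YAML
#'
#' Round-trips losslessly: `read_config(write_config(cfg, path))` equals
#' `cfg`.
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   validated `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  # Inf is not representable in YAML 1.1 core; use the .inf tag convention
  yaml::write_yaml(unclass(cfg), path,
                   handlers = list(numeric = function(x) {
                     if (length(x) == 1 && is.infinite(x)) ".inf" else x
                   }))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- rapply(raw, function(x) {
    if (identical(x, ".inf")) Inf else x
  }, how = "replace")
  validate_config(raw)
}

# Convenience converters from config sections to the model's typed objects
cfg_particle <- function(cfg) {
  particle_spec(cfg$particle$d_um, cfg$particle$rho_kg_m3,
                cfg$particle$cluster_factor, cfg$particle$label)
}
cfg_geometry <- function(cfg) {
  cell_geometry(cfg$geometry$d_cell_um, cfg$geometry$V_cell_um3,
                cfg$geometry$A_cell_um2, cfg$geometry$nucleus_fraction)
}
cfg_enhancement <- function(cfg) {
  enhancement_params(cfg$enhancement$V_star0_um_s, cfg$enhancement$alpha,
                     cfg$enhancement$phi_S_plateau)
}
cfg_uptake <- function(cfg, phi_S = NULL) {
  phi_S <- phi_S %||% cfg$coating$phi_S[1]
  up <- uptake_params(cfg$uptake$phi_is, a = cfg$uptake$a,
                      phi_S0 = cfg$uptake$phi_S0)
  up$phi_s <- membrane_fraction(phi_S, up)
  up
}

#' Published uptake parameters per particle type and coverage
#'
#' The fitted saturation fraction `phi_is`, membrane fraction `phi_s` and
#' adsorption threshold `phi_S0` at each studied substrate coverage, for the
#' three particle types. These are model parameters (inputs to
#' [particle_counts()] and [build_table1()]); the per-cell counts are always
#' recomputed from them.
#'
#' @return A data frame with columns `particle`, `d_um`, `phi_S`, `phi_is`,
#'   `phi_s`, `phi_S0`.
#' @export
table1_parameters <- function() {
  rbind(
    data.frame(particle = "PsAmine200", d_um = 0.8,
               phi_S = c(0.05, 0.31, 0.40, 0.45, 0.8, 1.2),
               phi_is = 0.23,
               phi_s = c(0, 0, 0, 0, 0.28, 0.47),
               phi_S0 = 0.5),
    data.frame(particle = "PsCarbo1000", d_um = 1,
               phi_S = c(0.13, 0.19, 0.23, 0.8, 1.2),
               phi_is = 0.11,
               phi_s = c(0, 0, 0, 0.43, 0.80),
               phi_S0 = 0.2),
    data.frame(particle = "SiO2Carbo1000", d_um = 1,
               phi_S = c(0.22, 0.44, 0.71, 1.06, 1.42),
               phi_is = 0.21,
               phi_s = c(0, 0, 0.22, 0.57, 0.87),
               phi_S0 = 0.46)
  )
}
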