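#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order on one configuration:
#' \describe{
#'   \item{simulate}{trajectories and front-uptake series for every coverage
#'     level in `cfg$coating$phi_S` -> `trajectories.csv`, `front_states.csv`}
#'   \item{render}{final-time micrograph per level -> `frame_<phi>.tif` (+
#'     YAML sidecars)}
#'   \item{measure}{film area, aureole width, surface fraction per frame ->
#'     `measurements.csv`}
#'   \item{fit}{per-aggregate velocity fits, enhancement fit across levels
#'     (when >= 4), uptake fit across levels (when >= 3) -> `fits.csv`}
#'   \item{report}{per-cell count table and a manifest with the seed, config
#'     hash and md5 of every artifact -> `table1.csv`, `manifest.yaml`}
#' }
#' Later stages read only the files earlier stages wrote; a stage whose
#' inputs are missing stops with a dependency error, so stages can be re-run
#' selectively.
#'
#' @param cfg A `pipeline_config`; `cfg$coating$phi_S` may be a vector of
#'   coverage levels.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; all stage randomness derives from it.
#' @param stages Character vector of stages to run, in canonical order.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, seed = 1,
                         stages = c("simulate", "render", "measure", "fit",
                                    "report")) {
  cfg <- validate_config(unclass(cfg))
  all_stages <- c("simulate", "render", "measure", "fit", "report")
  stopifnot(all(stages %in% all_stages))
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  levels <- cfg$coating$phi_S
  path <- function(...) file.path(out_dir, ...)
  need <- function(file, stage, producer) {
    if (!file.exists(file)) {
      stop("stage '", stage, "' requires ", basename(file),
           " produced by stage '", producer, "'; run it first")
    }
    file
  }
  write_config(cfg, path("config.yaml"))
  message("pipeline: levels phi_S = ", paste(levels, collapse = ", "),
          " | seed = ", seed)

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    seeds <- derive_seeds(seed, length(levels))
    traj_rows <- list(); front_rows <- list()
    for (i in seq_along(levels)) {
      cfg_i <- validate_config(.merge_config(unclass(cfg),
                                             list(coating = list(phi_S = levels[i]))))
      trajs <- make_trajectories(cfg_i, seed = seeds[i])
      traj_rows[[i]] <- do.call(rbind, lapply(seq_along(trajs), function(k) {
        data.frame(phi_S = levels[i], aggregate = k, t_s = trajs[[k]]$t,
                   A_um2 = trajs[[k]]$A, R0_um = trajs[[k]]$R0,
                   V_true_um_s = trajs[[k]]$V_true)
      }))
      if (levels[i] > 0) {
        fs <- simulate_front_uptake(cfg_i)
        front_rows[[i]] <- cbind(phi_S = levels[i], fs$states)
      }
    }
    write.csv(do.call(rbind, traj_rows), path("trajectories.csv"),
              row.names = FALSE)
    front <- do.call(rbind, front_rows)
    if (is.null(front)) {
      front <- data.frame(phi_S = numeric(0), t = numeric(0), R = numeric(0),
                          Delta = numeric(0))
    }
    write.csv(front, path("front_states.csv"), row.names = FALSE)
    message(sprintf("  simulate: done in %.1fs",
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("render" %in% stages) {
    t0 <- Sys.time()
    front_file <- need(path("front_states.csv"), "render", "simulate")
    front <- read.csv(front_file)
    seeds <- derive_seeds(seed + 1, length(levels))
    g <- cfg_geometry(cfg)
    for (i in seq_along(levels)) {
      phi <- levels[i]
      if (phi > 0 && any(front$phi_S == phi)) {
        last <- front[front$phi_S == phi, ]
        last <- last[nrow(last), ]
        R_i <- last$R; D_i <- last$Delta
      } else {
        sp <- spreading_params(enhanced_velocity(phi, cfg_enhancement(cfg)),
                               cfg$sim$R0_um)
        R_i <- spread_radius(cfg$sim$duration_s, sp); D_i <- 0
      }
      frame <- render_micrograph(cfg$sim$R0_um, R_i, D_i, phi, cfg$optics,
                                 d_cell = g$d_cell, seed = seeds[i])
      write_frame_tiff(frame, path(sprintf("frame_%03d.tif", i)))
    }
    message(sprintf("  render: %d frame(s) in %.1fs", length(levels),
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("measure" %in% stages) {
    t0 <- Sys.time()
    rows <- lapply(seq_along(levels), function(i) {
      f <- need(path(sprintf("frame_%03d.tif", i)), "measure", "render")
      frame <- read_frame_tiff(f)
      film <- measure_film_area(frame)
      aur <- measure_aureole_width(frame)
      data.frame(t_s = cfg$sim$duration_s, A_um2 = film$area_um2,
                 R_um = aur$R_um, Delta_um = aur$Delta_um,
                 phi_S = measure_surface_fraction(frame),
                 phi_S_nominal = levels[i])
    })
    write.csv(do.call(rbind, rows), path("measurements.csv"),
              row.names = FALSE)
    message(sprintf("  measure: done in %.1fs",
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("fit" %in% stages) {
    t0 <- Sys.time()
    traj <- read.csv(need(path("trajectories.csv"), "fit", "simulate"))
    meas <- read.csv(need(path("measurements.csv"), "fit", "measure"))
    vel_rows <- do.call(rbind, lapply(split(traj, traj[c("phi_S", "aggregate")],
                                            drop = TRUE), function(d) {
      fit <- fit_velocity(list(t = d$t_s, A = d$A_um2, R0 = d$R0_um[1]))
      data.frame(phi_S = d$phi_S[1], aggregate = d$aggregate[1],
                 V_star_um_s = fit$estimates[["V_star"]],
                 se_um_s = fit$se[["V_star"]])
    }))
    write.csv(vel_rows, path("velocity_fits.csv"), row.names = FALSE)
    summary_rows <- data.frame(parameter = character(0), value = numeric(0))
    mean_v <- tapply(vel_rows$V_star_um_s, vel_rows$phi_S, mean)
    if (length(mean_v) >= 4) {
      enh <- fit_enhancement(as.numeric(names(mean_v)), as.numeric(mean_v))
      summary_rows <- rbind(summary_rows,
                            data.frame(parameter = c("V0", "alpha",
                                                     "phi_plateau"),
                                       value = as.numeric(enh$estimates)))
    }
    pos <- meas[meas$phi_S_nominal > 0 & meas$Delta_um > 0, ]
    if (nrow(pos) >= 3) {
      upt <- fit_uptake(pos$phi_S_nominal, pos$Delta_um / pos$R_um,
                        cfg_geometry(cfg), cfg_particle(cfg))
      summary_rows <- rbind(summary_rows,
                            data.frame(parameter = c("phi_is", "a", "phi_S0"),
                                       value = as.numeric(upt$estimates)))
    }
    write.csv(summary_rows, path("fits.csv"), row.names = FALSE)
    message(sprintf("  fit: done in %.1fs",
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  manifest <- NULL
  if ("report" %in% stages) {
    t0 <- Sys.time()
    need(path("fits.csv"), "report", "fit")
    write.csv(build_table1(g = cfg_geometry(cfg)), path("table1.csv"),
              row.names = FALSE)
    artifacts <- sort(setdiff(list.files(out_dir), "manifest.yaml"))
    hashes <- as.list(tools::md5sum(file.path(out_dir, artifacts)))
    names(hashes) <- artifacts
    manifest <- list(seed = seed,
                     config_md5 = unname(tools::md5sum(path("config.yaml"))),
                     artifacts = hashes)
    yaml::write_yaml(manifest, path("manifest.yaml"))
    message(sprintf("  report: manifest with %d artifact(s) in %.1fs",
                    length(artifacts),
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  invisible(manifest)
}
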