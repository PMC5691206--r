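#' Simulate a noisy spreading trajectory
#'
#' Generates one aggregate's spread-area time series under the diffusive
#' spreading law. The aggregate's effective velocity is drawn once from a
#' normal law (mean given by the enhancement law at the configured coverage,
#' SD `velocity_sd_um_s` — the across-aggregate dispersion), then each area
#' sample receives multiplicative Gaussian noise of relative SD
#' `sim$area_noise`.
#'
#' @param cfg A `pipeline_config` from [load_preset()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `spreading_record`: list with `t` (s), `A`
#'   (um^2), `R0`, `A0`, `phi_S`, and the true drawn velocity `V_true`.
#' @export
make_trajectory <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$sim$area_noise < 0) stop("area_noise must be >= 0")
  with_seed(seed, {
    phi_S <- cfg$coating$phi_S[1]
    V_mean <- enhanced_velocity(phi_S, cfg_enhancement(cfg))
    V_eff <- rnorm(1, V_mean, cfg$velocity_sd_um_s)
    R0 <- cfg$sim$R0_um
    t <- seq(0, cfg$sim$duration_s, by = cfg$sim$dt_s)
    sp <- spreading_params(V_eff, R0)
    A <- spread_area(t, sp) * (1 + rnorm(length(t), 0, cfg$sim$area_noise))
    structure(list(t = t, A = A, R0 = R0, A0 = sp$A0, phi_S = phi_S,
                   V_true = V_eff),
              class = "spreading_record")
  })
}

#' Simulate an ensemble of spreading trajectories
#'
#' @inheritParams make_trajectory
#' @param n Number of aggregates; defaults to `cfg$sim$n_aggregates`.
#' @return A list of `spreading_record`s.
#' @export
make_trajectories <- function(cfg, n = cfg$sim$n_aggregates, seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1), n)
  lapply(seeds, function(s) make_trajectory(cfg, seed = s))
}

#' Discrete front-uptake simulation
#'
#' Simulates the collective clearing mechanism cell row by cell row: the film
#' front advances under the spreading law; at every step the particles swept
#' from the newly covered annulus are ingested by the outermost row of cells
#' that still has internal capacity (`n_i = phi_is * V_cell / v_p` per cell),
#' then adsorbed on its membrane (up to `n_s` per cell, only above the
#' adsorption threshold `phi_S0`), and any leftover is handed to the next row
#' inward. The aureole width is the number of internally saturated rows times
#' `d_cell`. All bookkeeping is in integer particle counts and conserves the
#' total exactly at every step.
#'
#' Rows are annuli of width `d_cell` anchored at the advancing front (row 1
#' outermost); the number of cells in a row is its annulus area divided by
#' `A_cell`, re-evaluated as the front grows.
#'
#' @param cfg A `pipeline_config`; `cfg$coating$phi_S` must be > 0.
#' @param V_star Front velocity in um/s; defaults to the enhancement law at
#'   the configured coverage (the simulation itself is deterministic).
#' @return An object of class `front_state`: list with `states` (data frame:
#'   `t`, `R`, `Delta`, `n_saturated_rows`, `swept`, `ingested`, `adsorbed`,
#'   `substrate_remaining`), `rows` (final per-row integer loads), `n_i`,
#'   `n_s_cell`, `initial_total`, and the configuration scalars used.
#' @export
simulate_front_uptake <- function(cfg, V_star = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  phi_S <- cfg$coating$phi_S[1]
  if (phi_S < 0) stop("phi_S must be >= 0")
  g <- cfg_geometry(cfg)
  p <- cfg_particle(cfg)
  if (g$A_cell <= 0) stop("A_cell must be > 0")
  V_star <- V_star %||% enhanced_velocity(phi_S, cfg_enhancement(cfg))
  nu <- phi_S / (pi * p$diameter^2 / 4)            # particles per um^2
  n_i <- max(1L, as.integer(round(cfg$uptake$phi_is * g$V_cell /
                                    particle_volume(p))))
  phi_s_cell <- max(0, cfg$uptake$a * (phi_S - cfg$uptake$phi_S0))
  n_s_cell <- as.integer(round(2 * phi_s_cell * g$A_cell /
                                 (pi * p$diameter^2 / 4)))

  R0 <- cfg$sim$R0_um
  t <- seq(0, cfg$sim$duration_s, by = cfg$sim$dt_s)
  sp <- spreading_params(V_star, R0)
  R <- sqrt(spread_area(t, sp) / pi)
  # integer particles swept by the front, via cumulative rounding so that
  # per-step counts sum exactly to the cumulative total; a bare substrate
  # sweeps nothing and the aureole never forms
  swept_cum <- round(nu * pi * (R^2 - R0^2))
  initial_total <- swept_cum[length(swept_cum)]

  load_i <- integer(0)   # internalized particles per row (row 1 = outermost)
  load_s <- integer(0)   # adsorbed particles per row
  n_steps <- length(t)
  out <- data.frame(t = t, R = R, Delta = 0, n_saturated_rows = 0L,
                    swept = swept_cum, ingested = 0L, adsorbed = 0L,
                    substrate_remaining = initial_total - swept_cum)

  # fractional number of cells in a row: one d_cell-wide annulus counted on
  # the front circumference (the thin-annulus counting the conservation
  # model itself uses, 2*pi*R*Delta/A_cell cells in the aureole); capacities
  # are floored to integers so the particle ledger stays exact
  row_cells <- function(j, R_now) {
    max(1, 2 * pi * R_now * g$d_cell / g$A_cell)
  }

  for (s in seq_len(n_steps)) {
    avail <- swept_cum[s] - if (s > 1) swept_cum[s - 1] else 0
    j <- 1L
    while (avail > 0) {
      if (j > length(load_i)) {
        load_i <- c(load_i, 0L)
        load_s <- c(load_s, 0L)
      }
      cells <- row_cells(j, R[s])
      cap_i <- floor(cells * n_i)
      take <- min(avail, max(0, cap_i - load_i[j]))
      load_i[j] <- load_i[j] + take
      avail <- avail - take
      if (avail > 0 && n_s_cell > 0) {
        cap_s <- floor(cells * n_s_cell)
        take_s <- min(avail, max(0, cap_s - load_s[j]))
        load_s[j] <- load_s[j] + take_s
        avail <- avail - take_s
      }
      j <- j + 1L
      if (j > 10000L) stop("front-uptake row overflow")  # defensive
    }
    if (length(load_i) > 0) {
      cells_now <- vapply(seq_along(load_i), row_cells, numeric(1),
                          R_now = R[s])
      saturated <- load_i >= floor(cells_now * n_i)
      # saturated rows form a prefix (rows are filled outside-in)
      m <- if (all(saturated)) length(saturated) else which(!saturated)[1] - 1L
    } else m <- 0L
    out$n_saturated_rows[s] <- m
    out$Delta[s] <- m * g$d_cell
    out$ingested[s] <- sum(load_i)
    out$adsorbed[s] <- sum(load_s)
  }

  structure(list(states = out, rows = data.frame(load_i = load_i,
                                                 load_s = load_s),
                 n_i = n_i, n_s_cell = n_s_cell,
                 initial_total = initial_total,
                 phi_S = phi_S, V_star = V_star, R0 = R0),
            class = "front_state")
}
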