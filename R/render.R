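# Default bright-field-like intensity levels. The ordering is the rendering
# contract the measurement module relies on:
#   aureole (darkest) < aggregate < speckle dot < background < film (brightest)
.default_intensities <- function() {
  list(background = 0.55, speckle = 0.30, speckle2 = 0.18,
       film = 0.95, aggregate = 0.08, aureole = 0.05)
}

#' Render a bright-field-like micrograph of a spreading aggregate
#'
#' Draws the concentric scene observed in bright field: the dark aggregate
#' disk (radius `R0`), the cleared film (bright, much brighter than the
#' coated substrate), the aureole annulus of particle-laden cells (darkest,
#' width `Delta`, inner edge at `R - Delta`), and the outer microparticle
#' carpet rendered as per-pixel Bernoulli speckle at coverage `phi_S`
#' (coverages above 1 deposit a second, darker speckle layer). The ground
#' truth is embedded in the frame.
#'
#' @param R0 Aggregate radius in um.
#' @param R Film radius in um (outer edge of the aureole).
#' @param Delta Aureole width in um (`0 <= Delta <= R - R0`).
#' @param phi_S Substrate surface fraction of the carpet.
#' @param optics List with `pixel_size_um`, `fov_um`, and optional `noise_sd`
#'   (additive Gaussian intensity noise, default 0.01) and `intensities`.
#' @param d_cell First-row cell diameter (um), used to check that the pixel
#'   size resolves single cells (>= 4 px per cell).
#' @param seed Integer seed for the speckle and noise.
#' @return An object of class `image_frame`: list with `pixels` (numeric
#'   matrix in \[0, 1\]), `pixel_size_um`, and `truth` (list with `R0`, `R`,
#'   `Delta`, `phi_S`, `A = pi R^2`, `center_px`).
#' @export
render_micrograph <- function(R0, R, Delta, phi_S, optics, d_cell = 22,
                              seed = NULL) {
  px <- optics$pixel_size_um
  fov <- optics$fov_um
  stopifnot(px > 0, fov > 0, R >= R0, Delta >= 0, Delta <= R - 0)
  if (d_cell / px < 4) {
    stop("pixel size too coarse: need >= 4 px per cell diameter")
  }
  if (fov < 2 * (R + Delta)) {
    stop("field of view smaller than 2*(R + Delta); enlarge fov_um")
  }
  ints <- optics$intensities %||% .default_intensities()
  noise_sd <- optics$noise_sd %||% 0.01
  n <- as.integer(round(fov / px))
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * px
  r <- sqrt(outer(xy^2, xy^2, `+`))    # distance from center in um

  with_seed(seed, {
    img <- matrix(ints$background, n, n)
    carpet <- r > R
    if (phi_S > 0) {
      p1 <- min(phi_S, 1)
      dots <- carpet & matrix(runif(n * n) < p1, n, n)
      img[dots] <- ints$speckle
      if (phi_S > 1) {
        p2 <- min(phi_S - 1, 1)
        dots2 <- dots & matrix(runif(n * n) < p2, n, n)
        img[dots2] <- ints$speckle2
      }
    }
    img[r <= R] <- ints$film
    img[r <= R0] <- ints$aggregate
    if (Delta > 0) img[r <= R & r > (R - Delta)] <- ints$aureole
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(n * n, 0, noise_sd), n, n)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(pixels = img, pixel_size_um = px,
                   truth = list(R0 = R0, R = R, Delta = Delta, phi_S = phi_S,
                                A = pi * R^2, center_px = c(ctr, ctr))),
              class = "image_frame")
  })
}

#' Render a confocal-like Z-stack of a particle-laden cell
#'
#' Voxelizes a spherical cell (volume `V_cell`), its nucleus, and `n` rigid
#' spherical beads placed uniformly at random inside the cytoplasm without
#' overlap, on a grid with the given lateral pixel size and axial step. Three
#' binary channels are produced (cell body, nucleus, beads) together with the
#' analytic ground-truth volumes.
#'
#' @param g A [cell_geometry()] (`V_cell` and `nucleus_fraction` are used).
#' @param up An [uptake_params()]; `phi_is` sets the bead volume fraction.
#' @param p A [particle_spec()]; bead diameter.
#' @param seed Integer seed for bead placement.
#' @param pixel_size_um Lateral voxel size (um), default 0.25.
#' @param z_step_um Axial slice spacing (um), default 0.25.
#' @param max_tries Rejection-sampling budget per bead.
#' @return An object of class `zstack`: list of 3D arrays `cell`, `nucleus`,
#'   `beads`, plus `pixel_size_um`, `z_step_um`, and `truth` (analytic
#'   volumes, fractions and bead count).
#' @export
render_zstack <- function(g, up, p, seed = NULL, pixel_size_um = 0.25,
                          z_step_um = 0.25, max_tries = 400) {
  stopifnot(inherits(g, "cell_geometry"), inherits(up, "uptake_params"),
            inherits(p, "particle_spec"))
  if (up$phi_is > 0.4) {
    stop("bead volume fraction > 0.4 cannot be packed without overlap")
  }
  r_cell <- (3 * g$V_cell / (4 * pi))^(1 / 3)
  r_nuc <- g$nucleus_fraction^(1 / 3) * r_cell
  r_bead <- p$diameter / 2
  n_beads <- round(up$phi_is * g$V_cell / particle_volume(p))

  centers <- with_seed(seed, {
    placed <- matrix(numeric(0), ncol = 3)
    r_max <- r_cell - r_bead
    for (b in seq_len(n_beads)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        # uniform point in the sphere of radius r_max
        u <- rnorm(3)
        pt <- u / sqrt(sum(u^2)) * r_max * runif(1)^(1 / 3)
        if (sqrt(sum(pt^2)) < r_nuc + r_bead) next   # inside nucleus
        if (nrow(placed) > 0) {
          d2 <- colSums((t(placed) - pt)^2)
          if (min(d2) < (2 * r_bead)^2) next         # overlaps a bead
        }
        placed <- rbind(placed, pt)
        ok <- TRUE
        break
      }
      if (!ok) stop("bead packing failed within the retry budget")
    }
    placed
  })

  half <- r_cell + 2 * pixel_size_um
  x <- seq(-half, half, by = pixel_size_um)
  z <- seq(-half, half, by = z_step_um)
  nx <- length(x); nz <- length(z)
  # squared distance from the origin for every voxel, built slice by slice
  rho2 <- outer(x^2, x^2, `+`)
  cell_ch <- array(0, c(nx, nx, nz))
  nuc_ch <- array(0, c(nx, nx, nz))
  bead_ch <- array(0, c(nx, nx, nz))
  for (k in seq_len(nz)) {
    d2 <- rho2 + z[k]^2
    cell_ch[, , k] <- as.numeric(d2 <= r_cell^2)
    nuc_ch[, , k] <- as.numeric(d2 <= r_nuc^2)
  }
  if (n_beads > 0) {
    for (b in seq_len(nrow(centers))) {
      cb <- centers[b, ]
      ix <- which(abs(x - cb[1]) <= r_bead + pixel_size_um)
      iy <- which(abs(x - cb[2]) <= r_bead + pixel_size_um)
      iz <- which(abs(z - cb[3]) <= r_bead + z_step_um)
      for (k in iz) {
        d2 <- outer((x[ix] - cb[1])^2, (x[iy] - cb[2])^2, `+`) + (z[k] - cb[3])^2
        sub <- bead_ch[ix, iy, k]
        sub[d2 <= r_bead^2] <- 1
        bead_ch[ix, iy, k] <- sub
      }
    }
  }
  V_nuc <- 4 / 3 * pi * r_nuc^3
  V_beads <- n_beads * particle_volume(p)
  structure(list(cell = cell_ch, nucleus = nuc_ch, beads = bead_ch,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 truth = list(V_cell = g$V_cell, V_nucleus = V_nuc,
                              V_beads = V_beads, n_beads = n_beads,
                              bead_fraction = V_beads / g$V_cell,
                              nucleus_fraction = V_nuc / g$V_cell)),
            class = "zstack")
}
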