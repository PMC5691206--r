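# Measurement operations on rendered frames and stacks.

test_that("film area of a rendered disk is recovered within 2%", {
  opt <- list(pixel_size_um = 1, fov_um = 300, noise_sd = 0.01)
  f <- render_micrograph(40, 100, 0, 0, opt, seed = 2)
  m <- measure_film_area(f)
  expect_equal(m$area_um2, pi * 100^2, tolerance = 0.02)
  expect_equal(m$radius_um, 100, tolerance = 0.01)
})

test_that("blank frames raise an empty-segmentation error", {
  blank <- structure(list(pixels = matrix(0.5, 100, 100), pixel_size_um = 1,
                          truth = NULL), class = "image_frame")
  expect_error(measure_film_area(blank), "segmentation")
  expect_error(measure_aureole_width(blank), "segmentation")
})

test_that("measured film area is invariant under image translation", {
  opt <- list(pixel_size_um = 2, fov_um = 700, noise_sd = 0)
  f <- render_micrograph(50, 120, 0, 0.2, opt, seed = 4)
  a0 <- measure_film_area(f)$area_um2
  shift <- 25
  px <- f$pixels
  shifted <- px
  shifted[(shift + 1):nrow(px), ] <- px[1:(nrow(px) - shift), ]
  shifted[1:shift, ] <- 0.55
  f2 <- f; f2$pixels <- shifted
  expect_equal(measure_film_area(f2)$area_um2, a0, tolerance = 0.01)
})

test_that("aureole width round-trips through render and measure", {
  opt <- list(pixel_size_um = 2, fov_um = 900, noise_sd = 0.01)
  f <- render_micrograph(75, 300, 50, 0.22, opt, seed = 8)
  m <- measure_aureole_width(f)
  expect_true(m$found)
  expect_equal(m$Delta_um, 50, tolerance = max(2 * 2, 0.05 * 50) / 50)
  expect_equal(m$R_um, 300, tolerance = 0.02)
  # no particles, no aureole: undetected flag
  f0 <- render_micrograph(75, 300, 0, 0, opt, seed = 8)
  m0 <- measure_aureole_width(f0)
  expect_false(m0$found)
  expect_equal(m0$Delta_um, 0)
})

test_that("a perfect annulus recovers outer minus inner radius to a pixel", {
  # noiseless scene: bright film ring, dark annulus, no speckle
  opt <- list(pixel_size_um = 1, fov_um = 500, noise_sd = 0)
  f <- render_micrograph(40, 200, 30, 0, opt, seed = 1)
  m <- measure_aureole_width(f)
  expect_equal(m$Delta_um, 30, tolerance = 1 / 30)   # +- 1 px on the width
})

test_that("surface-fraction measurement is accurate and monotone", {
  opt <- list(pixel_size_um = 2, fov_um = 800, noise_sd = 0.01)
  f <- render_micrograph(75, 200, 30, 0.22, opt, seed = 12)
  expect_equal(measure_surface_fraction(f), 0.22, tolerance = 0.03 / 0.22)
  # bare carpet measures zero
  f0 <- render_micrograph(75, 200, 0, 0, opt, seed = 12)
  expect_equal(measure_surface_fraction(f0), 0)
  # monotone on a coverage ladder
  ladder <- vapply(c(0.05, 0.2, 0.4), function(phi) {
    measure_surface_fraction(render_micrograph(75, 200, 0, phi, opt, seed = 3))
  }, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("measured Delta/R tracks the conservation model on simulator output", {
  cfg <- load_preset("SiO2Carbo1000", coating = list(phi_S = 0.22),
                     sim = list(duration_s = 288000),
                     optics = list(fov_um = 1600, pixel_size_um = 2))
  st <- simulate_front_uptake(cfg)$states
  last <- st[nrow(st), ]
  f <- render_micrograph(75, last$R, last$Delta, 0.22, cfg$optics, seed = 5)
  m <- measure_aureole_width(f)
  up <- uptake_params(0.21, phi_s = 0)
  pred <- aureole_width(last$R, 0.22, up, ref_geometry(), ref_particle()) / last$R
  expect_equal(m$Delta_um / m$R_um, pred, tolerance = 0.20)
  # the measurement itself reproduces the simulator state closely
  expect_equal(m$Delta_um, last$Delta, tolerance = 0.06)
  expect_equal(m$R_um, last$R, tolerance = 0.02)
})

test_that("z-stack volume fractions recover the ground truth within 5%", {
  g <- cell_geometry(nucleus_fraction = 0.28)
  zs <- render_zstack(g, uptake_params(0.12), ref_particle(), seed = 21)
  vf <- zstack_volume_fractions(zs)
  expect_equal(vf$bead_fraction, zs$truth$bead_fraction, tolerance = 0.05)
  expect_equal(vf$bead_fraction, 0.12, tolerance = 0.02 / 0.12)  # +-0.02
  expect_equal(vf$nucleus_fraction, 0.28, tolerance = 0.05)
  # empty bead channel measures zero
  z0 <- render_zstack(g, uptake_params(0), ref_particle(), seed = 1)
  expect_equal(zstack_volume_fractions(z0)$bead_fraction, 0)
  # missing channel is an error
  broken <- z0; broken$beads <- NULL
  expect_error(zstack_volume_fractions(broken), "missing channel")
})

test_that("radial darkness profile is flat where the scene is uniform", {
  flat <- structure(list(pixels = matrix(0.5, 200, 200), pixel_size_um = 2,
                         truth = NULL), class = "image_frame")
  pr <- radial_darkness_profile(flat)
  expect_lt(diff(range(pr$intensity)), 1e-9)
  expect_equal(nrow(pr), ceiling(200 * 2 / 2 / 22))
  # across a rendered aureole the minimum plateau is flat within 5%
  opt <- list(pixel_size_um = 2, fov_um = 900, noise_sd = 0.01)
  f <- render_micrograph(75, 300, 60, 0.22, opt, seed = 2)
  pr2 <- radial_darkness_profile(f)
  annulus <- pr2$intensity[pr2$r_mid_um > 245 & pr2$r_mid_um < 295]
  expect_gt(length(annulus), 1)
  expect_lt(diff(range(annulus)) / mean(annulus), 0.05)
})

test_that("frames and z-stacks survive a TIFF round-trip", {
  dir <- withr::local_tempdir()
  opt <- list(pixel_size_um = 2, fov_um = 500, noise_sd = 0.01)
  f <- render_micrograph(50, 150, 20, 0.3, opt, seed = 6)
  path <- file.path(dir, "frame.tif")
  write_frame_tiff(f, path)
  f2 <- read_frame_tiff(path)
  expect_equal(f2$pixel_size_um, 2)
  expect_equal(f2$truth$R, 150)
  expect_equal(f2$pixels, f$pixels, tolerance = 1 / 65535)  # 16-bit quantization
  expect_equal(measure_aureole_width(f2)$Delta_um,
               measure_aureole_width(f)$Delta_um, tolerance = 0.02)
  zs <- render_zstack(ref_geometry(), uptake_params(0.03), ref_particle(),
                      seed = 2, pixel_size_um = 0.5, z_step_um = 0.5)
  write_zstack_tiff(zs, file.path(dir, "stack"))
  zs2 <- read_zstack_tiff(file.path(dir, "stack"))
  expect_equal(zs2$z_step_um, 0.5)
  expect_equal(zstack_volume_fractions(zs2)$bead_fraction,
               zstack_volume_fractions(zs)$bead_fraction, tolerance = 1e-6)
})
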