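# Generators: trajectories, discrete front-uptake simulator, renderers.

test_that("noiseless trajectory is exactly linear and fit recovers V*", {
  cfg <- load_preset("bare", sim = list(area_noise = 0),
                     velocity_sd_um_s = 0)
  tr <- make_trajectory(cfg, seed = 1)
  fit <- fit_velocity(tr)
  expect_equal(fit$estimates[["V_star"]], 4.9e-2, tolerance = 1e-12)
  expect_equal(tr$A, tr$A0 + tr$R0 * 4.9e-2 * tr$t, tolerance = 1e-12)
  expect_equal(length(tr$t), 54000 / 600 + 1)   # 10-min sampling over 15 h
})

test_that("trajectory generation is deterministic under a fixed seed", {
  cfg <- load_preset("bare")
  expect_identical(make_trajectory(cfg, seed = 42), make_trajectory(cfg, seed = 42))
  t1 <- make_trajectories(cfg, n = 3, seed = 9)
  t2 <- make_trajectories(cfg, n = 3, seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1[[1]]$A, t1[[2]]$A))
})

test_that("negative noise is rejected as a config error", {
  expect_error(load_preset("bare", sim = list(area_noise = -0.1)),
               "area_noise")
})

test_that("front-uptake simulator conserves particles exactly at every step", {
  for (phi in c(0.22, 1.2)) {
    cfg <- quick_cfg("PsCarbo1000", phi_S = phi)
    fs <- simulate_front_uptake(cfg)
    st <- fs$states
    expect_true(all(st$ingested + st$adsorbed + st$substrate_remaining ==
                      fs$initial_total))
    expect_true(all(st$ingested == floor(st$ingested)))  # integer ledger
    expect_true(all(diff(st$Delta) >= 0))                # aureole only grows
  }
})

test_that("no adsorption below the threshold; aureole absent on bare substrate", {
  cfg <- quick_cfg("PsCarbo1000", phi_S = 0.15)   # below phi_S0 = 0.2
  fs <- simulate_front_uptake(cfg)
  expect_true(all(fs$states$adsorbed == 0))
  cfg0 <- quick_cfg("PsCarbo1000", phi_S = 0)
  fs0 <- simulate_front_uptake(cfg0)
  expect_true(all(fs0$states$Delta == 0))
  expect_true(all(fs0$states$swept == 0))
})

test_that("emergent Delta(R) slope agrees with the conservation model", {
  cfg <- load_preset("SiO2Carbo1000", coating = list(phi_S = 0.22),
                     sim = list(duration_s = 288000))
  fs <- simulate_front_uptake(cfg)
  st <- fs$states
  Rc <- critical_radius(0.22, uptake_params(0.21), ref_geometry(),
                        ref_particle())
  sel <- st$R > 2 * Rc
  slope <- coef(lm(Delta ~ R, data = st[sel, ]))[[2]]
  expect_equal(slope, theory_slope(0.22, 0.21), tolerance = 0.1)
})

test_that("the emergent aureole grows linearly with the film radius", {
  # high coverage and a long run so the 22-um row quantization is small
  # relative to the aureole range
  cfg <- load_preset("SiO2Carbo1000", coating = list(phi_S = 1.42),
                     sim = list(duration_s = 600000))
  st <- simulate_front_uptake(cfg)$states
  expect_gt(summary(lm(Delta ~ R, data = st[st$Delta > 0, ]))$r.squared, 0.99)
})

test_that("micrograph rendering is deterministic and honors its contracts", {
  opt <- list(pixel_size_um = 2, fov_um = 800, noise_sd = 0.01)
  f1 <- render_micrograph(75, 250, 40, 0.22, opt, seed = 5)
  f2 <- render_micrograph(75, 250, 40, 0.22, opt, seed = 5)
  expect_identical(f1$pixels, f2$pixels)
  # aureole annulus is darker than the film interior
  n <- nrow(f1$pixels); ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * 2
  r <- sqrt(outer(xy^2, xy^2, `+`))
  aureole_px <- f1$pixels[r <= 250 & r > 210]
  film_px <- f1$pixels[r <= 210 & r > 75]
  expect_lt(mean(aureole_px), mean(film_px))
  # phi_S = 0 leaves a uniform background outside the film
  f0 <- render_micrograph(75, 250, 0, 0, opt, seed = 5)
  expect_lt(sd(f0$pixels[r > 255]), 0.02)
  # contract errors
  expect_error(render_micrograph(75, 350, 80, 0.2, opt), "field of view")
  expect_error(render_micrograph(75, 100, 0, 0.2,
                                 list(pixel_size_um = 10, fov_um = 800)),
               "pixel size")
})

test_that("speckle carpet reproduces the configured coverage", {
  opt <- list(pixel_size_um = 2, fov_um = 800, noise_sd = 0.01)
  for (phi in c(0.1, 0.35, 0.5)) {
    f <- render_micrograph(75, 150, 0, phi, opt, seed = 17)
    n <- nrow(f$pixels); ctr <- (n + 1) / 2
    xy <- (seq_len(n) - ctr) * 2
    r <- sqrt(outer(xy^2, xy^2, `+`))
    carpet <- f$pixels[r > 160]
    frac <- mean(carpet < 0.45)
    expect_equal(frac, phi, tolerance = 0.03 / phi)  # 3% absolute
  }
})

test_that("z-stack renderer embeds ground truth and rejects impossible packings", {
  g <- ref_geometry()
  zs <- render_zstack(g, uptake_params(0.05), ref_particle(), seed = 3)
  expect_equal(zs$truth$n_beads, round(0.05 * 1600 / (pi / 6)))
  expect_identical(render_zstack(g, uptake_params(0.05), ref_particle(), seed = 3)$beads,
                   zs$beads)
  z0 <- render_zstack(g, uptake_params(0), ref_particle(), seed = 1)
  expect_equal(sum(z0$beads), 0)
  expect_error(render_zstack(g, uptake_params(0.45), ref_particle()),
               "0.4")
})
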