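# Closed-form physics: sedimentation, coating, spreading law, dissipation
# balance, velocity enhancement, conservation model, counts, clearing times.

test_that("sedimentation length matches direct SI evaluation and flags buoyancy", {
  const <- physical_constants(thermal_energy = 4.11e-21)
  # independent evaluation in SI units
  oracle <- function(d_um, drho) {
    4.11e-21 / ((pi / 6 * d_um^3 * 1e-18) * drho * 9.81) * 1e6
  }
  heavy <- sedimentation_length(particle_spec(1, 2000), const)
  expect_equal(heavy$length_um, oracle(1, 1000), tolerance = 1e-12)
  expect_equal(heavy$length_um, 0.80, tolerance = 0.01)
  expect_true(heavy$sediments_fully)   # l_S < d: all particles fall

  ps <- sedimentation_length(particle_spec(1, 1050), const)
  expect_equal(ps$length_um, oracle(1, 50), tolerance = 1e-12)
  expect_equal(ps$length_um, 16, tolerance = 0.01)
  expect_false(ps$sediments_fully)     # l_S > d: partial sedimentation

  neutral <- sedimentation_length(particle_spec(1, 1000), const)
  expect_identical(neutral$length_um, Inf)
  expect_false(neutral$sinks)
})

test_that("sedimentation length scales as d^-3 at fixed density contrast", {
  l1 <- sedimentation_length(particle_spec(1, 2000))$length_um
  l2 <- sedimentation_length(particle_spec(2, 2000))$length_um
  expect_equal(l2 / l1, 1 / 8, tolerance = 1e-12)
})

test_that("coating from suspension implements nu = C*H and phi_S = nu*pi*d^2/4", {
  p <- particle_spec(1, 2000)
  expect_equal(coating_from_suspension(0, 4000, p)$surface_fraction, 0)
  co <- coating_from_suspension(1.25e-4, 4000, p)
  expect_equal(co$areal_density, 0.5, tolerance = 1e-12)
  expect_equal(co$surface_fraction, 0.5 * pi / 4, tolerance = 1e-12)
  # sub-um particle at measured areal density
  co8 <- coating_spec(1.0, particle_spec(0.8, 1050))
  expect_equal(co8$surface_fraction, pi * 0.64 / 4, tolerance = 1e-12)
  # partial sedimentation refuses to predict and demands a measurement
  expect_error(coating_from_suspension(1e-4, 4000, p, fully_sedimented = FALSE),
               "measured optically")
  co_m <- coating_from_suspension(1e-4, 4000, p, fully_sedimented = FALSE,
                                  nu_measured = 0.2)
  expect_equal(co_m$areal_density, 0.2)
})

test_that("spread area is linear in time with slope R0*V*", {
  sp <- spreading_params(6.2e-2, 75)
  expect_equal(spread_area(0, sp), sp$A0)
  expect_equal(spread_area(54000, sp) - sp$A0, 75 * 6.2e-2 * 54000)
  expect_equal(spread_area(54000, sp) - sp$A0, 251100)
  expect_equal(spread_radius(0, sp), 75)
  # doubling R0 doubles the area growth rate
  sp2 <- spreading_params(6.2e-2, 150)
  expect_equal((spread_area(1000, sp2) - sp2$A0) /
                 (spread_area(1000, sp) - sp$A0), 2)
  expect_equal(sp$D, 6.2e-2 * 75)
})

test_that("dissipation terms reproduce the permeation/slippage balance", {
  fp <- friction_params(1, 1, contact_radius = 1)
  d <- dissipation_terms(2, 1, fp)
  expect_equal(d[["permeation"]], 4 * pi, tolerance = 1e-12)
  expect_equal(d[["slippage"]], 8 * pi * log(2), tolerance = 1e-12)
  # at the contact line the slippage integral vanishes
  expect_equal(dissipation_terms(1, 1, fp)[["slippage"]], 0)
  # frictionless substrate
  fp0 <- friction_params(2, 0, contact_radius = 1)
  d0 <- dissipation_terms(3, 0.5, fp0)
  expect_equal(d0[["slippage"]], 0)
  expect_equal(d0[["permeation"]], 2 * pi * 2 * 3 * 0.25)
  expect_error(dissipation_terms(0.5, 1, fp), "R_L")
})

test_that("permeation dominance criterion eta/R_L > k ln(R/R_L)", {
  expect_true(permeation_dominant(friction_params(1, 5, contact_radius = 1), 1))
  expect_true(permeation_dominant(friction_params(1, 0, contact_radius = 1), 100))
  expect_false(permeation_dominant(friction_params(1, 10, contact_radius = 1),
                                   exp(1)))
})

test_that("enhanced velocity is linear below the plateau and clamped above", {
  ep <- enhancement_params(4.9e-2, 1.3, 0.6)
  expect_equal(enhanced_velocity(0, ep), 4.9e-2)
  expect_equal(enhanced_velocity(0.6, ep), 4.9e-2 * (1 + 1.3 * 0.6))
  expect_equal(enhanced_velocity(0.6, ep), 8.722e-2, tolerance = 1e-6)
  expect_equal(enhanced_velocity(1.2, ep), enhanced_velocity(0.6, ep))
  # non-decreasing in coverage for a positive slope
  phis <- seq(0, 1.5, by = 0.05)
  expect_true(all(diff(enhanced_velocity(phis, ep)) >= 0))
})

test_that("critical radius carries the 137-um coefficient and hyperbolic phi_S dependence", {
  g <- ref_geometry()
  p <- ref_particle()
  up <- uptake_params(0.17)
  for (phi in c(0.1, 0.22, 0.5, 1.2)) {
    Rc <- critical_radius(phi, up, g, p)
    expect_equal(Rc * phi / up$phi_is, 3 * 22 * 1600 / 770, tolerance = 1e-12)
  }
  expect_equal(critical_radius(0.22, up, g, p), 106, tolerance = 0.01)
  # proportional to phi_is
  expect_equal(critical_radius(0.3, uptake_params(0.34), g, p) /
                 critical_radius(0.3, uptake_params(0.17), g, p), 2,
               tolerance = 1e-12)
  expect_identical(critical_radius(0, up, g, p), Inf)
})

test_that("aureole width equals d_cell at the critical radius (branch continuity)", {
  g <- ref_geometry()
  set.seed(11)
  for (i in 1:25) {
    p <- particle_spec(runif(1, 0.2, 5))
    up <- uptake_params(runif(1, 0.02, 0.6))
    phi <- runif(1, 0.01, 1.5)
    Rc <- critical_radius(phi, up, g, p)
    expect_equal(aureole_width(Rc, phi, up, g, p), g$d_cell, tolerance = 1e-9)
    expect_equal(aureole_width(Rc * (1 + 1e-9), phi, up, g, p), g$d_cell,
                 tolerance = 1e-6)
  }
})

test_that("aureole width reproduces the printed plateau ratio and edge cases", {
  g <- ref_geometry()
  p <- ref_particle()
  up <- uptake_params(0.21, phi_s = 0.87)
  R <- 400
  expect_equal(aureole_width(R, 1.42, up, g, p) / R, 0.30,
               tolerance = 0.02 / 0.30)
  expect_equal(aureole_width(R, 0, up, g, p), 0)
  expect_error(aureole_width(R, 0.5, uptake_params(0), g, p), "nowhere to go")
})

test_that("membrane fraction is a thresholded linear law", {
  up <- uptake_params(0.2, a = 0.9, phi_S0 = 0.5)
  expect_equal(membrane_fraction(c(0, 0.3, 0.5), up), c(0, 0, 0))
  expect_equal(membrane_fraction(1.2, up), 0.9 * 0.7)
  expect_equal(membrane_fraction(1.2, up), 0.63, tolerance = 1e-12)
  up0 <- uptake_params(0.2, a = 0, phi_S0 = 0.5)
  expect_equal(membrane_fraction(c(0.6, 1, 2), up0), c(0, 0, 0))
})

test_that("conservation residual vanishes for model-consistent states", {
  g <- ref_geometry()
  set.seed(23)
  for (i in 1:25) {
    p <- particle_spec(runif(1, 0.3, 3))
    phi <- runif(1, 0.05, 1.4)
    up <- uptake_params(runif(1, 0.05, 0.4), phi_s = runif(1, 0, 0.9))
    R <- runif(1, 150, 800)
    Rc <- critical_radius(phi, up, g, p)
    if (R <= Rc) next
    Delta <- aureole_width(R, phi, up, g, p)
    C_i <- 6 * up$phi_is / (pi * p$diameter^3)       # saturation concentration
    C_S <- 4 * up$phi_s / (pi * p$diameter^2)        # membrane concentration
    nu <- phi / (pi * p$diameter^2 / 4)
    expect_lt(abs(conservation_residual(R, Delta, C_i, C_S, g, nu)), 1e-9)
    # halving Delta halves the stored side: normalized residual -0.5
    expect_equal(conservation_residual(R, Delta / 2, C_i, C_S, g, nu), -0.5,
                 tolerance = 1e-9)
  }
  expect_equal(conservation_residual(100, 0, 1, 1, g, 0), 0)
})

test_that("per-cell counts match the published table within 5%", {
  g <- ref_geometry()
  p <- ref_particle()
  ps_carbo <- particle_counts(uptake_params(0.11, phi_s = 0.80), g, p)
  expect_equal(ps_carbo$n_i, 330, tolerance = 0.05)
  expect_equal(ps_carbo$n_s, 1550, tolerance = 0.05)
  sio2 <- particle_counts(uptake_params(0.21, phi_s = 0.87), g, p)
  expect_equal(sio2$n_tot, 2330, tolerance = 0.05)
  zero <- particle_counts(uptake_params(0), g, p)
  expect_identical(unlist(zero), c(n_i = 0, n_s = 0, n_tot = 0))
  # counts divide by the cluster factor for flocculating particles
  halved <- particle_counts(uptake_params(0.11, phi_s = 0.80), g,
                            particle_spec(1, cluster_factor = 2))
  expect_equal(halved$n_i, round(ps_carbo$n_i / 2), tolerance = 0.01)
})

test_that("phi_is round-trips through the internalized count", {
  g <- ref_geometry()
  set.seed(7)
  for (phi_is in runif(5, 0.05, 0.35)) {
    p <- ref_particle()
    n_i <- particle_counts(uptake_params(phi_is), g, p)$n_i
    back <- n_i * particle_volume(p) / g$V_cell
    expect_equal(back, phi_is, tolerance = 1 / n_i)  # rounding error only
  }
})

test_that("passage time and clearing feasibility follow V* tau_p = d_cell", {
  g <- ref_geometry()
  tp <- passage_time(g, 6.2e-2)
  expect_equal(tp, 22 / 6.2e-2)
  expect_equal(round(tp / 60), 6)   # about six minutes
  expect_identical(passage_time(g, 0), Inf)
  expect_equal(passage_time(cell_geometry(d_cell = 1e-9), 1), 1e-9)
  expect_lt(passage_time(g, 10), 3)

  expect_true(clearing_feasible(clearing_times(120, tp)))
  expect_false(clearing_feasible(clearing_times(tp, tp)))   # strict inequality
  expect_false(clearing_feasible(clearing_times(900, tp)))  # large beads
})
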