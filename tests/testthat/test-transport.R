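test_that("particle Reynolds number matches direct evaluation and scales linearly", {
  expect_equal(particle_reynolds(0, 5e-6, 1.2, 1.81e-5), 0)
  expect_equal(particle_reynolds(100, 5e-6, 1.2, 1.81e-5), 33.149, tolerance = 1e-4)
  expect_equal(particle_reynolds(100, 1e-5, 1.2, 1.81e-5),
               2 * particle_reynolds(100, 5e-6, 1.2, 1.81e-5))
  expect_error(particle_reynolds(10, 0, 1.2, 1.81e-5))
})

test_that("Schiller-Naumann drag coefficient has the right branches and Stokes limit", {
  expect_equal(drag_coefficient(0.1), 247.40, tolerance = 1e-4)
  expect_equal(drag_coefficient(2000), 0.44)
  expect_equal(drag_coefficient(1e4), 0.44)
  # CD * Re -> 24 as Re -> 0
  Re <- 10^seq(-6, -3)
  expect_equal(drag_coefficient(Re) * Re, rep(24, length(Re)), tolerance = 1e-2)
  expect_error(drag_coefficient(-1))
})

test_that("drag force is zero at rest, quadratic in speed, and Stokes at small Re", {
  expect_equal(drag_force(c(0, 0, 0), 5e-6, 1.204, 1.81e-5), c(0, 0, 0))
  # quadratic dependence with CD held fixed: compare in the plateau regime
  f1 <- drag_force(c(400, 0, 0), 1e-4, 1.204, 1.81e-5)
  f2 <- drag_force(c(800, 0, 0), 1e-4, 1.204, 1.81e-5)
  expect_equal(f2[1] / f1[1], 4, tolerance = 1e-6)
  # Stokes-law oracle at small relative speed
  D <- 5e-6; v <- 0.05; mu <- 1.81e-5
  expect_equal(drag_force(c(v, 0, 0), D, 1.204, mu)[1],
               3 * pi * mu * D * v, tolerance = 1e-2)
})

test_that("sampled eddy fluctuations have variance 2k/3 per component", {
  set.seed(101)
  e <- sample_eddy(1e5, k = 3, l_eps = 7e-6)
  v <- apply(e$fluctuation, 2, var)
  expect_equal(unname(v), rep(2, 3), tolerance = 0.025)
  expect_true(all(e$interaction_time >= 0))
  # laminar limit: zero fluctuation, infinite (never-expiring) eddies
  e0 <- sample_eddy(10, k = 0, l_eps = 7e-6)
  expect_equal(max(abs(e0$fluctuation)), 0)
  set.seed(5); a <- sample_eddy(100, 1, 7e-6)
  set.seed(5); b <- sample_eddy(100, 1, 7e-6)
  expect_identical(a, b)
})

test_that("a force-free parcel moves in a straight line at constant velocity", {
  # gas moving with the parcel, no turbulence: zero relative velocity
  fl <- uniform_flow(velocity = c(2, 1, -1), k = 0)
  p <- parcels(x = 0, y = 0, z = 0, vx = 2, vy = 1, vz = -1, diameter = 5e-6)
  props <- compound_properties("PFD")
  q <- advance_parcels(p, fl, props, dt = 1e-3, nsub = 10, turbulence = FALSE)
  expect_equal(c(q$x, q$y, q$z), c(2e-3, 1e-3, -1e-3), tolerance = 1e-12)
  expect_equal(c(q$vx, q$vy, q$vz), c(2, 1, -1), tolerance = 1e-12)
})

test_that("Stokes-regime relaxation matches the analytic exponential solution to 1%", {
  props <- compound_properties("PFD")
  D <- 1e-5; u <- 0.1                       # Re_p ~ 7e-4: deep Stokes regime
  tau <- particle_relaxation_time(D, props$liquid_density, 1.81e-5)
  fl <- uniform_flow(velocity = c(u, 0, 0), k = 0)
  p <- parcels(x = 0, diameter = D, vx = 0)
  t_end <- 3 * tau
  nstep <- 30
  for (i in seq_len(nstep))
    p <- advance_parcels(p, fl, props, dt = t_end / nstep, turbulence = FALSE)
  expect_equal(p$vx, u * (1 - exp(-t_end / tau)), tolerance = 0.01)
  expect_equal(p$x, u * (t_end - tau * (1 - exp(-t_end / tau))),
               tolerance = 0.01)
  # advection changes neither diameter nor droplet count
  expect_equal(p$diameter, D)
  expect_equal(p$count, 1)
})

test_that("transport is deterministic under a fixed seed and seed-sensitive otherwise", {
  tb <- load_injection_table("PFD", 4)
  fl <- jet_flow_config(4, domain_length = 0.02)
  a <- simulate_spray(tb, fl, duration = 2e-3, parcels_per_step = 50, seed = 3)
  b <- simulate_spray(tb, fl, duration = 2e-3, parcels_per_step = 50, seed = 3)
  d <- simulate_spray(tb, fl, duration = 2e-3, parcels_per_step = 50, seed = 4)
  expect_identical(a$outlet, b$outlet)
  expect_identical(a$step_log, b$step_log)
  expect_false(identical(a$outlet, d$outlet))
  # with turbulence disabled any two seeds coincide
  a0 <- simulate_spray(tb, fl, duration = 2e-3, parcels_per_step = 50, seed = 3,
                       turbulence_enabled = FALSE)
  b0 <- simulate_spray(tb, fl, duration = 2e-3, parcels_per_step = 50, seed = 99,
                       turbulence_enabled = FALSE)
  expect_identical(a0$outlet, b0$outlet)
})

test_that("ensemble-mean axial penetration is seed-independent under turbulence", {
  props <- compound_properties("PFD")
  fl <- uniform_flow(velocity = c(10, 0, 0), k = 1.5, l_eps = 7e-6)
  mean_x <- vapply(1:20, function(s) {
    set.seed(s)
    p <- parcels(x = numeric(200), diameter = 5e-6, vx = 0)
    for (i in 1:10) p <- advance_parcels(p, fl, props, dt = 1e-4, nsub = 4)
    mean(p$x)
  }, numeric(1))
  # seed-to-seed scatter of the 200-parcel ensemble mean stays within a
  # tight confidence band around the grand mean
  expect_lt(sd(mean_x) / mean(mean_x), 0.01)
  expect_lt(max(abs(mean_x - mean(mean_x))) / mean(mean_x), 0.03)
})

test_that("zero injections give zero outlet flux and invalid steps are rejected", {
  tb0 <- injection_table("PFD", 4, Dg_um = c(1, 2), mass_flow = c(0, 0))
  fl <- jet_flow_config(4, domain_length = 0.02)
  s0 <- simulate_spray(tb0, fl, duration = 1e-3, parcels_per_step = 10, seed = 1)
  expect_equal(nrow(s0$outlet), 0)
  expect_equal(sum(s0$step_log$outlet_mass_kg), 0)
  expect_error(simulate_spray(tb0, fl, duration = -1))
  expect_error(simulate_spray(tb0, fl, duration = 1e-3, dt = 0))
  p <- parcels(x = 0, diameter = 1e-6)
  expect_error(advance_parcels(p, uniform_flow(), compound_properties("PFD"), dt = 0))
})
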