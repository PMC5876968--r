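props_pfd <- compound_properties("PFD")

test_that("Weber number matches direct evaluation and is linear in diameter", {
  expect_equal(weber_number(1.2, 0, 5e-6, 0.019), 0)
  expect_equal(weber_number(1.2, 50, 5e-6, 0.019), 0.78947, tolerance = 1e-4)
  expect_equal(weber_number(1.2, 50, 1e-5, 0.019),
               2 * weber_number(1.2, 50, 5e-6, 0.019))
  expect_error(weber_number(1.2, 50, 5e-6, 0))
  expect_error(weber_number(1.2, 50, -5e-6, 0.019))
})

test_that("the unforced oscillator stays at equilibrium", {
  st <- tab_advance_distortion(0, 0, 20e-6, rel_speed = 0, gas_density = 1.2,
                               props = props_pfd, dt = 1e-4)
  expect_equal(st$y, 0)
  expect_equal(st$ydot, 0)
  expect_false(st$breakup)
})

test_that("an inviscid droplet oscillates at its natural frequency with conserved amplitude", {
  props0 <- compound_properties("PFD", liquid_viscosity = 1e-12)
  consts <- tab_constants()
  D <- 20e-6; r <- D / 2
  omega0 <- sqrt(consts$C_k * props0$surface_tension /
                   (props0$liquid_density * r^3))
  period <- 2 * pi / omega0
  y <- 0.1; ydot <- 0
  # 100 periods, 16 analytic sub-updates per period
  for (i in seq_len(1600)) {
    st <- tab_advance_distortion(y, ydot, D, 0, 1.2, props0,
                                 consts, dt = period / 16)
    y <- st$y; ydot <- st$ydot
  }
  amp <- sqrt(y^2 + (ydot / omega0)^2)
  expect_equal(amp, 0.1, tolerance = 1e-6)
  expect_equal(y, 0.1, tolerance = 1e-6)   # whole number of periods
})

test_that("sub-critical constant forcing converges to a steady distortion below 1", {
  consts <- tab_constants()
  D <- 10e-6; r <- D / 2; u <- 20; rho_g <- 1.204
  y_eq <- consts$C_F * rho_g * u^2 * r /
    (consts$C_b * consts$C_k * props_pfd$surface_tension)
  expect_lt(y_eq, 1)
  y <- 0; ydot <- 0
  for (i in seq_len(4000)) {
    st <- tab_advance_distortion(y, ydot, D, u, rho_g, props_pfd,
                                 consts, dt = 1e-6)
    y <- st$y; ydot <- st$ydot
    expect_false(st$breakup)
  }
  expect_equal(y, y_eq, tolerance = 1e-3)
})

test_that("the distortion update is stable for extremely stiff (overdamped) droplets", {
  # sub-micron droplet with a viscous liquid: damping rate ~1e8 1/s
  st <- tab_advance_distortion(0.5, 1e3, 4e-7, 30, 1.204, props_pfd,
                               dt = 1e-4)
  expect_true(is.finite(st$y) && is.finite(st$ydot))
})

test_that("breakup conserves mass exactly and only shrinks droplets", {
  set.seed(11)
  for (i in 1:50) {
    D <- runif(1, 5e-6, 3e-5)
    m <- runif(1, 1e-12, 1e-9)
    ch <- tab_breakup(D, m, ydot = runif(1, 0, 1e4), props = props_pfd)
    expect_equal(sum(ch$mass), m, tolerance = 1e-15)
    expect_equal(sum(ch$count * props_pfd$liquid_density * pi / 6 * ch$diameter^3),
                 m, tolerance = 1e-12)
    expect_true(all(ch$diameter < D))
    expect_true(all(ch$count > 0))
  }
})

test_that("child sizes follow the truncated Rosin-Rammler law (KS check)", {
  set.seed(202)
  consts <- tab_constants()
  D <- 20e-6
  d_all <- replicate(1e3, tab_breakup(D, 1e-10, 0, props_pfd, consts)$diameter)
  d_all <- as.numeric(d_all)
  # analytic truncated CDF with the scale implied by the energy balance
  r32 <- (D / 2) / (1 + 8 * consts$K_energy / 20)
  scl <- 2 * r32 * gamma(1 - 1 / consts$child_spread_q)
  Fmax <- 1 - exp(-(0.999 * D / scl)^consts$child_spread_q)
  cdf <- function(x) (1 - exp(-(x / scl)^consts$child_spread_q)) / Fmax
  ks <- max(abs(stats::ecdf(d_all)(sort(d_all)) - cdf(sort(d_all))))
  expect_lt(ks, 0.02)
})

test_that("disabling breakup preserves the injected size spectrum through transport", {
  tb <- load_injection_table("PFD", 4)
  fl <- jet_flow_config(4, domain_length = 0.02)
  s <- simulate_spray(tb, fl, duration = 3e-3, parcels_per_step = 100, seed = 8,
                      breakup_enabled = FALSE)
  expect_true(all(sort(unique(round(s$outlet$diameter_um, 6))) %in%
                    round(tb$Dg_um, 6)))
})
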