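test_that("aerodynamic/geometric conversion matches the density scaling and round-trips", {
  expect_equal(aerodynamic_to_geometric(4.33, 1), 4.33)
  expect_equal(aerodynamic_to_geometric(4.33, 1.95), 3.101, tolerance = 1e-3)
  d <- runif(20, 0.5, 20)
  expect_equal(aerodynamic_to_geometric(geometric_to_aerodynamic(d, 1.78), 1.78),
               d, tolerance = 1e-12)
  # strictly decreasing in density at fixed Da
  rho <- seq(1, 2.5, by = 0.1)
  expect_true(all(diff(aerodynamic_to_geometric(5, rho)) < 0))
  expect_error(aerodynamic_to_geometric(5, 0))
  expect_error(geometric_to_aerodynamic(5, -1))
})

test_that("cumulative mass distribution is a normalized non-decreasing curve", {
  # two equal-mass sizes at 2 and 8 um
  cv <- cumulative_mass_distribution(c(2, 8), mass = c(1, 1))
  f <- approxfun(cv$diameter_um, cv$cum_fraction, method = "constant",
                 yleft = 0, yright = 1)
  expect_equal(f(5), 0.5)
  expect_equal(cv$cum_fraction[nrow(cv)], 1)
  expect_true(all(diff(cv$cum_fraction) >= 0))
  expect_error(cumulative_mass_distribution(c(2, 8), mass = c(0, 0)))
})

test_that("the empirical mass CDF matches the analytic lognormal CDF", {
  set.seed(77)
  n <- 1e5
  d <- exp(rnorm(n, log(6), log(1.8)))         # equal-mass draws
  cv <- cumulative_mass_distribution(d, mass = rep(1, n))
  truth <- pnorm(log(cv$diameter_um / 6) / log(1.8))
  expect_lt(max(abs(cv$cum_fraction - truth)), 0.01)
})

test_that("MMAD handles degenerate, edge-split, and lognormal inputs", {
  expect_equal(mmad(rep(5, 10)), 5)                         # monodisperse
  expect_equal(mmad(size_distribution(c(1, 2, 4), c(1, 1))), 2)  # shared-edge split
  set.seed(42)
  d <- exp(rnorm(1e5, log(7.2), log(1.9)))
  expect_equal(mmad(d, mass = rep(1, 1e5)), 7.2, tolerance = 0.1 / 7.2)
  expect_error(mmad(size_distribution(c(1, 2), 0)))
})

test_that("GSD recovers the lognormal spread and flags heterodispersity above 1.25", {
  expect_equal(gsd(rep(5, 10)), 1)
  set.seed(43)
  d <- exp(rnorm(1e5, log(7.2), log(1.8)))
  expect_equal(gsd(d, mass = rep(1, 1e5)), 1.8, tolerance = 0.03 / 1.8)
  # quantile-ratio and moment definitions agree for lognormal input
  expect_equal(gsd(d, mass = rep(1, 1e5)), exp(sd(log(d))), tolerance = 0.02)
  edges <- exp(seq(log(0.5), log(20), length.out = 53))
  mid <- sqrt(edges[-1] * edges[-53])
  m13 <- dnorm(log(mid), log(5), log(1.3))
  s <- aerosol_summary(size_distribution(edges, m13))
  expect_true(s$heterodisperse)       # GSD 1.3 aerosol
  m11 <- dnorm(log(mid), log(5), log(1.1))
  expect_false(aerosol_summary(size_distribution(edges, m11))$heterodisperse)
})

test_that("the cumulative curve of a pooled sample is the mass-weighted mixture", {
  set.seed(9)
  d1 <- exp(rnorm(2e4, log(3), log(1.5))); m1 <- rep(2, 2e4)
  d2 <- exp(rnorm(2e4, log(9), log(1.4))); m2 <- rep(1, 2e4)
  pool <- cumulative_mass_distribution(c(d1, d2), c(m1, m2))
  f1 <- approxfun(cumulative_mass_distribution(d1, m1)$diameter_um,
                  cumulative_mass_distribution(d1, m1)$cum_fraction,
                  yleft = 0, yright = 1)
  f2 <- approxfun(cumulative_mass_distribution(d2, m2)$diameter_um,
                  cumulative_mass_distribution(d2, m2)$cum_fraction,
                  yleft = 0, yright = 1)
  w1 <- sum(m1) / (sum(m1) + sum(m2))
  grid <- seq(1, 15, by = 0.5)
  fp <- approxfun(pool$diameter_um, pool$cum_fraction, yleft = 0, yright = 1)
  expect_equal(fp(grid), w1 * f1(grid) + (1 - w1) * f2(grid), tolerance = 5e-3)
})

test_that("aerosolization rate follows the chamber mass loss", {
  expect_equal(aerosolization_rate(10, 10, 1, 1.95), 0)
  expect_equal(aerosolization_rate(10.1, 10.0, 1, 1.95), 0.05128, tolerance = 1e-4)
  expect_equal(aerosolization_rate(10.1, 10.0, 0.5, 1.95),
               2 * aerosolization_rate(10.1, 10.0, 1, 1.95))
  expect_error(aerosolization_rate(10.0, 10.1, 1, 1.95))
  expect_error(aerosolization_rate(10.1, 10.0, 0, 1.95))
})

test_that("four-event classification partitions every particle exactly once", {
  ev <- classify_aps_events(c(0.3, 10, 25))
  expect_equal(unname(ev), c(1, 1, 0, 1))
  d <- c(0.1, 0.5, 5, 20, 30)
  ev <- classify_aps_events(d, coincidence = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(sum(ev), length(d))
  expect_equal(unname(ev["event3"]), 1)
  # boundary diameters belong to the in-range event
  expect_equal(unname(classify_aps_events(c(0.5, 20))["event2"]), 2)
  expect_equal(sum(classify_aps_events(numeric(0))), 0)
  expect_error(classify_aps_events(-1))
})

test_that("APS samples round-trip through the CSV dialect", {
  s <- generate_aps_sample(synthetic_aerosol_spec(6, 1.7, 1e4, seed = 12,
                                                  coincidence_fraction = 0.02))
  path <- tempfile(fileext = ".csv")
  write_aps_sample(s, path)
  s2 <- read_aps_sample(path)
  expect_equal(s2$bin_edges_um, s$bin_edges_um, tolerance = 1e-12)
  expect_equal(s2$counts, s$counts, tolerance = 1e-10)
  expect_equal(s2$events, s$events)
  expect_equal(mmad(as_size_distribution(s2)), mmad(as_size_distribution(s)),
               tolerance = 1e-6)
  unlink(path)
})
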