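test_that("observed order matches hand evaluation on the mesh-study velocities", {
  expect_equal(observed_order(9.58, 9.41, 8.92, r = 2), 1.5273, tolerance = 1e-4)
  expect_error(observed_order(9.5, 9.5, 9.0), "converged")
  expect_error(observed_order(9.5, 9.4, 9.45), "oscillatory")
  expect_error(observed_order(9.58, 9.41, 8.92, r = 1))
})

test_that("Richardson extrapolation recovers constructed p-th order data exactly", {
  # v(h) = v0 + C h^p on geometric meshes
  for (p_true in c(0.5, 1, 2, 4)) for (r in c(1.5, 2, 3)) {
    ms <- generate_mesh_series(v0 = 9.67, C = 0.8, p = p_true, r = r)
    p_hat <- observed_order(ms$value[1], ms$value[2], ms$value[3], r)
    expect_equal(p_hat, p_true, tolerance = 1e-10)
    expect_equal(richardson_extrapolate(ms$value[1], ms$value[2], r, p_hat),
                 9.67, tolerance = 1e-10)
    rep <- gci_report(ms$value, r = r)
    # with per-pair coarse normalization the exact-data asymptotic ratio is
    # v2/v3, which tends to 1 as the discretization errors become small
    expect_equal(rep$asymptotic_ratio, ms$value[2] / ms$value[3],
                 tolerance = 1e-10)
    ms_small <- generate_mesh_series(v0 = 9.67, C = 0.01 / r^(2 * p_true),
                                     p = p_true, r = r)
    expect_equal(gci_report(ms_small$value, r = r)$asymptotic_ratio, 1,
                 tolerance = 0.01)
  }
  expect_error(richardson_extrapolate(9.5, 9.4, r = 1, p = 2))
  expect_error(richardson_extrapolate(9.5, 9.4, r = 2, p = 0))
})

test_that("GCI has the documented conventions and degenerate limits", {
  p <- observed_order(9.58, 9.41, 8.92, 2)
  expect_equal(gci(9.41, 8.92, 2, p, 1.25), 3.65, tolerance = 0.005)
  expect_equal(gci(9.58, 9.41, 2, p, 1.25), 1.20, tolerance = 0.005)
  expect_equal(gci(9.58, 9.41, 2, p, 1.25, normalize = "fine"), 1.18,
               tolerance = 0.005)
  expect_equal(gci(9.5, 9.5, 2, p), 0)
  expect_error(gci(9.5, 9.4, 1, p))
})

test_that("the asymptotic ratio is near 1 for the mesh study and decreases with p", {
  rep <- gci_report(c(9.58, 9.41, 8.92))
  expect_equal(rep$asymptotic_ratio, 1.05, tolerance = 0.01)
  p <- rep$observed_order_p
  expect_lt(asymptotic_ratio(rep$gci_23, rep$gci_12, 2, 2 * p),
            asymptotic_ratio(rep$gci_23, rep$gci_12, 2, p))
  expect_error(asymptotic_ratio(3, 0, 2, p))
})

test_that("per-level errors reproduce the mesh-study error column", {
  vext <- 9.670312
  e <- per_level_errors(c(9.58, 9.41, 8.92), vext)
  expect_equal(e, c(0.93, 2.69, 7.76), tolerance = 0.005)
  expect_equal(per_level_errors(vext, vext), 0)
  expect_error(per_level_errors(c(1, 2, 3), 0))
})

test_that("noisy synthetic mesh series yield order estimates centred on the truth", {
  p_hat <- vapply(1:100, function(s) {
    ms <- generate_mesh_series(9.67, C = 0.8, p = 1.5, r = 2, noise_sd = 0.002,
                               seed = s)
    tryCatch(observed_order(ms$value[1], ms$value[2], ms$value[3], 2),
             error = function(e) NA_real_)
  }, numeric(1))
  expect_gt(mean(!is.na(p_hat)), 0.9)
  expect_equal(median(p_hat, na.rm = TRUE), 1.5, tolerance = 0.05)
})

test_that("mesh-level CSV files round-trip into a report", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("M1", "M2", "M3"),
                       cell_count = c(404620, 196107, 98854),
                       value = c(9.58, 9.41, 8.92)),
            path, row.names = FALSE)
  lv <- read_mesh_levels(path)
  rep <- gci_report(lv$value, cell_counts = lv$cell_count, labels = lv$label)
  expect_equal(rep$extrapolated_value, 9.67, tolerance = 0.005)
  expect_output(print(rep), "asymptotic ratio")
  unlink(path)
})
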