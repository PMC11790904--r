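test_that("reference_current averages the waiting plateau", {
  cv <- coarse_curve(4)
  expect_equal(reference_current(cv), test_pipette()$i_ref_pA)
  # noisy plateau: within 3 SD / sqrt(n) of truth (seeded)
  cn <- coarse_curve(4, noise_sd = 0.01, seed = 5)
  n_pl <- cn$plateau[2] - cn$plateau[1] + 1
  expect_lt(abs(reference_current(cn) - 1000), 3 * 10 / sqrt(n_pl))
  cv$plateau <- NULL
  expect_error(reference_current(cv), "no-reference")
})

test_that("setpoint_z finds the interpolated crossing", {
  # generator places the crossing exactly at surface_z_nm
  cv <- coarse_curve(4, surface_z_nm = 500)
  expect_equal(setpoint_z(cv, setpoint = 0.98), 500, tolerance = 1e-6)
  # monotone curve: unique crossing equals the constructed one at any height
  cv2 <- coarse_curve(1.5, surface_z_nm = 1234)
  expect_equal(setpoint_z(cv2, setpoint = 0.98), 1234, tolerance = 1e-6)
  # curve above the set point throughout -> no contact
  pip <- test_pipette()
  high <- synth_approach_curve(4, pip, z_grid = seq(5000, 4000, by = -10),
                               surface_z_nm = 0, n_plateau = 10)
  expect_error(setpoint_z(high, setpoint = 0.98), "no-contact")
})

test_that("window_slope fits the 98.5-99% line and rejects sparse windows", {
  pip <- test_pipette()
  cv <- coarse_curve(4)
  s <- window_slope(cv, smooth_n = 1L)
  expect_lt(abs(s - pip$s_inf / 2) / (pip$s_inf / 2), 1e-6)
  # window with < 2 samples errors
  sparse <- synth_approach_curve(4, pip, z_grid = seq(3000, -300, by = -300),
                                 n_plateau = 5)
  expect_error(window_slope(sparse, smooth_n = 1L), "window-too-sparse")
})

test_that("youngs_modulus inverts the slope with rigid/invalid flags", {
  expect_equal(youngs_modulus(1e-4, 2e-4, p0 = 10, A = 0.4), 4)
  expect_equal(youngs_modulus(5e-5, 2e-4, p0 = 10, A = 0.4), 4 / 3)
  expect_identical(youngs_modulus(2e-4, 2e-4), Inf)      # rigid flag
  expect_error(youngs_modulus(0, 2e-4), "invalid-slope")
  expect_error(youngs_modulus(3e-4, 2e-4), "invalid-slope")
})

test_that("stiffness_map round-trips a noise-free phantom", {
  ph <- small_phantom()
  g <- coarse_scan(ph, seed = 1)
  sm <- stiffness_map(g)
  expect_identical(dim(sm$E), c(16L, 16L))
  cell <- ph$labels != "substrate"
  expect_true(all(sm$valid_mask))
  relerr <- abs(sm$E[cell] - ph$E[cell]) / ph$E[cell]
  expect_lt(max(relerr), 1e-6)
  # topography reproduced on all pixels
  expect_lt(max(abs(sm$topography - ph$topography)), 1e-6)
  # substrate pixels flagged rigid
  expect_true(all(sm$substrate_mask[!cell]))
  expect_false(any(sm$substrate_mask[cell]))
})

test_that("all-substrate grids yield a full substrate mask", {
  ph <- make_phantom(nx = 8, ny = 8, extent_um = 10, process_length_um = 0,
                     soma_axes_um = c(0.01, 0.01))
  ph$labels[] <- "substrate"; ph$E[] <- Inf; ph$topography[] <- 0
  g <- coarse_scan(ph)
  sm <- stiffness_map(g)
  expect_true(all(sm$substrate_mask))
  expect_false(any(is.finite(sm$E)))
})

test_that("s_inf can be estimated from a substrate mask", {
  ph <- small_phantom()
  g <- coarse_scan(ph)
  sub <- ph$labels == "substrate"
  sm <- stiffness_map(g, substrate_mask = sub)
  expect_equal(sm$s_inf, test_pipette()$s_inf, tolerance = 1e-6)
})

test_that("roi_delta_series measures stiffness changes against the control", {
  ph <- small_phantom()
  pipette <- test_pipette()
  g1 <- coarse_scan(ph)
  sm1 <- stiffness_map(g1)
  # identical maps -> all deltas 0
  expect_equal(roi_delta_series(list(sm1, sm1, sm1), ph$labels == "soma"),
               c(0, 0))
  # E increased by +2 kPa on cell pixels at t2 -> delta ~ +2
  ph2 <- ph; ph2$E[ph$labels != "substrate"] <- ph$E[ph$labels != "substrate"] + 2
  sm2 <- stiffness_map(coarse_scan(ph2))
  d <- roi_delta_series(list(sm1, sm2), ph$labels == "soma")
  expect_equal(d, 2, tolerance = 1e-6)
  # 3 timepoints -> 2 retained deltas; with the control kept it is 3
  expect_length(roi_delta_series(list(sm1, sm2, sm2), ph$labels == "soma"), 2)
  full <- roi_delta_series(list(sm1, sm2, sm2), ph$labels == "soma",
                           drop_first = FALSE)
  expect_equal(full[1], 0)
  # polygon ROI route
  dpoly <- roi_delta_series(list(sm1, sm2),
                            list(x_um = c(0.5, 4.5, 4.5, 0.5),
                                 y_um = c(3, 3, 7, 7)))
  expect_equal(dpoly, 2, tolerance = 1e-6)
  expect_error(roi_delta_series(list(sm1), ph$labels == "soma"), "roi-error")
  empty <- matrix(FALSE, 16, 16)
  expect_error(roi_delta_series(list(sm1, sm2), empty), "roi-error")
})

test_that("stiffness change tracks length change on coupled-cohort records", {
  # positive tension-length coupling: per cell, tension (stiffness proxy)
  # sampled at 3 timepoints relative to the first mirrors the length change
  co <- small_cohort(n = 12, seed = 40)
  dL <- dT <- NULL
  for (rec in co) {
    idx <- c(1, 721, 1441)          # 0, 60, 120 min on the 5-s grid
    dL <- c(dL, diff(rec$length_um[idx]))
    dT <- c(dT, diff(rec$tension_ns[idx]))
  }
  expect_gte(length(dL), 20)
  expect_gt(spearman_test(dT, dL)$rho, 0)
})
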