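test_that("hydraulic diameter matches hand-evaluated cases and its bounds", {
  expect_equal(hydraulic_diameter(500e-6, 100e-6), 166.67e-6,
               tolerance = 1e-4)
  expect_equal(hydraulic_diameter(500e-6, 70e-6), 122.81e-6,
               tolerance = 1e-4)
  expect_equal(hydraulic_diameter(37e-6, 37e-6), 37e-6)  # square duct
  # symmetry and upper bound 2*min(w, h)
  for (wh in list(c(1e-3, 5e-5), c(2e-4, 2e-4), c(7e-4, 1e-4))) {
    expect_identical(hydraulic_diameter(wh[1], wh[2]),
                     hydraulic_diameter(wh[2], wh[1]))
    expect_lte(hydraulic_diameter(wh[1], wh[2]), 2 * min(wh))
  }
  expect_equal(hydraulic_diameter(3e-4, 3e-4), 2 * 3e-4 / 2) # equality w = h
  expect_error(hydraulic_diameter(0, 1e-4), "invalid geometry")
})

test_that("Reynolds number and its inverse agree with hand evaluation", {
  fl <- fluid_properties()
  D_h <- hydraulic_diameter(500e-6, 70e-6)
  expect_equal(reynolds_number(fl, 0, D_h), 0)
  expect_equal(mean_velocity_from_reynolds(fl, 65, D_h), 0.5293,
               tolerance = 1e-3)
  expect_equal(mean_velocity_from_reynolds(fl, 40, D_h), 0.3257,
               tolerance = 1e-3)
  # round trip
  U <- mean_velocity_from_reynolds(fl, 47.3, D_h)
  expect_equal(reynolds_number(fl, U, D_h), 47.3)
})

test_that("Dean number follows Re sqrt(D_h / 2R) with curvature limits", {
  D_h <- 122.81e-6
  expect_equal(dean_number(65, D_h, Inf), 0)      # straight channel
  expect_equal(dean_number(65, D_h, 5e-3), 7.20, tolerance = 1e-3)
  expect_equal(dean_number(40, D_h, 5e-3), 4.43, tolerance = 1e-3)
  expect_error(dean_number(65, D_h, -1), "invalid curvature")
  # De < Re for every catalogued geometry (delta < 1 there)
  for (ch in c("S1", "S2", "S3", "S4")) {
    g <- build_channel(ch)
    expect_lt(dean_number(65, g$D_h_spiral, g$first_radius), 65)
  }
})

test_that("Dean velocity correlation is anchored, monotone and continuous", {
  expect_equal(dean_velocity(0), 0)
  expect_equal(dean_velocity(1), 1.8e-4)
  expect_equal(dean_velocity(7.20), 4.49e-3, tolerance = 1e-2)
  De <- seq(0, 12, length.out = 400)
  expect_true(all(diff(dean_velocity(De)) > 0))
  expect_lt(abs(dean_velocity(5 + 1e-9) - dean_velocity(5)), 1e-9)
  expect_error(dean_velocity(-0.1), "non-negative")
})

test_that("Dean drag force is 3 pi mu U_De a_p and linear in both", {
  expect_equal(dean_drag_force(1e-3, 0, 20e-6), 0)
  expect_equal(dean_drag_force(1e-3, 4.49e-3, 20e-6), 8.46e-10,
               tolerance = 1e-2)
  f1 <- dean_drag_force(1e-3, 2e-3, 10e-6)
  expect_equal(dean_drag_force(1e-3, 2e-3, 20e-6), 2 * f1)
  expect_equal(dean_drag_force(1e-3, 4e-3, 10e-6), 2 * f1)
})

test_that("inertial lift force scales with U_max^2 and a_p^4", {
  expect_equal(inertial_lift_force(0.5, 1000, 0, 20e-6, 122.81e-6), 0)
  expect_equal(inertial_lift_force(0.5, 1000, 1.0, 20e-6, 122.81e-6),
               5.30e-9, tolerance = 1e-2)
  f1 <- inertial_lift_force(0.5, 1000, 1.0, 10e-6, 1e-4)
  expect_equal(inertial_lift_force(0.5, 1000, 1.0, 20e-6, 1e-4), 16 * f1)
  expect_equal(inertial_lift_force(0.5, 1000, 2.0, 10e-6, 1e-4), 4 * f1)
})

test_that("lift grows as a_p^4 while Dean drag grows as a_p, so their ratio
          orders particle sizes", {
  ratio <- function(a) {
    inertial_lift_force(0.5, 1000, 0.5, a, 122.81e-6) /
      dean_drag_force(1e-3, 2e-3, a)
  }
  expect_equal(ratio(2 * 10e-6) / ratio(10e-6), 8)  # a^4 / a = a^3
})

test_that("focusing criterion reproduces the catalogued thresholds", {
  expect_true(focusing_ratio(11.7e-6, 166.67e-6)$focused)
  expect_true(focusing_ratio(8.6e-6, 122.81e-6)$focused)
  expect_false(focusing_ratio(6e-6, 166.67e-6)$focused)
  expect_equal(focusing_ratio(6e-6, 166.67e-6)$ratio, 0.036,
               tolerance = 1e-2)
  expect_equal(threshold_diameter(166.67e-6), 0.07 * 166.67e-6)
})

test_that("acoustic contrast factor has the right sign structure", {
  # medium-matched particle
  expect_equal(acoustic_contrast_factor(1000, 1000, 4.48e-10, 4.48e-10), 0)
  expect_equal(acoustic_contrast_factor(1050, 1000, 4.0e-10, 4.48e-10),
               0.156, tolerance = 1e-2)
  # rigid dense limit: (5 rho_p)/(2 rho_p) - 0 -> 2.5
  expect_equal(acoustic_contrast_factor(1e12, 1000, 0, 4.48e-10), 2.5,
               tolerance = 1e-6)
  # default cells migrate to nodes (positive contrast)
  for (ty in c("CTC", "WBC", "RBC")) {
    cl <- cell_preset(ty)
    expect_gt(acoustic_contrast_factor(cl$density, 1000,
                                       cl$compressibility, 4.48e-10), 0)
  }
})

test_that("acoustic radiation force vanishes at nodes, restores, and
          integrates to zero over a wavelength", {
  lam <- 454.5e-6
  V <- pi * (20e-6)^3 / 6
  F <- function(y) acoustic_radiation_force(1.8e5, lam, V, 4.48e-10,
                                            0.156, y, node_offset = 0)
  expect_equal(F(0), 0)             # at the node
  expect_equal(F(lam / 2), 0, tolerance = 1e-25)
  expect_lt(F(1e-6), 0)             # restoring just beyond the node
  expect_gt(F(-1e-6), 0)
  # peak magnitude for the CTC defaults
  expect_equal(max(abs(F(seq(0, lam, length.out = 2001)))), 3.27e-11,
               tolerance = 1e-2)
  # periodicity: integral over one wavelength is zero
  y <- seq(0, lam, length.out = 4001)
  integral <- sum((F(y[-1]) + F(y[-length(y)])) / 2) * diff(y)[1]
  expect_lt(abs(integral), 1e-22)
})

test_that("Stokes drag opposes relative motion linearly", {
  expect_equal(stokes_drag(1e-3, 10e-6, 0), 0)
  expect_equal(abs(stokes_drag(1e-3, 10e-6, 1e-3)), 1.885e-10,
               tolerance = 1e-3)
  expect_lt(stokes_drag(1e-3, 10e-6, 1e-3), 0)  # opposes motion
  expect_equal(stokes_drag(1e-3, 10e-6, 2e-3),
               2 * stokes_drag(1e-3, 10e-6, 1e-3))
  # vector form
  expect_equal(stokes_drag(1e-3, 10e-6, c(1e-3, -2e-3)),
               c(-1, 2) * abs(stokes_drag(1e-3, 10e-6, 1e-3)))
})

test_that("cell presets carry consistent derived quantities", {
  ctc <- cell_preset("CTC")
  expect_equal(ctc$diameter, 20e-6)
  expect_equal(cell_preset("WBC")$diameter, 9e-6)
  expect_equal(cell_preset("RBC")$diameter, 6e-6)
  expect_equal(ctc$density, 1050)
  expect_equal(ctc$volume, pi * (20e-6)^3 / 6, tolerance = 1e-12)
  expect_equal(ctc$mass, 1050 * ctc$volume)
  expect_equal(ctc$radius, 10e-6)
  expect_error(cell_preset("platelet"), "unknown cell preset")
  expect_error(cell_type("x", -1e-6), "strictly positive")
})
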