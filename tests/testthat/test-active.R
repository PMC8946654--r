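test_that("standing-wave envelope: nodes at zero pressure, amplitude p_0,
          symmetric magnitude about the midline", {
  fld <- acoustic_field()
  nodes <- nodal_positions(fld)
  expect_equal(standing_pressure(nodes, fld), rep(0, 5), tolerance = 1e-10)
  y <- seq(0, 1e-3, length.out = 20001)
  expect_equal(max(abs(standing_pressure(y, fld))), 1.8e5,
               tolerance = 1e-6)
  expect_equal(abs(standing_pressure(0.2e-3, fld)),
               abs(standing_pressure(0.8e-3, fld)))
  expect_equal(fld$wavelength * fld$frequency, fld$sound_speed)
})

test_that("five nodal lines at the catalogued positions, spaced half a
          wavelength", {
  fld <- acoustic_field()
  nodes <- nodal_positions(fld)
  expect_length(nodes, 5)
  expect_equal(nodes, c(45.5, 272.7, 500.0, 727.3, 954.5) * 1e-6,
               tolerance = 2e-4)
  expect_equal(diff(nodes), rep(fld$wavelength / 2, 4), tolerance = 1e-9)
  # independent zero-finder: sign changes of the envelope, refined
  y <- seq(0, 1e-3, length.out = 5000)
  p <- standing_pressure(y, fld)
  sgn <- which(diff(sign(p)) != 0)
  found <- vapply(sgn, function(i) {
    stats::uniroot(function(q) standing_pressure(q, fld),
                   c(y[i], y[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  expect_equal(sort(found), nodes, tolerance = 1e-9 / max(nodes))
  # a section exactly one wavelength wide has its wall zeros discarded
  expect_length(nodal_positions(fld, width = fld$wavelength), 1)
})

test_that("a particle released on a node with zero velocity stays there", {
  ens <- make_cell_ensemble(c(CTC = 1), 1e-3, 70e-6, placement = "point",
                            seed = 1)
  ens$particles$y0 <- 500e-6      # the midline node
  res <- run_active_stage(ens, acoustic_field(), fluid_properties(),
                          duration = 0.2)
  expect_true(res$particles$trapped)
  expect_equal(res$particles$trapping_time, 0)
  expect_equal(res$particles$y_final, 500e-6, tolerance = 1e-12)
})

test_that("closed-form trapping time: zero on the node, rate inversely
          proportional to particle radius, antinode divergence", {
  fld <- acoustic_field(); k <- fld$wavenumber
  expect_equal(trapping_time_closed_form(500e-6, 500e-6, 3.3e-11, k,
                                         1e-3, 10e-6), 0)
  t1 <- trapping_time_closed_form(530e-6, 500e-6, 3.3e-11, k, 1e-3, 10e-6)
  t2 <- trapping_time_closed_form(530e-6, 500e-6, 3.3e-11, k, 1e-3, 5e-6)
  expect_equal(t2, t1 / 2)
  expect_warning(
    t_anti <- trapping_time_closed_form(500e-6 + fld$wavelength / 4,
                                        500e-6, 3.3e-11, k, 1e-3, 10e-6),
    "antinode")
  expect_identical(t_anti, Inf)
})

test_that("adaptive overdamped integration matches the tangent closed form
          to 1e-6 relative", {
  fld <- acoustic_field(); fl <- fluid_properties()
  ctc <- cell_preset("CTC")
  rs <- spiralsaw:::radiation_scale(fld, fl, ctc)
  k <- fld$wavenumber
  gamma <- drag_coefficient(fl$viscosity, ctc$radius)
  rate <- 2 * k * rs$F0 / gamma
  y0 <- 560e-6; node <- 500e-6
  times <- seq(0, 0.5, by = 0.05)
  num <- overdamped_acoustic_trajectory(y0, fld, fl, ctc, times)
  analytic <- node + atan(tan(k * (y0 - node)) * exp(-rate * times)) / k
  expect_equal(num[, 2], analytic, tolerance = 1e-6)
})

test_that("the Newtonian trapping integrator agrees with the closed form
          within 1% for the CTC defaults", {
  fld <- acoustic_field(); fl <- fluid_properties()
  ctc <- cell_preset("CTC")
  rs <- spiralsaw:::radiation_scale(fld, fl, ctc)
  t_ref <- trapping_time_closed_form(530e-6, 500e-6, rs$F0,
                                     fld$wavenumber, fl$viscosity,
                                     ctc$radius)
  ens <- make_cell_ensemble(c(CTC = 1), 1e-3, 70e-6, placement = "point",
                            seed = 1)
  ens$particles$y0 <- 530e-6
  res <- run_active_stage(ens, fld, fl, duration = 1)
  expect_equal(res$particles$trapping_time, t_ref, tolerance = 0.01)
})

test_that("trapping times order by size, with the RBC:CTC ratio near the
          inverse-square diameter scaling", {
  fld <- acoustic_field(); fl <- fluid_properties()
  ens <- make_cell_ensemble(c(CTC = 1, WBC = 1, RBC = 1), 1e-3, 70e-6,
                            placement = "point", seed = 1)
  ens$particles$y0 <- rep(530e-6, 3)   # identical off-node release
  res <- run_active_stage(ens, fld, fl, duration = 8)
  tt <- res$particles$trapping_time[match(c("CTC", "WBC", "RBC"),
                                          res$particles$type)]
  expect_true(all(res$particles$trapped))
  expect_lt(tt[1], tt[2])
  expect_lt(tt[2], tt[3])
  expect_gt(tt[3] / tt[1], 8)
  expect_lt(tt[3] / tt[1], 14)
})

test_that("distance to the nearest node is non-increasing in overdamped
          trapping dynamics", {
  fld <- acoustic_field(); fl <- fluid_properties()
  ctc <- cell_preset("CTC")
  times <- seq(0, 1, by = 0.01)
  y0 <- c(100e-6, 333e-6, 610e-6, 900e-6)
  out <- overdamped_acoustic_trajectory(y0, fld, fl, ctc, times)
  nodes <- nodal_positions(fld)
  for (j in seq_along(y0)) {
    d <- vapply(out[, j + 1], function(yy) min(abs(nodes - yy)),
                numeric(1))
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("a grid-released CTC ensemble is fully trapped within the run and
          no slower than the closed-form worst case", {
  fld <- acoustic_field(); fl <- fluid_properties()
  ens <- make_cell_ensemble(c(CTC = 40), 1e-3, 70e-6, placement = "grid",
                            seed = 7)
  res <- run_active_stage(ens, fld, fl, duration = 3)
  expect_true(all(res$particles$trapped))
  # worst grid release against the closed form, within integrator slack
  ctc <- cell_preset("CTC")
  rs <- spiralsaw:::radiation_scale(fld, fl, ctc)
  nodes <- nodal_positions(fld)
  t_ref <- vapply(ens$particles$y0, function(y0) {
    nd <- nodes[which.min(abs(nodes - y0))]
    trapping_time_closed_form(y0, nd, rs$F0, fld$wavenumber,
                              fl$viscosity, ctc$radius)
  }, numeric(1))
  expect_equal(res$particles$trapping_time, t_ref, tolerance = 0.02)
})

test_that("negative contrast cells trigger the antinode-migration warning", {
  fl <- fluid_properties()
  soft <- cell_type("bubble-like", 8e-6, density = 1050,
                    compressibility = 9e-10)  # beta_p >> beta_m
  ens <- make_cell_ensemble(c(`bubble-like` = 2), 1e-3, 70e-6, seed = 1,
                            cells = list(`bubble-like` = soft))
  expect_warning(run_active_stage(ens, acoustic_field(), fl,
                                  duration = 0.01),
                 "antinode")
})
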