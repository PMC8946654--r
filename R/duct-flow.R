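# Analytic surrogate for the device flow solution: fully developed
# rectangular-duct axial profile (Fourier series) plus a parametric
# two-vortex Dean secondary-flow field anchored to the Dean velocity
# correlation.

# cosh(a)/cosh(b) and sinh(a)/sinh-free gradients, computed in exp form so
# the series stays finite for large n * aspect ratio.
cosh_ratio <- function(a, b) {
  aa <- abs(a)
  (exp(aa - b) + exp(-aa - b)) / (1 + exp(-2 * b))
}
sinh_over_cosh <- function(a, b) {
  aa <- abs(a)
  sign(a) * (exp(aa - b) - exp(-aa - b)) / (1 + exp(-2 * b))
}

#' Axial velocity profile of a rectangular duct
#'
#' Classical Fourier-series solution for pressure-driven laminar flow in a
#' rectangular duct of width `width` (lateral y in `[0, width]`) and height
#' `height` (vertical z in `[0, height]`), truncated at `n_terms` odd modes
#' and normalised so the cross-sectional mean equals `U` (the mean is
#' evaluated analytically, so the normalisation is exact to machine
#' precision). The sine expansion runs along the height with hyperbolic
#' terms across the width.
#'
#' @param width,height Duct sides (m).
#' @param U Mean axial velocity (m/s).
#' @param n_terms Number of odd series terms (default 51, at which the
#'   square-duct peak-to-mean ratio is stable to 1e-5).
#' @return An object of class `duct_profile`: vectorised samplers
#'   `u(y, z)`, `du_dy(y, z)`, `du_dz(y, z)`, plus `U_max`, `U`, `width`,
#'   `height`, `shear_max` (the largest wall shear |du/dz|, used to
#'   normalise the lift direction model).
#' @export
#' @examples
#' pr <- rect_duct_profile(100e-6, 100e-6, U = 0.1)
#' pr$U_max / pr$U # ~ 2.096 for a square duct
rect_duct_profile <- function(width, height, U, n_terms = 51L) {
  if (n_terms < 1L) stop("n_terms must be at least 1", call. = FALSE)
  if (width <= 0 || height <= 0) {
    stop("invalid geometry: duct sides must be strictly positive",
         call. = FALSE)
  }
  if (U < 0) stop("U must be non-negative", call. = FALSE)
  n <- 2 * seq_len(n_terms) - 1           # odd modes
  bn <- n * pi * width / (2 * height)     # cosh half-width arguments
  # analytic cross-sectional mean of the unnormalised shape
  shape_mean <- sum((1 / n^3) * (2 / (n * pi)) *
                      (1 - (2 * height / (n * pi * width)) * tanh(bn)))

  shape <- function(y, z) {
    out <- numeric(length(y) * 0 + max(length(y), length(z)))
    y <- rep_len(y, length(out)); z <- rep_len(z, length(out))
    for (i in seq_along(n)) {
      a <- n[i] * pi * (y - width / 2) / height
      out <- out + (1 / n[i]^3) * (1 - cosh_ratio(a, bn[i])) *
        sin(n[i] * pi * z / height)
    }
    out
  }
  shape_dy <- function(y, z) {
    out <- numeric(max(length(y), length(z)))
    y <- rep_len(y, length(out)); z <- rep_len(z, length(out))
    for (i in seq_along(n)) {
      a <- n[i] * pi * (y - width / 2) / height
      out <- out - (1 / n[i]^3) * (n[i] * pi / height) *
        sinh_over_cosh(a, bn[i]) * sin(n[i] * pi * z / height)
    }
    out
  }
  shape_dz <- function(y, z) {
    out <- numeric(max(length(y), length(z)))
    y <- rep_len(y, length(out)); z <- rep_len(z, length(out))
    for (i in seq_along(n)) {
      a <- n[i] * pi * (y - width / 2) / height
      out <- out + (1 / n[i]^3) * (1 - cosh_ratio(a, bn[i])) *
        (n[i] * pi / height) * cos(n[i] * pi * z / height)
    }
    out
  }
  scale <- U / shape_mean
  U_max <- scale * shape(width / 2, height / 2)
  shear_max <- abs(scale * shape_dz(width / 2, 0))
  structure(list(
    u = function(y, z) scale * shape(y, z),
    du_dy = function(y, z) scale * shape_dy(y, z),
    du_dz = function(y, z) scale * shape_dz(y, z),
    U = U, U_max = U_max, shear_max = shear_max,
    width = width, height = height, n_terms = n_terms
  ), class = "duct_profile")
}

#' @export
print.duct_profile <- function(x, ...) {
  cat(sprintf(
    "<duct_profile> %g x %g um, U=%.4g m/s, U_max/U=%.4f (%d terms)\n",
    x$width * 1e6, x$height * 1e6, x$U,
    if (x$U > 0) x$U_max / x$U else NA_real_, x$n_terms))
  invisible(x)
}

#' Sample a duct profile on a grid
#'
#' @param profile A [rect_duct_profile()].
#' @param ny,nz Grid resolution.
#' @return A data frame with columns `y`, `z`, `u` for inspection/plotting.
#' @export
profile_grid <- function(profile, ny = 101L, nz = 51L) {
  y <- seq(0, profile$width, length.out = ny)
  z <- seq(0, profile$height, length.out = nz)
  g <- expand.grid(y = y, z = z)
  g$u <- profile$u(g$y, g$z)
  g
}

#' Parametric Dean secondary-flow field
#'
#' Two counter-rotating vortices, mirror-symmetric about mid-height, built
#' from the stream function \eqn{\psi \propto \sin(\pi y/w)\sin(2\pi z/h)}
#' and scaled so the peak in-plane speed equals the Dean velocity
#' correlation at the given Dean number. Direction: outward (inner to outer
#' wall) at mid-height, returning along the top and bottom walls. The field
#' is divergence-free by construction and tangent to all four walls.
#'
#' @param width,height Duct sides (m).
#' @param De Dean number (non-negative; `De = 0` gives the zero field).
#' @return An object of class `dean_field` with vectorised samplers
#'   `v_y(y, z)`, `v_z(y, z)` and the peak speed `U_De`.
#' @export
dean_secondary_field <- function(width, height, De) {
  if (De < 0) stop("De must be non-negative", call. = FALSE)
  U_De <- dean_velocity(De)
  structure(list(
    v_y = function(y, z) {
      -U_De * sin(pi * y / width) * cos(2 * pi * z / height)
    },
    v_z = function(y, z) {
      U_De * (height / (2 * width)) * cos(pi * y / width) *
        sin(2 * pi * z / height)
    },
    U_De = U_De, De = De, width = width, height = height
  ), class = "dean_field")
}

#' Flow state along the device path
#'
#' Fixes the mean axial velocity per section from the prescribed Reynolds
#' number (defined on the spiral hydraulic diameter) and mass conservation
#' across the expansion, and exposes the local Dean number and Dean
#' velocity as functions of arc length.
#'
#' @param path A [build_spiral_path()].
#' @param fluid A [fluid_properties()].
#' @param Re Channel Reynolds number (spiral section).
#' @param n_terms Series truncation forwarded to [rect_duct_profile()].
#' @return An object of class `flow_state`: mean and peak velocities per
#'   section (`U_spiral`, `U_straight`, `profile_spiral`,
#'   `profile_straight`), and vectorised `De_at(s)`, `U_De_at(s)`.
#' @export
#' @examples
#' path <- build_spiral_path(build_channel("S4"))
#' fs <- flow_state_along_path(path, fluid_properties(), Re = 65)
#' fs$U_spiral   # 0.5293 m/s
#' fs$De_at(0)   # 7.20
flow_state_along_path <- function(path, fluid, Re, n_terms = 51L) {
  stopifnot(inherits(path, "spiral_path"), inherits(fluid, "fluid_properties"))
  geom <- path$geometry
  U_sp <- mean_velocity_from_reynolds(fluid, Re, geom$D_h_spiral)
  # mass conservation across the expansion (same height both sections)
  U_st <- U_sp * geom$spiral_width / geom$straight_width
  De_at <- function(s) {
    R <- path$radius_at(s)
    dean_number(Re, geom$D_h_spiral, R)
  }
  structure(list(
    path = path, fluid = fluid, Re = Re,
    U_spiral = U_sp, U_straight = U_st,
    profile_spiral = rect_duct_profile(geom$spiral_width, geom$height,
                                       U_sp, n_terms),
    profile_straight = rect_duct_profile(geom$straight_width, geom$height,
                                         U_st, n_terms),
    De_at = De_at,
    U_De_at = function(s) dean_velocity(De_at(s))
  ), class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf(
    "<flow_state> Re=%g: U=%.4g m/s (spiral), %.4g m/s (straight); De(0)=%.2f\n",
    x$Re, x$U_spiral, x$U_straight, x$De_at(0)))
  invisible(x)
}
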