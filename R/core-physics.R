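# Closed-form microfluidic force laws and dimensionless groups.
# All quantities SI unless noted. Pure functions: no device state.

#' Fluid properties
#'
#' Container for the carrier-fluid constants used throughout the simulator.
#' Defaults are water at room temperature: the density/viscosity pair that,
#' together with c = 1500 m/s, reproduces the device's printed focusing
#' thresholds and acoustic wavelength.
#'
#' @param density Fluid density \eqn{\rho_m} (kg/m^3).
#' @param viscosity Dynamic viscosity \eqn{\mu} (Pa s).
#' @param sound_speed Speed of sound \eqn{c} (m/s).
#' @param compressibility Fluid compressibility \eqn{\beta_m} (1/Pa).
#' @return An object of class `fluid_properties`.
#' @export
#' @examples
#' fluid_properties()
fluid_properties <- function(density = 1000, viscosity = 1e-3,
                             sound_speed = 1500, compressibility = 4.48e-10) {
  vals <- c(density = density, viscosity = viscosity,
            sound_speed = sound_speed, compressibility = compressibility)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fluid properties must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf(
    "<fluid_properties> rho=%g kg/m^3  mu=%g Pa.s  c=%g m/s  beta=%g 1/Pa\n",
    x$density, x$viscosity, x$sound_speed, x$compressibility))
  invisible(x)
}

#' Cell type
#'
#' A spherical cell model: diameter, density and compressibility, with the
#' derived radius, volume and mass. Presets for the three blood-sample cell
#' classes are available through [cell_preset()].
#'
#' @param name Label, e.g. `"CTC"`.
#' @param diameter Cell diameter \eqn{a_p} (m).
#' @param density Cell density \eqn{\rho_p} (kg/m^3).
#' @param compressibility Cell compressibility \eqn{\beta_p} (1/Pa).
#' @return An object of class `cell_type` with fields `radius`, `volume`
#'   (\eqn{\pi a_p^3/6}) and `mass`.
#' @export
#' @examples
#' cell_type("CTC", diameter = 20e-6)
cell_type <- function(name, diameter, density = 1050,
                      compressibility = 4.0e-10) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(diameter) || diameter <= 0) {
    stop("cell diameter must be strictly positive", call. = FALSE)
  }
  if (density <= 0 || compressibility <= 0) {
    stop("cell density and compressibility must be strictly positive",
         call. = FALSE)
  }
  volume <- pi * diameter^3 / 6
  structure(list(
    name = name,
    diameter = diameter,
    density = density,
    compressibility = compressibility,
    radius = diameter / 2,
    volume = volume,
    mass = density * volume
  ), class = "cell_type")
}

#' @export
print.cell_type <- function(x, ...) {
  cat(sprintf("<cell_type> %s: a_p=%.3g um  rho_p=%g kg/m^3  m_p=%.3g kg\n",
              x$name, x$diameter * 1e6, x$density, x$mass))
  invisible(x)
}

#' Cell presets: CTC, WBC, RBC
#'
#' The three monodisperse cell classes of the blood-sample model: circulating
#' tumor cells (20 um), white blood cells (9 um) and red blood cells (6 um),
#' all at 1050 kg/m^3.
#'
#' @param name One of `"CTC"`, `"WBC"`, `"RBC"` (case-insensitive).
#' @param compressibility Cell compressibility (1/Pa), shared by all presets.
#' @return A [cell_type()].
#' @export
#' @examples
#' cell_preset("RBC")
cell_preset <- function(name, compressibility = 4.0e-10) {
  key <- toupper(name)
  diam <- switch(key, CTC = 20e-6, WBC = 9e-6, RBC = 6e-6,
                 stop(sprintf("unknown cell preset '%s'", name), call. = FALSE))
  cell_type(key, diameter = diam, density = 1050,
            compressibility = compressibility)
}

#' Hydraulic diameter of a rectangular duct
#'
#' \eqn{D_h = 2ab/(a+b)} for a duct of sides `width` and `height`.
#'
#' @param width,height Duct sides (m).
#' @return Hydraulic diameter (m).
#' @export
#' @examples
#' hydraulic_diameter(500e-6, 100e-6) # 166.67 um
hydraulic_diameter <- function(width, height) {
  if (any(width <= 0) || any(height <= 0)) {
    stop("invalid geometry: duct sides must be strictly positive",
         call. = FALSE)
  }
  2 * width * height / (width + height)
}

#' Channel Reynolds number
#'
#' \eqn{Re = \rho U D_h / \mu}: ratio of inertial to viscous forces.
#'
#' @param fluid A [fluid_properties()].
#' @param U Mean (section-averaged) velocity (m/s).
#' @param D_h Hydraulic diameter (m).
#' @return Dimensionless Reynolds number.
#' @seealso [mean_velocity_from_reynolds()] for the algebraic inverse.
#' @export
reynolds_number <- function(fluid, U, D_h) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(D_h <= 0)) stop("D_h must be strictly positive", call. = FALSE)
  fluid$density * U * D_h / fluid$viscosity
}

#' Mean velocity at a prescribed Reynolds number
#'
#' Inverse of [reynolds_number()]: \eqn{U = Re\,\mu/(\rho D_h)}.
#'
#' @inheritParams reynolds_number
#' @param Re Target Reynolds number.
#' @return Mean velocity (m/s).
#' @export
#' @examples
#' mean_velocity_from_reynolds(fluid_properties(), 65, 122.81e-6) # 0.529 m/s
mean_velocity_from_reynolds <- function(fluid, Re, D_h) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(D_h <= 0)) stop("D_h must be strictly positive", call. = FALSE)
  Re * fluid$viscosity / (fluid$density * D_h)
}

#' Dean number
#'
#' \eqn{De = Re\sqrt{D_h/(2R)}}: strength of the curvature-induced secondary
#' flow at local curvature radius `R`. `R = Inf` (straight channel) gives 0.
#'
#' @param Re Reynolds number.
#' @param D_h Hydraulic diameter (m).
#' @param R Local radius of curvature (m); may be `Inf`.
#' @return Dimensionless Dean number.
#' @export
dean_number <- function(Re, D_h, R) {
  if (any(D_h <= 0)) stop("D_h must be strictly positive", call. = FALSE)
  if (any(R <= 0)) stop("invalid curvature: R must be strictly positive",
                        call. = FALSE)
  Re * sqrt(D_h / (2 * R))
}

#' Dean secondary-flow velocity correlation
#'
#' Empirical magnitude of the in-plane secondary flow,
#' \eqn{U_{De} = 1.8\times 10^{-4}\, De^{1.63}} (m/s).
#'
#' @param De Dean number (must be non-negative).
#' @return Secondary-flow velocity scale (m/s).
#' @export
dean_velocity <- function(De) {
  if (any(De < 0)) stop("De must be non-negative", call. = FALSE)
  1.8e-4 * De^1.63
}

#' Dean drag force magnitude
#'
#' Stokes drag of the secondary flow on a particle entrained at rest relative
#' to the axial flow: \eqn{F_{De} = 3\pi\mu U_{De} a_p}. Directed with the
#' local secondary flow.
#'
#' @param viscosity Fluid dynamic viscosity (Pa s).
#' @param U_De Dean velocity (m/s), see [dean_velocity()].
#' @param a_p Particle diameter (m).
#' @return Force magnitude (N).
#' @export
dean_drag_force <- function(viscosity, U_De, a_p) {
  if (any(a_p <= 0)) stop("a_p must be strictly positive", call. = FALSE)
  3 * pi * viscosity * U_De * a_p
}

#' Inertial lift force magnitude
#'
#' \eqn{F_L = C_L \rho U_{max}^2 a_p^4 / D_h^2}. Magnitude only; the lift
#' direction model lives in the passive-stage force composition.
#'
#' @param C_L Lift coefficient (dimensionless).
#' @param density Fluid density (kg/m^3).
#' @param U_max Maximum axial velocity (m/s).
#' @param a_p Particle diameter (m).
#' @param D_h Hydraulic diameter (m).
#' @return Force magnitude (N).
#' @export
inertial_lift_force <- function(C_L, density, U_max, a_p, D_h) {
  if (any(D_h <= 0)) stop("D_h must be strictly positive", call. = FALSE)
  C_L * density * U_max^2 * a_p^4 / D_h^2
}

#' Inertial focusing criterion
#'
#' The threshold ratio for inertial focusing: particles focus when
#' \eqn{a_p/D_h \ge 0.07}.
#'
#' @param a_p Particle diameter (m).
#' @param D_h Hydraulic diameter (m).
#' @return A list with `ratio` and logical `focused`.
#' @seealso [threshold_diameter()]
#' @export
#' @examples
#' focusing_ratio(9e-6, 122.81e-6)$focused # TRUE: just above threshold
focusing_ratio <- function(a_p, D_h) {
  if (any(D_h <= 0)) stop("D_h must be strictly positive", call. = FALSE)
  r <- a_p / D_h
  list(ratio = r, focused = r >= 0.07)
}

#' Smallest diameter subject to inertial focusing
#'
#' Companion of [focusing_ratio()]: \eqn{0.07\, D_h}.
#'
#' @param D_h Hydraulic diameter (m).
#' @return Threshold diameter (m).
#' @export
threshold_diameter <- function(D_h) {
  if (any(D_h <= 0)) stop("D_h must be strictly positive", call. = FALSE)
  0.07 * D_h
}

#' Acoustic contrast factor
#'
#' \eqn{\phi = (5\rho_p - 2\rho_m)/(2\rho_p + \rho_m) - \beta_p/\beta_m}.
#' Its sign decides the migration target in a standing wave: pressure nodes
#' for \eqn{\phi > 0}, antinodes for \eqn{\phi < 0}.
#'
#' @param rho_p,rho_m Particle and medium density (kg/m^3).
#' @param beta_p,beta_m Particle and medium compressibility (1/Pa).
#' @return Dimensionless contrast factor.
#' @export
#' @examples
#' acoustic_contrast_factor(1050, 1000, 4.0e-10, 4.48e-10) # ~ +0.156
acoustic_contrast_factor <- function(rho_p, rho_m, beta_p, beta_m) {
  if (any(rho_p <= 0) || any(rho_m <= 0) || any(beta_m <= 0)) {
    stop("densities and medium compressibility must be strictly positive",
         call. = FALSE)
  }
  (5 * rho_p - 2 * rho_m) / (2 * rho_p + rho_m) - beta_p / beta_m
}

#' Acoustic radiation force in a planar standing wave
#'
#' Lateral force on a small particle in a 1D standing wave of amplitude
#' \eqn{p_0} and wavelength \eqn{\lambda}:
#' \deqn{F_r = -\frac{\pi p_0^2 V_p \beta_m}{2\lambda}\,\phi\,
#'       \sin\!\big(2k(y - y_0)\big)}
#' with \eqn{k = 2\pi/\lambda} and `node_offset` \eqn{y_0} the position of a
#' pressure node. The force vanishes at every node and, for \eqn{\phi > 0},
#' is restoring there.
#'
#' @param p_0 Acoustic pressure amplitude (Pa).
#' @param wavelength Acoustic wavelength \eqn{\lambda} (m).
#' @param V_p Particle volume (m^3).
#' @param beta_m Medium compressibility (1/Pa).
#' @param phi Acoustic contrast factor, see [acoustic_contrast_factor()].
#' @param y Lateral position(s) (m).
#' @param node_offset Lateral position of a pressure node (m).
#' @return Signed force along the width axis (N); vectorised over `y`.
#' @export
acoustic_radiation_force <- function(p_0, wavelength, V_p, beta_m, phi, y,
                                     node_offset = 0) {
  if (wavelength <= 0) stop("wavelength must be strictly positive",
                            call. = FALSE)
  k <- 2 * pi / wavelength
  -(pi * p_0^2 * V_p * beta_m / (2 * wavelength)) * phi *
    sin(2 * k * (y - node_offset))
}

#' Stokes drag
#'
#' \eqn{F_d = -6\pi\mu R_p u_r}: viscous drag opposing the particle velocity
#' relative to the fluid. Vectorised: `u_r` may be a velocity vector.
#'
#' @param viscosity Fluid dynamic viscosity (Pa s).
#' @param R_p Particle radius (m).
#' @param u_r Relative velocity (particle minus fluid), m/s.
#' @return Drag force with the same shape as `u_r` (N).
#' @export
stokes_drag <- function(viscosity, R_p, u_r) {
  if (any(R_p <= 0)) stop("R_p must be strictly positive", call. = FALSE)
  -6 * pi * viscosity * R_p * u_r
}

# Stokes drag coefficient 6*pi*mu*R_p (N s/m); internal shorthand.
drag_coefficient <- function(viscosity, R_p) 6 * pi * viscosity * R_p
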