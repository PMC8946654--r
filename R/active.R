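# Active stage: 1D standing acoustic wave across the straight-section
# width and acoustophoretic trapping on its nodal lines.

#' Standing acoustic field in the straight section
#'
#' A lossless 1D standing wave across the channel width:
#' \eqn{p(y) = p_0 \cos(k(y - y_{mid}) - \mathrm{phase})}. The default
#' phase of \eqn{\pi/2} puts a pressure node on the channel midline, which
#' yields five interior nodal lines across the default 1 mm section, one
#' inside each outlet span.
#'
#' @param p_0 Pressure amplitude (Pa). The field extremum equals `p_0`.
#' @param frequency Driving frequency (Hz).
#' @param sound_speed Speed of sound in the fluid (m/s).
#' @param width Channel width the wave spans (m).
#' @param phase Phase offset (rad) relative to a midline antinode;
#'   `pi/2` (default) centres a node on the midline.
#' @param transducer_length Axial extent over which the wave acts in
#'   pipeline mode (m).
#' @return An object of class `acoustic_field` with derived `wavelength`
#'   (\eqn{\lambda = c/f}), `wavenumber` (\eqn{k = 2\pi/\lambda}),
#'   `omega` and `y_mid`.
#' @export
#' @examples
#' acoustic_field()$wavelength * 1e6 # 454.5 um
acoustic_field <- function(p_0 = 1.8e5, frequency = 3.3e6,
                           sound_speed = 1500, width = 1e-3,
                           phase = pi / 2, transducer_length = 5e-3) {
  if (any(c(p_0, frequency, sound_speed, width, transducer_length) <= 0)) {
    stop("acoustic field parameters must be strictly positive",
         call. = FALSE)
  }
  wavelength <- sound_speed / frequency
  structure(list(
    p_0 = p_0, frequency = frequency, sound_speed = sound_speed,
    width = width, phase = phase, transducer_length = transducer_length,
    wavelength = wavelength, wavenumber = 2 * pi / wavelength,
    omega = 2 * pi * frequency, y_mid = width / 2
  ), class = "acoustic_field")
}

#' @export
print.acoustic_field <- function(x, ...) {
  cat(sprintf(
    "<acoustic_field> f=%.3g MHz, c=%g m/s, lambda=%.1f um, p0=%.3g Pa, %d nodes\n",
    x$frequency / 1e6, x$sound_speed, x$wavelength * 1e6, x$p_0,
    length(nodal_positions(x))))
  invisible(x)
}

#' Standing-wave pressure amplitude envelope
#'
#' @param y Lateral position(s) (m) in `[0, width]`.
#' @param field An [acoustic_field()].
#' @return Pressure amplitude at `y` (Pa); the time factor is dropped.
#' @export
standing_pressure <- function(y, field) {
  stopifnot(inherits(field, "acoustic_field"))
  field$p_0 * cos(field$wavenumber * (y - field$y_mid) - field$phase)
}

#' Pressure nodal-line positions
#'
#' All interior zeros of the standing-wave envelope across the width,
#' spaced half a wavelength apart. Zeros falling on the walls are not
#' counted.
#'
#' @param field An [acoustic_field()].
#' @param width Channel width (m); defaults to the field's width.
#' @return Ordered numeric vector of node coordinates (m).
#' @export
#' @examples
#' round(nodal_positions(acoustic_field()) * 1e6, 1)
#' # 45.5 272.7 500.0 727.3 954.5
nodal_positions <- function(field, width = field$width) {
  if (width <= 0) stop("width must be strictly positive", call. = FALSE)
  k <- field$wavenumber
  y_mid <- width / 2   # pattern centered on the midline of the given width
  # zeros of cos(k(y - y_mid) - phase): k(y - y_mid) - phase = pi/2 + m*pi
  y_of <- function(m) y_mid + (field$phase + pi / 2 + m * pi) / k
  m_lo <- ceiling((k * (0 - y_mid) - field$phase - pi / 2) / pi)
  m_hi <- floor((k * (width - y_mid) - field$phase - pi / 2) / pi)
  nodes <- sort(y_of(seq(m_lo, m_hi)))
  eps <- 1e-12 * max(width, 1)
  nodes[nodes > eps & nodes < width - eps]
}

#' Active-stage parameters
#'
#' @param tol Trapping tolerance (m): a particle counts as trapped from the
#'   first time its distance to the nearest node stays within `tol`.
#'   Default 5 um — smaller than the smallest cell diameter, larger than
#'   integrator noise.
#' @param dt Newtonian integrator step (s).
#' @param rtol,atol Tolerances of the adaptive overdamped integrator.
#' @param mode `"newtonian"` or `"overdamped"`.
#' @return An object of class `active_params`.
#' @export
active_params <- function(tol = 5e-6, dt = 2e-4, rtol = 1e-10, atol = 1e-14,
                          mode = c("newtonian", "overdamped")) {
  mode <- match.arg(mode)
  if (tol <= 0 || dt <= 0) stop("tol and dt must be strictly positive",
                                call. = FALSE)
  structure(list(tol = tol, dt = dt, rtol = rtol, atol = atol, mode = mode),
            class = "active_params")
}

# Radiation-force parameters per cell type.
radiation_scale <- function(field, fluid, cell) {
  phi <- acoustic_contrast_factor(cell$density, fluid$density,
                                  cell$compressibility,
                                  fluid$compressibility)
  F0 <- pi * field$p_0^2 * cell$volume * fluid$compressibility /
    (2 * field$wavelength) * abs(phi)
  list(phi = phi, F0 = F0)
}

#' Run the acoustophoretic trapping stage (standalone, zero flow)
#'
#' Integrates the lateral equation of motion of every particle under the
#' acoustic radiation force and Stokes drag, from zero initial velocity,
#' and records per-particle trapping times (first time the distance to the
#' nearest node enters the tolerance band and stays inside it). This
#' mirrors the standalone standing-wave study: no axial flow, mesh-based
#' release.
#'
#' @param ensemble A [make_cell_ensemble()] over the straight cross-section.
#' @param field An [acoustic_field()].
#' @param fluid A [fluid_properties()].
#' @param duration Simulated time (s).
#' @param params An [active_params()].
#' @return An object of class `trapping_result`: data frame `particles`
#'   with `id`, `type`, `y0`, `y_final`, `node` (index of the nearest node),
#'   `trapping_time`, `trapped`; plus the node positions.
#' @export
run_active_stage <- function(ensemble, field, fluid, duration = 3,
                             params = active_params()) {
  stopifnot(inherits(ensemble, "cell_ensemble"),
            inherits(field, "acoustic_field"))
  nodes <- nodal_positions(field)
  if (!length(nodes)) stop("no interior nodes in the field", call. = FALSE)
  cp <- cell_table(ensemble)
  phis <- vapply(ensemble$cells, function(cl)
    acoustic_contrast_factor(cl$density, fluid$density,
                             cl$compressibility,
                             fluid$compressibility), numeric(1))
  if (any(phis < 0)) {
    warning("negative acoustic contrast factor: these cells migrate to ",
            "antinodes, not nodes", call. = FALSE)
  }
  cellv <- vapply(ensemble$cells, `[[`, numeric(1), "volume")[cp$type]
  phi_p <- phis[cp$type]
  gamma <- drag_coefficient(fluid$viscosity, cp$R_p)
  tau <- cp$mass / gamma
  k <- field$wavenumber
  Famp <- pi * field$p_0^2 * cellv * fluid$compressibility /
    (2 * field$wavelength) * phi_p

  n <- nrow(ensemble$particles)
  y <- ensemble$particles$y0
  v <- ensemble$particles$vy0
  t_trap <- rep(NA_real_, n)
  dist_node <- function(y) {
    idx <- vapply(y, function(yi) which.min(abs(nodes - yi)), integer(1))
    list(idx = idx, d = abs(y - nodes[idx]))
  }
  dn <- dist_node(y)
  d_old <- dn$d
  t_trap[d_old <= params$tol] <- 0
  dt <- params$dt
  overdamped <- params$mode == "overdamped"
  t <- 0
  while (t < duration) {
    Fr <- -Famp * sin(2 * k * (y - field$y_mid))
    if (overdamped) {
      v <- Fr / gamma
      y <- y + v * dt
    } else {
      st <- exp_step(y, v, Fr / gamma, tau, dt)
      y <- st$pos; v <- st$vel
    }
    rw <- reflect_walls(y, v, cp$R_p, field$width - cp$R_p)
    y <- rw$pos; v <- rw$vel
    t <- t + dt
    dn <- dist_node(y)
    entered <- is.na(t_trap) & dn$d <= params$tol
    if (any(entered)) {
      frac <- (d_old[entered] - params$tol) /
        pmax(d_old[entered] - dn$d[entered], .Machine$double.eps)
      t_trap[entered] <- t - dt + pmin(pmax(frac, 0), 1) * dt
    }
    # a particle that leaves the band was not durably trapped
    left <- !is.na(t_trap) & dn$d > params$tol
    t_trap[left] <- NA_real_
    d_old <- dn$d
  }
  particles <- data.frame(
    id = ensemble$particles$id, type = cp$type,
    y0 = ensemble$particles$y0, y_final = y, node = dn$idx,
    trapping_time = t_trap, trapped = !is.na(t_trap),
    stringsAsFactors = FALSE)
  structure(list(particles = particles, nodes = nodes, field = field,
                 duration = duration, tol = params$tol),
            class = "trapping_result")
}

#' @export
print.trapping_result <- function(x, ...) {
  tab <- tapply(x$particles$trapped, x$particles$type, mean)
  cat(sprintf("<trapping_result> %d particles over %g s, tol %g um\n",
              nrow(x$particles), x$duration, x$tol * 1e6))
  cat("  trapped fraction: ",
      paste(sprintf("%s %.0f%%", names(tab), 100 * tab), collapse = "  "),
      "\n")
  med <- tapply(x$particles$trapping_time, x$particles$type,
                stats::median, na.rm = TRUE)
  cat("  median trapping time (s): ",
      paste(sprintf("%s %.3g", names(med), med), collapse = "  "), "\n")
  invisible(x)
}

#' Closed-form overdamped trapping time
#'
#' In the overdamped regime the lateral coordinate relative to a node obeys
#' \eqn{\tan(k u(t)) = \tan(k u_0)\, e^{-2kF_0 t/(6\pi\mu R_p)}}; solving
#' for the first time \eqn{|u| \le} `tol` gives the trapping time. The
#' release must lie strictly between the two antinodes flanking the node;
#' a release exactly at an antinode is an unstable equilibrium and returns
#' `Inf`.
#'
#' @param y0 Release position (m).
#' @param node Node position (m).
#' @param F_0 Radiation force amplitude (N), i.e. the peak of
#'   \eqn{|F_r| = F_0 |\sin(2k u)|}.
#' @param k Wavenumber (1/m).
#' @param viscosity Fluid dynamic viscosity (Pa s).
#' @param R_p Particle radius (m).
#' @param tol Trapping tolerance (m).
#' @return Time to reach the tolerance band (s); 0 if already inside,
#'   `Inf` at an antinode.
#' @export
trapping_time_closed_form <- function(y0, node, F_0, k, viscosity, R_p,
                                      tol = 5e-6) {
  u0 <- abs(y0 - node)
  if (u0 >= pi / (2 * k) - 1e-15) {
    warning("release at or beyond an antinode: unstable equilibrium",
            call. = FALSE)
    return(Inf)
  }
  if (u0 <= tol) return(0)
  rate <- 2 * k * F_0 / drag_coefficient(viscosity, R_p)
  log(tan(k * u0) / tan(k * tol)) / rate
}

#' Overdamped acoustophoresis trajectory (adaptive integration)
#'
#' Integrates \eqn{dy/dt = F_r(y)/(6\pi\mu R_p)} with `deSolve::lsoda` at
#' tight tolerances. Used as the reference numerical path for validating
#' the trapping dynamics against [trapping_time_closed_form()].
#'
#' @param y0 Release position(s) (m).
#' @param field An [acoustic_field()].
#' @param fluid A [fluid_properties()].
#' @param cell A [cell_type()].
#' @param times Output times (s).
#' @param rtol,atol Integration tolerances.
#' @return A matrix: column 1 time, remaining columns one trajectory per
#'   release position.
#' @export
overdamped_acoustic_trajectory <- function(y0, field, fluid, cell, times,
                                           rtol = 1e-10, atol = 1e-14) {
  rs <- radiation_scale(field, fluid, cell)
  gamma <- drag_coefficient(fluid$viscosity, cell$radius)
  k <- field$wavenumber
  sgn <- sign(rs$phi)
  deriv <- function(t, y, parms) {
    list(-sgn * rs$F0 * sin(2 * k * (y - field$y_mid)) / gamma)
  }
  out <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  unclass(out)
}
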