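# Lagrangian particle tracing primitives.
#
# The Newtonian mode advances m_p dv/dt = F_drag + F_ext with an
# exponential (drag-exact) update: over one step the external force and
# fluid velocity are frozen, for which the linear drag ODE has the exact
# solution used below. The Stokes relaxation time (rho_p a_p^2 / 18 mu,
# microseconds for blood cells) is thereby integrated exactly, so the step
# size is set by the ms-scale variation of the force fields, not by drag
# stiffness. The overdamped mode drops particle inertia entirely and is
# integrated adaptively with deSolve::lsoda.

# Exact one-step solution of  m dv/dt = gamma (u_eff - v)  with constant
# u_eff = u_fluid + F_ext / gamma. Vectorised over particles/axes.
exp_step <- function(pos, vel, u_eff, tau, dt) {
  decay <- exp(-dt / tau)
  pos_new <- pos + u_eff * dt + (vel - u_eff) * tau * (1 - decay)
  vel_new <- u_eff + (vel - u_eff) * decay
  list(pos = pos_new, vel = vel_new)
}

#' Advance a particle by one time step
#'
#' One exponential (drag-exact) step of the Newtonian equation of motion
#' \eqn{d(m_p v)/dt = F_t}, where the total force is Stokes drag toward
#' `u_fluid` plus the constant external force `force`. With `drag_coef = 0`
#' the particle is free: position advances linearly and velocity changes by
#' `force / mass * dt`.
#'
#' @param position,velocity Numeric vectors (any number of axes).
#' @param mass Particle mass (kg).
#' @param force External (non-drag) force vector (N).
#' @param dt Time step (s), strictly positive.
#' @param drag_coef Stokes drag coefficient \eqn{6\pi\mu R_p} (N s/m).
#' @param u_fluid Local fluid velocity vector (m/s).
#' @return A list with updated `position` and `velocity`.
#' @export
#' @examples
#' # free particle: linear motion
#' step_particle(0, 1, 1e-12, 0, dt = 0.5)
step_particle <- function(position, velocity, mass, force, dt,
                          drag_coef = 0, u_fluid = 0) {
  if (dt <= 0) stop("dt must be strictly positive", call. = FALSE)
  if (drag_coef <= 0) {
    acc <- force / mass
    return(list(position = position + velocity * dt + 0.5 * acc * dt^2,
                velocity = velocity + acc * dt))
  }
  tau <- mass / drag_coef
  st <- exp_step(position, velocity, u_fluid + force / drag_coef, tau, dt)
  list(position = st$pos, velocity = st$vel)
}

# Specular bounce at the particle-radius inset planes: positions outside
# [lo, hi] are reflected and the normal velocity component is flipped.
# Returns updated (pos, vel); vectorised.
reflect_walls <- function(pos, vel, lo, hi) {
  below <- pos < lo
  above <- pos > hi
  pos[below] <- 2 * lo[below] - pos[below]
  pos[above] <- 2 * hi[above] - pos[above]
  vel[below | above] <- -vel[below | above]
  # a reflected position can still be outside after extreme steps: clamp
  pos <- pmin(pmax(pos, lo), hi)
  list(pos = pos, vel = vel)
}

# Linear interpolation of the crossing time/state when s passes s_target
# within a step.
crossing_fraction <- function(s_old, s_new, s_target) {
  (s_target - s_old) / (s_new - s_old)
}
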