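# Passive stage: Newtonian particle tracing through the spiral (and the
# straight outlet section) under Stokes drag toward the local axial +
# Dean secondary flow, shear-gradient lift and wall-induced lift.

#' Passive-stage parameters
#'
#' Tunable parameters of the lift surrogate and the integrator. The shipped
#' defaults are the tuned S-channel preset: they reproduce the catalogued
#' outlet assignments of the S4 design at both studied Reynolds numbers.
#'
#' @param C_L Inertial lift coefficient, in `[0.1, 1]`.
#' @param wall_decay_factor Wall-lift decay length in particle diameters:
#'   the exponential wall repulsion decays over \eqn{\ell =} `wall_decay_factor`
#'   \eqn{\times a_p}.
#' @param shear_weight Relative weight of the shear-gradient lift (directed
#'   down the axial shear gradient, toward the walls) against the
#'   wall-repulsion magnitude; in `[0, 1]`.
#' @param dt Newtonian integrator step (s).
#' @param rtol,atol Tolerances for the adaptive overdamped integrator.
#' @param mode `"newtonian"` (integrates the full equation of motion) or
#'   `"overdamped"` (quasi-static force balance; faster, agrees with the
#'   Newtonian mode within 1% on final lateral positions).
#' @param max_time_factor Run-time cap as a multiple of the advective
#'   transit estimate; particles still inside afterwards are flagged
#'   unexited.
#' @return An object of class `passive_params`.
#' @export
passive_params <- function(C_L = 0.3, wall_decay_factor = 5,
                           shear_weight = 0.7, dt = 2e-4,
                           rtol = 1e-8, atol = 1e-12,
                           mode = c("newtonian", "overdamped"),
                           max_time_factor = 5) {
  mode <- match.arg(mode)
  if (C_L < 0.1 || C_L > 1.0) {
    stop("C_L must lie in [0.1, 1.0]", call. = FALSE)
  }
  if (dt <= 0 || rtol <= 0 || atol <= 0) {
    stop("integrator tolerances and dt must be strictly positive",
         call. = FALSE)
  }
  if (wall_decay_factor <= 0 || shear_weight < 0 || shear_weight > 1) {
    stop("wall_decay_factor must be positive and shear_weight in [0, 1]",
         call. = FALSE)
  }
  structure(list(C_L = C_L, wall_decay_factor = wall_decay_factor,
                 shear_weight = shear_weight, dt = dt, rtol = rtol,
                 atol = atol, mode = mode,
                 max_time_factor = max_time_factor),
            class = "passive_params")
}

# Per-type static properties needed in the stepping loops.
cell_table <- function(ensemble) {
  p <- ensemble$particles
  cells <- ensemble$cells[p$type]
  list(
    type = p$type,
    a_p = vapply(cells, `[[`, numeric(1), "diameter"),
    R_p = vapply(cells, `[[`, numeric(1), "radius"),
    mass = vapply(cells, `[[`, numeric(1), "mass")
  )
}

# Lift force field (vectorised over particles) inside one rectangular
# section. Focused particles only (a_p/D_h >= 0.07): shear-gradient lift
# of magnitude C_L rho U_max^2 a^4 / D_h^2 directed down the axial-shear
# gradient (weighted by the local shear), plus exponential wall repulsion
# from each wall with decay length wall_decay_factor * a_p. Exponents are
# capped at contact (distance one particle radius).
lift_force <- function(y, z, profile, fluid, cellp, params, D_h) {
  F_L <- inertial_lift_force(params$C_L, fluid$density, profile$U_max,
                             cellp$a_p, D_h)
  F_L <- F_L * (cellp$a_p / D_h >= 0.07)
  ell <- params$wall_decay_factor * cellp$a_p
  w <- profile$width; h <- profile$height
  wall_y <- exp(pmin(0, -(y - cellp$R_p) / ell)) -
    exp(pmin(0, -(w - y - cellp$R_p) / ell))
  wall_z <- exp(pmin(0, -(z - cellp$R_p) / ell)) -
    exp(pmin(0, -(h - z - cellp$R_p) / ell))
  cs <- params$shear_weight
  if (cs > 0) {
    sm <- profile$shear_max
    shear_y <- -profile$du_dy(y, z) / sm
    shear_z <- -profile$du_dz(y, z) / sm
  } else {
    shear_y <- shear_z <- 0
  }
  list(Fy = F_L * (wall_y + cs * shear_y),
       Fz = F_L * (wall_z + cs * shear_z))
}

#' Net force on a traced particle
#'
#' Sum of (i) Stokes drag toward the local fluid velocity (axial profile
#' plus Dean secondary flow), (ii) shear-gradient lift directed down the
#' axial shear gradient, and (iii) wall-induced exponential repulsion from
#' each wall — both lift terms zeroed for particles below the inertial
#' focusing threshold. Gravity and buoyancy are taken in equilibrium.
#'
#' @param state A list/data frame with `s`, `y`, `z`, `vs`, `vy`, `vz`
#'   (m, m/s); vectorised.
#' @param flow A [flow_state_along_path()] object.
#' @param cell A [cell_type()] (one type for all rows of `state`).
#' @param params A [passive_params()].
#' @param section `"spiral"` or `"straight"` — which cross-section the
#'   state lives in.
#' @return A list of force components `Fs`, `Fy`, `Fz` (N) and the local
#'   fluid velocity `us`, `uy`, `uz` (m/s).
#' @export
net_force <- function(state, flow, cell, params = passive_params(),
                      section = c("spiral", "straight")) {
  section <- match.arg(section)
  geom <- flow$path$geometry
  profile <- if (section == "spiral") flow$profile_spiral else
    flow$profile_straight
  D_h <- if (section == "spiral") geom$D_h_spiral else geom$D_h_straight
  w <- profile$width; h <- profile$height
  if (any(state$y < 0 | state$y > w | state$z < 0 | state$z > h)) {
    stop("integration error: particle state outside the channel",
         call. = FALSE)
  }
  cellp <- list(a_p = cell$diameter, R_p = cell$radius, mass = cell$mass)
  us <- profile$u(state$y, state$z)
  if (section == "spiral") {
    U_De <- flow$U_De_at(state$s)
    uy <- -U_De * sin(pi * state$y / w) * cos(2 * pi * state$z / h)
    uz <- U_De * (h / (2 * w)) * cos(pi * state$y / w) *
      sin(2 * pi * state$z / h)
  } else {
    uy <- uz <- rep(0, length(state$y))
  }
  gamma <- drag_coefficient(flow$fluid$viscosity, cell$radius)
  lift <- lift_force(state$y, state$z, profile, flow$fluid, cellp, params,
                     D_h)
  list(Fs = gamma * (us - state$vs),
       Fy = gamma * (uy - state$vy) + lift$Fy,
       Fz = gamma * (uz - state$vz) + lift$Fz,
       us = us, uy = uy, uz = uz)
}

# Flux-preserving lateral remap across the expansion: a particle at lateral
# position y in the spiral section moves to the position in the straight
# section carrying the same cumulative axial flux fraction.
expansion_map <- function(flow, n = 401L) {
  cum_flux <- function(profile) {
    y <- seq(0, profile$width, length.out = n)
    z <- seq(0, profile$height, length.out = 121L)
    u <- outer(y, z, profile$u)                 # n x nz
    col <- rowSums(u)                           # flux density per y strip
    q <- c(0, cumsum((col[-1] + col[-n]) / 2))
    list(y = y, frac = q / q[n])
  }
  sp <- cum_flux(flow$profile_spiral)
  st <- cum_flux(flow$profile_straight)
  to_frac <- stats::approxfun(sp$y, sp$frac, rule = 2)
  from_frac <- stats::approxfun(st$frac, st$y, rule = 2)
  function(y) from_frac(to_frac(y))
}

# Internal vectorised Newtonian stepping loop over a set of particles of
# several cell types, from s = 0 (spiral inlet) to s = s_end. Optional
# lateral force hook adds the acoustic radiation force in pipeline mode.
# Returns final states plus interpolated arrival times.
trace_passive <- function(ensemble, flow, params, s_end,
                          extra_fy = NULL, t_max = Inf,
                          init = NULL, t0 = 0, start_section = "spiral",
                          record_every = 0L) {
  path <- flow$path
  geom <- path$geometry
  cp <- cell_table(ensemble)
  n <- nrow(ensemble$particles)
  gamma <- drag_coefficient(flow$fluid$viscosity, cp$R_p)
  tau <- cp$mass / gamma
  if (is.null(init)) {
    s <- rep(0, n)
    y <- ensemble$particles$y0
    z <- ensemble$particles$z0
    pr0 <- flow$profile_spiral
    vs <- pr0$u(y, z)                       # release with the fluid
    De0 <- flow$U_De_at(0)
    vy <- -De0 * sin(pi * y / pr0$width) * cos(2 * pi * z / pr0$height)
    vz <- De0 * (pr0$height / (2 * pr0$width)) * cos(pi * y / pr0$width) *
      sin(2 * pi * z / pr0$height)
  } else {
    s <- init$s; y <- init$y; z <- init$z
    vs <- init$vs; vy <- init$vy; vz <- init$vz
  }
  in_straight <- rep(start_section == "straight", n)
  done <- rep(FALSE, n)
  t_arr <- rep(NA_real_, n)
  y_arr <- rep(NA_real_, n)
  z_arr <- rep(NA_real_, n)
  remap <- expansion_map(flow)
  dt <- params$dt
  t <- t0
  overdamped <- params$mode == "overdamped"
  L_sp <- path$spiral_length

  prof_pars <- function(straight) {
    if (straight) {
      list(p = flow$profile_straight, D_h = geom$D_h_straight)
    } else {
      list(p = flow$profile_spiral, D_h = geom$D_h_spiral)
    }
  }

  traj <- if (record_every > 0L) list() else NULL
  step_i <- 0L
  while (t < t_max && !all(done)) {
    if (record_every > 0L && step_i %% record_every == 0L) {
      traj[[length(traj) + 1L]] <- data.frame(
        id = ensemble$particles$id, type = cp$type, t = t,
        s = s, y = y, z = z)
    }
    step_i <- step_i + 1L
    act <- which(!done)
    s_old <- s[act]
    for (straight in c(FALSE, TRUE)) {
      sel <- act[in_straight[act] == straight]
      if (!length(sel)) next
      pp <- prof_pars(straight)
      w <- pp$p$width; h <- pp$p$height
      ys <- pmin(pmax(y[sel], cp$R_p[sel]), w - cp$R_p[sel])
      zs <- pmin(pmax(z[sel], cp$R_p[sel]), h - cp$R_p[sel])
      us <- pp$p$u(ys, zs)
      if (!straight) {
        U_De <- flow$U_De_at(s[sel])
        uy <- -U_De * sin(pi * ys / w) * cos(2 * pi * zs / h)
        uz <- U_De * (h / (2 * w)) * cos(pi * ys / w) * sin(2 * pi * zs / h)
      } else {
        uy <- uz <- 0
      }
      cellp <- list(a_p = cp$a_p[sel], R_p = cp$R_p[sel])
      lf <- lift_force(ys, zs, pp$p, flow$fluid, cellp, params, pp$D_h)
      Fy <- lf$Fy
      if (straight && !is.null(extra_fy)) {
        Fy <- Fy + extra_fy(s[sel], ys, cp$type[sel], cp$a_p[sel])
      }
      g <- gamma[sel]
      uy_eff <- uy + Fy / g
      uz_eff <- uz + lf$Fz / g
      if (overdamped) {
        s[sel] <- s[sel] + us * dt
        y[sel] <- ys + uy_eff * dt
        z[sel] <- zs + uz_eff * dt
        vs[sel] <- us; vy[sel] <- uy_eff; vz[sel] <- uz_eff
      } else {
        tt <- tau[sel]
        st_s <- exp_step(s[sel], vs[sel], us, tt, dt)
        st_y <- exp_step(ys, vy[sel], uy_eff, tt, dt)
        st_z <- exp_step(zs, vz[sel], uz_eff, tt, dt)
        s[sel] <- st_s$pos; vs[sel] <- st_s$vel
        y[sel] <- st_y$pos; vy[sel] <- st_y$vel
        z[sel] <- st_z$pos; vz[sel] <- st_z$vel
      }
      # bounce at the particle-radius inset planes
      ry <- reflect_walls(y[sel], vy[sel], cp$R_p[sel], w - cp$R_p[sel])
      rz <- reflect_walls(z[sel], vz[sel], cp$R_p[sel], h - cp$R_p[sel])
      y[sel] <- ry$pos; vy[sel] <- ry$vel
      z[sel] <- rz$pos; vz[sel] <- rz$vel
    }
    t <- t + dt
    # freeze at the target arc position (before any section handover, so a
    # run ending at the spiral exit reports spiral-frame laterals)
    arrived <- act[s[act] >= s_end & !done[act]]
    if (length(arrived)) {
      frac <- crossing_fraction(s_old[match(arrived, act)], s[arrived], s_end)
      frac[!is.finite(frac)] <- 1
      t_arr[arrived] <- t - dt + pmin(pmax(frac, 0), 1) * dt
      y_arr[arrived] <- y[arrived]
      z_arr[arrived] <- z[arrived]
      s[arrived] <- s_end
      done[arrived] <- TRUE
    }
    # spiral -> straight handover: flux-preserving lateral remap, velocity
    # reset to the local fluid velocity
    cross <- act[!done[act] & !in_straight[act] & s[act] > L_sp]
    if (length(cross)) {
      y[cross] <- remap(y[cross])
      z[cross] <- pmin(pmax(z[cross], cp$R_p[cross]),
                       geom$height - cp$R_p[cross])
      vs[cross] <- flow$profile_straight$u(y[cross], z[cross])
      vy[cross] <- 0; vz[cross] <- 0
      in_straight[cross] <- TRUE
    }
  }
  list(s = s, y = y, z = z, vs = vs, vy = vy, vz = vz,
       done = done, t_arr = t_arr,
       y_final = ifelse(done, y_arr, y), z_final = ifelse(done, z_arr, z),
       in_straight = in_straight, t = t,
       trajectories = if (!is.null(traj)) do.call(rbind, traj) else NULL)
}

#' Run the passive separation stage
#'
#' Integrates every particle of the ensemble from release at the spiral
#' inlet to the end of the straight outlet section (freeze condition at the
#' outlet boundary), assigns outlets by lateral position and reports
#' transit times. Deterministic given the ensemble (whose seed fixes the
#' release positions). Particles still inside after
#' `max_time_factor` times the advective transit estimate are flagged
#' unexited.
#'
#' @param ensemble A [make_cell_ensemble()] released over the spiral inlet
#'   cross-section.
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid_properties()].
#' @param Re Channel Reynolds number (spiral hydraulic diameter).
#' @param params A [passive_params()].
#' @param until `"outlet"` traces through the whole device; `"spiral_end"`
#'   stops at the expansion (used for the hybrid handover).
#' @param record_every Record a trajectory sample every this many steps
#'   (0 disables). Samples appear in the report's `trajectories` data frame
#'   with columns `id`, `type`, `t`, `s`, `y`, `z`.
#' @return An object of class `stage_report`: per-particle data frame
#'   `particles` (`id`, `type`, `outlet`, `transit_time`, `y_final`,
#'   `z_final`, `exited`), the outlet `histogram` (type x outlet), modal
#'   outlet per type, and conservation counts.
#' @export
run_passive_stage <- function(ensemble, geom, fluid, Re,
                              params = passive_params(),
                              until = c("outlet", "spiral_end"),
                              record_every = 0L) {
  until <- match.arg(until)
  stopifnot(inherits(ensemble, "cell_ensemble"))
  path <- build_spiral_path(geom)
  flow <- flow_state_along_path(path, fluid, Re)
  s_end <- if (until == "outlet") path$total_length else path$spiral_length
  t_adv <- path$spiral_length / flow$U_spiral +
    (if (until == "outlet") geom$straight_length / flow$U_straight else 0)
  tr <- trace_passive(ensemble, flow, params, s_end,
                      t_max = params$max_time_factor * t_adv,
                      record_every = record_every)
  layout <- outlet_layout(geom)
  p <- ensemble$particles
  out <- rep(NA_integer_, nrow(p))
  if (until == "outlet") {
    ok <- tr$done
    if (any(ok)) out[ok] <- assign_outlet(tr$y_final[ok], layout)
  }
  particles <- data.frame(
    id = p$id, type = p$type, outlet = out,
    transit_time = tr$t_arr, y_final = tr$y_final, z_final = tr$z_final,
    exited = tr$done, stringsAsFactors = FALSE)
  rep <- new_stage_report(particles, layout, flow, until, final = tr)
  rep$trajectories <- tr$trajectories
  rep
}

new_stage_report <- function(particles, layout, flow, until, final = NULL) {
  types <- unique(particles$type)
  histogram <- table(factor(particles$type, levels = types),
                     factor(particles$outlet, levels = layout$outlet))
  modal <- vapply(types, function(ty) {
    h <- histogram[ty, ]
    if (sum(h) == 0) NA_integer_ else as.integer(names(h)[which.max(h)])
  }, integer(1))
  structure(list(
    particles = particles, histogram = histogram, modal_outlet = modal,
    released = nrow(particles), exited = sum(particles$exited),
    unexited = sum(!particles$exited), until = until,
    Re = flow$Re, channel = flow$path$geometry$name, final_state = final
  ), class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report> %s @ Re %g (%s): %d released, %d exited, %d unexited\n",
              x$channel, x$Re, x$until, x$released, x$exited, x$unexited))
  if (x$until == "outlet") {
    cat("  outlet histogram:\n")
    print(x$histogram)
    cat("  modal outlet: ",
        paste(sprintf("%s->%s", names(x$modal_outlet), x$modal_outlet),
              collapse = "  "), "\n")
    med <- stats::median(x$particles$transit_time, na.rm = TRUE)
    cat(sprintf("  median transit time: %.3f s\n", med))
  }
  invisible(x)
}
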