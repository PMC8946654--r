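# Config-driven orchestration: passive -> active with reports and
# reproducibility metadata.

#' Run configuration
#'
#' A run configuration fully determines a simulation: channel, fluid, flow,
#' cells, stage parameters and seed. Values are validated before any
#' computation.
#'
#' @param channel Channel preset name (`"S1"`..`"S4"`) or a
#'   [channel_geometry()].
#' @param Re Channel Reynolds number (0 for a zero-flow active run).
#' @param counts Named cell counts per type.
#' @param placement Release placement, see [make_cell_ensemble()].
#' @param seed Integer seed.
#' @param stage `"passive"`, `"active"` or `"hybrid"`.
#' @param fluid A [fluid_properties()].
#' @param passive A [passive_params()].
#' @param active A [active_params()].
#' @param p_0,frequency,transducer_length Acoustic drive settings, see
#'   [acoustic_field()].
#' @param duration Active-stage duration (s), standalone mode.
#' @param cell_compressibility Compressibility assigned to all cell
#'   presets (1/Pa).
#' @param name Optional label.
#' @return An object of class `run_config`.
#' @export
run_config <- function(channel = "S4", Re = 40,
                       counts = c(CTC = 50, WBC = 50, RBC = 50),
                       placement = "uniform", seed = 42L,
                       stage = c("hybrid", "passive", "active"),
                       fluid = fluid_properties(),
                       passive = passive_params(),
                       active = active_params(),
                       p_0 = 1.8e5, frequency = 3.3e6,
                       transducer_length = 5e-3,
                       duration = 3,
                       cell_compressibility = 4.0e-10,
                       name = NULL) {
  stage <- match.arg(stage)
  geom <- if (inherits(channel, "channel_geometry")) channel else
    build_channel(channel)
  if (Re < 0) stop("Re must be non-negative", call. = FALSE)
  if (stage != "active" && Re == 0) {
    stop("passive/hybrid runs need Re > 0", call. = FALSE)
  }
  structure(list(
    name = name %||% geom$name, channel = geom, Re = Re,
    counts = counts, placement = placement, seed = as.integer(seed),
    stage = stage, fluid = fluid, passive = passive, active = active,
    p_0 = p_0, frequency = frequency,
    transducer_length = transducer_length, duration = duration,
    cell_compressibility = cell_compressibility
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s: %s stage, %s @ Re %g, %d cells, seed %d\n",
              x$name, x$stage, x$channel$name, x$Re, sum(x$counts), x$seed))
  invisible(x)
}

config_field <- function(cfg, field) cfg[[field]]

ensemble_from_config <- function(config) {
  geom <- config$channel
  cells <- lapply(names(config$counts), cell_preset,
                  compressibility = config$cell_compressibility)
  names(cells) <- names(config$counts)
  if (config$stage == "active") {
    make_cell_ensemble(config$counts, geom$straight_width, geom$height,
                       placement = if (config$placement == "uniform")
                         "uniform" else "grid",
                       seed = config$seed, cells = cells)
  } else {
    make_cell_ensemble(config$counts, geom$spiral_width, geom$height,
                       placement = config$placement, seed = config$seed,
                       cells = cells)
  }
}

acoustic_field_from_config <- function(config) {
  acoustic_field(p_0 = config$p_0, frequency = config$frequency,
                 sound_speed = config$fluid$sound_speed,
                 width = config$channel$straight_width,
                 transducer_length = config$transducer_length)
}

#' Run the hybrid pipeline
#'
#' Passive stage through the spiral, flux-preserving handover across the
#' expansion, then the straight outlet section with the standing-wave
#' radiation force active over the transducer span (the final
#' `transducer_length` of the section; the remainder is force-free).
#' Rerunning with an identical config and seed gives an identical report.
#'
#' @param config A [run_config()] (stage `"hybrid"`).
#' @return An object of class `hybrid_report`: the per-stage reports, the
#'   outlet histogram per cell type, the separation-success flag (every
#'   cell type has a unique modal outlet), nearest-node distances at the
#'   outlets, the config echo and package version.
#' @export
run_hybrid_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  geom <- config$channel
  ensemble <- ensemble_from_config(config)
  path <- build_spiral_path(geom)
  flow <- flow_state_along_path(path, config$fluid, config$Re)
  field <- acoustic_field_from_config(config)
  nodes <- nodal_positions(field)

  # stage 1: spiral (passive)
  t_adv_sp <- path$spiral_length / flow$U_spiral
  tr1 <- trace_passive(ensemble, flow, config$passive, path$spiral_length,
                       t_max = config$passive$max_time_factor * t_adv_sp)
  # handover: remap laterals of particles that reached the spiral end
  remap <- expansion_map(flow)
  cp <- cell_table(ensemble)
  y2 <- ifelse(tr1$done, remap(tr1$y_final), tr1$y_final)
  y2 <- pmin(pmax(y2, cp$R_p), geom$straight_width - cp$R_p)
  z2 <- pmin(pmax(tr1$z_final, cp$R_p), geom$height - cp$R_p)
  init <- list(s = rep(path$spiral_length, nrow(ensemble$particles)),
               y = y2, z = z2,
               vs = flow$profile_straight$u(y2, z2),
               vy = rep(0, length(y2)), vz = rep(0, length(y2)))

  # stage 2: straight section with the radiation force over the
  # transducer span next to the outlets
  fluidc <- config$fluid
  phi <- vapply(ensemble$cells, function(cl)
    acoustic_contrast_factor(cl$density, fluidc$density,
                             cl$compressibility, fluidc$compressibility),
    numeric(1))
  k <- field$wavenumber
  s_on <- path$total_length - field$transducer_length
  famp_of <- function(a_p, type) {
    pi * field$p_0^2 * (pi * a_p^3 / 6) * fluidc$compressibility /
      (2 * field$wavelength) * phi[type]
  }
  extra_fy <- function(s, y, type, a_p) {
    on <- s >= s_on
    -famp_of(a_p, type) * sin(2 * k * (y - field$y_mid)) * on
  }
  t_adv <- t_adv_sp + geom$straight_length / flow$U_straight
  tr2 <- trace_passive(ensemble, flow, config$passive, path$total_length,
                       extra_fy = extra_fy,
                       t_max = config$passive$max_time_factor * t_adv,
                       init = init, t0 = 0, start_section = "straight")

  layout <- outlet_layout(geom)
  p <- ensemble$particles
  out <- rep(NA_integer_, nrow(p))
  out[tr2$done] <- assign_outlet(tr2$y_final[tr2$done], layout)
  node_idx <- vapply(tr2$y_final,
                     function(yi) which.min(abs(nodes - yi)), integer(1))
  node_dist <- abs(tr2$y_final - nodes[node_idx])
  particles <- data.frame(
    id = p$id, type = p$type, outlet = out,
    spiral_time = tr1$t_arr, transit_time = tr2$t_arr,
    y_final = tr2$y_final, z_final = tr2$z_final,
    node = node_idx, node_distance = node_dist,
    trapped = node_dist <= config$active$tol,
    exited = tr2$done, stringsAsFactors = FALSE)
  types <- unique(particles$type)
  histogram <- table(factor(particles$type, levels = types),
                     factor(particles$outlet, levels = layout$outlet))
  modal <- vapply(types, function(ty) {
    h <- histogram[ty, ]
    if (sum(h) == 0) NA_integer_ else as.integer(names(h)[which.max(h)])
  }, integer(1))
  mo <- modal[!is.na(modal)]
  success <- length(mo) == length(types) && !anyDuplicated(mo)
  structure(list(
    particles = particles, histogram = histogram, modal_outlet = modal,
    separation_success = success, nodes = nodes,
    released = nrow(particles), exited = sum(particles$exited),
    unexited = sum(!particles$exited),
    config = config, package_version =
      as.character(utils::packageVersion("spiralsaw")),
    wall_clock = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "hybrid_report")
}

#' @export
print.hybrid_report <- function(x, ...) {
  cat(sprintf("<hybrid_report> %s @ Re %g: %d released, %d exited\n",
              x$config$channel$name, x$config$Re, x$released, x$exited))
  print(x$histogram)
  cat("  modal outlet: ",
      paste(sprintf("%s->%s", names(x$modal_outlet), x$modal_outlet),
            collapse = "  "), "\n")
  cat(sprintf("  separation success: %s\n", x$separation_success))
  invisible(x)
}

#' Derived design quantities for a configuration
#'
#' Recomputes, from the closed-form relations, the quantities that
#' characterise a device design: hydraulic diameters, mean and peak
#' velocities per section, the Dean number and Dean velocity range along
#' the spiral, the inertial focusing threshold diameter, the acoustic
#' wavelength and the nodal-line positions.
#'
#' @param config A [run_config()].
#' @return A list of class `design_summary`.
#' @export
#' @examples
#' design_summary(device_fixture("S4@Re40"))
design_summary <- function(config) {
  stopifnot(inherits(config, "run_config"))
  geom <- config$channel
  fluid <- config$fluid
  path <- build_spiral_path(geom)
  field <- acoustic_field_from_config(config)
  res <- list(
    channel = geom$name, Re = config$Re,
    D_h_spiral = geom$D_h_spiral, D_h_straight = geom$D_h_straight,
    threshold_diameter_spiral = threshold_diameter(geom$D_h_spiral),
    threshold_diameter_straight = threshold_diameter(geom$D_h_straight),
    spiral_length = path$spiral_length,
    total_length = path$total_length,
    wavelength = field$wavelength,
    nodes = nodal_positions(field)
  )
  if (config$Re > 0) {
    flow <- flow_state_along_path(path, fluid, config$Re)
    De <- flow$De_at(c(path$spiral_length * 0.999999, 0))
    res <- c(res, list(
      U_spiral = flow$U_spiral, U_straight = flow$U_straight,
      U_max_spiral = flow$profile_spiral$U_max,
      U_max_straight = flow$profile_straight$U_max,
      De_range = sort(De), U_De_range = sort(dean_velocity(De))
    ))
  }
  class(res) <- "design_summary"
  res
}

#' @export
print.design_summary <- function(x, ...) {
  um <- function(v) sprintf("%.1f um", v * 1e6)
  cat(sprintf("<design_summary> %s\n", x$channel))
  cat(sprintf("  D_h: spiral %s, straight %s\n",
              um(x$D_h_spiral), um(x$D_h_straight)))
  cat(sprintf("  focusing threshold diameter: spiral %s, straight %s\n",
              um(x$threshold_diameter_spiral),
              um(x$threshold_diameter_straight)))
  cat(sprintf("  path: spiral %.2f mm, total %.2f mm\n",
              x$spiral_length * 1e3, x$total_length * 1e3))
  if (!is.null(x$U_spiral)) {
    cat(sprintf("  Re %g: U %.4f / %.4f m/s, U_max %.4f / %.4f m/s (spiral/straight)\n",
                x$Re, x$U_spiral, x$U_straight, x$U_max_spiral,
                x$U_max_straight))
    cat(sprintf("  De %.2f-%.2f, U_De %.3g-%.3g m/s along the spiral\n",
                x$De_range[1], x$De_range[2],
                x$U_De_range[1], x$U_De_range[2]))
  }
  cat(sprintf("  acoustic wavelength %.1f um; nodes at %s\n",
              x$wavelength * 1e6,
              paste(sprintf("%.1f", x$nodes * 1e6), collapse = ", ")))
  invisible(x)
}

#' Write a report as JSON
#'
#' Serialises a [run_hybrid_pipeline()] or [run_passive_stage()] report.
#' Wall-clock metadata is excluded so identical runs produce byte-identical
#' files.
#'
#' @param report A `hybrid_report` or `stage_report`.
#' @param path Output file.
#' @param include_wall_clock Include timing metadata (breaks byte
#'   determinism).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, include_wall_clock = FALSE) {
  x <- report_as_list(report)
  if (!include_wall_clock) x$wall_clock <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

report_as_list <- function(report) {
  if (inherits(report, "hybrid_report")) {
    list(
      schema = "spiralsaw/hybrid-report/v1",
      channel = report$config$channel$name, Re = report$config$Re,
      seed = report$config$seed,
      released = report$released, exited = report$exited,
      unexited = report$unexited,
      modal_outlet = as.list(report$modal_outlet),
      separation_success = report$separation_success,
      histogram = apply(report$histogram, 1, as.list, simplify = FALSE),
      nodes_um = report$nodes * 1e6,
      wall_clock = report$wall_clock,
      package_version = report$package_version,
      particles = report$particles
    )
  } else if (inherits(report, "stage_report")) {
    list(
      schema = "spiralsaw/stage-report/v1",
      channel = report$channel, Re = report$Re, until = report$until,
      released = report$released, exited = report$exited,
      unexited = report$unexited,
      modal_outlet = as.list(report$modal_outlet),
      median_transit_time =
        stats::median(report$particles$transit_time, na.rm = TRUE),
      histogram = apply(report$histogram, 1, as.list, simplify = FALSE),
      particles = report$particles
    )
  } else {
    stop("unsupported report class", call. = FALSE)
  }
}
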