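# Structured config files (YAML) with explicit unit suffixes.

unit_table <- c(
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "nm" = 1e-9,
  "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
  "s" = 1, "ms" = 1e-3,
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6,
  "m/s" = 1, "mm/s" = 1e-3,
  "kg/m3" = 1, "Pa.s" = 1, "1/Pa" = 1
)

#' Parse a quantity with an explicit unit suffix
#'
#' Accepts strings such as `"500 um"`, `"3.3 MHz"`, `"5 mm"`, `"1.8e5 Pa"`
#' and converts them to SI. Bare numbers pass through unchanged.
#'
#' @param x A number or a string with a unit suffix.
#' @return The value in SI units.
#' @export
#' @examples
#' parse_quantity("3.3 MHz") # 3.3e6
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([A-Za-z/.0-9]*)\\s*$", x))[[1]]
  if (length(m) != 3 || !nzchar(m[2])) {
    stop(sprintf("cannot parse quantity '%s'", x), call. = FALSE)
  }
  val <- as.numeric(m[2])
  if (is.na(val)) stop(sprintf("cannot parse quantity '%s'", x),
                       call. = FALSE)
  if (!nzchar(m[3])) return(val)
  if (!m[3] %in% names(unit_table)) {
    stop(sprintf("unknown unit '%s'", m[3]), call. = FALSE)
  }
  val * unit_table[[m[3]]]
}

#' Write a run configuration to a YAML file
#'
#' Scalar physical quantities are written with explicit unit suffixes so
#' the file round-trips through [read_run_config()] unchanged.
#'
#' @param config A [run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  g <- config$channel
  x <- list(
    name = config$name,
    stage = config$stage,
    channel = list(
      name = g$name,
      spiral_width = sprintf("%g um", g$spiral_width * 1e6),
      straight_width = sprintf("%g um", g$straight_width * 1e6),
      height = sprintf("%g um", g$height * 1e6),
      first_radius = sprintf("%g mm", g$first_radius * 1e3),
      loops = g$loops,
      gap = sprintf("%g um", g$gap * 1e6),
      straight_length = sprintf("%g mm", g$straight_length * 1e3),
      n_outlets = g$n_outlets,
      outlet_width = sprintf("%g um", g$outlet_width * 1e6)
    ),
    Re = config$Re,
    counts = as.list(config$counts),
    placement = config$placement,
    seed = config$seed,
    fluid = list(
      density = config$fluid$density,
      viscosity = config$fluid$viscosity,
      sound_speed = config$fluid$sound_speed,
      compressibility = config$fluid$compressibility
    ),
    passive = unclass(config$passive),
    active = unclass(config$active),
    p_0 = sprintf("%g Pa", config$p_0),
    frequency = sprintf("%g MHz", config$frequency / 1e6),
    transducer_length = sprintf("%g mm", config$transducer_length * 1e3),
    duration = sprintf("%g s", config$duration),
    cell_compressibility = config$cell_compressibility
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path A file written by [write_run_config()] (or hand-authored in
#'   the same schema; quantities may carry unit suffixes).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  ch <- x$channel
  geom <- channel_geometry(
    name = ch$name,
    spiral_width = parse_quantity(ch$spiral_width),
    straight_width = parse_quantity(ch$straight_width),
    height = parse_quantity(ch$height),
    first_radius = parse_quantity(ch$first_radius),
    loops = ch$loops,
    gap = parse_quantity(ch$gap),
    straight_length = parse_quantity(ch$straight_length),
    n_outlets = ch$n_outlets,
    outlet_width = parse_quantity(ch$outlet_width)
  )
  run_config(
    channel = geom, Re = x$Re,
    counts = unlist(x$counts), placement = x$placement, seed = x$seed,
    stage = x$stage,
    fluid = fluid_properties(x$fluid$density, x$fluid$viscosity,
                             x$fluid$sound_speed, x$fluid$compressibility),
    passive = do.call(passive_params, x$passive),
    active = do.call(active_params, x$active),
    p_0 = parse_quantity(x$p_0),
    frequency = parse_quantity(x$frequency),
    transducer_length = parse_quantity(x$transducer_length),
    duration = parse_quantity(x$duration),
    cell_compressibility = x$cell_compressibility,
    name = x$name
  )
}
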