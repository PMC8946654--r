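# Channel geometry: two-loop spiral + expansion + straight outlet section,
# and the five-outlet lateral layout.

#' Channel geometry
#'
#' Construct the geometry of a two-loop spiral device: a spiral section of
#' width `spiral_width`, an abrupt expansion to `straight_width`, and a
#' straight outlet section of length `straight_length` carrying five
#' equally spaced outlets. The four catalogued designs S1-S4 share all
#' dimensions except the channel height (100 or 70 um) and the radius of the
#' first spiral (10 or 5 mm); use [build_channel()] for those presets.
#'
#' @param name Label for the design.
#' @param spiral_width Channel width along the spiral (m).
#' @param straight_width Channel width in the straight outlet section (m).
#' @param height Channel height (m), common to both sections.
#' @param first_radius Centerline radius at the spiral inlet (m).
#' @param loops Number of spiral turns.
#' @param gap Wall-to-wall distance between successive spiral loops (m).
#' @param straight_length Length of the straight outlet section (m).
#' @param n_outlets Number of outlets.
#' @param outlet_width Width of each outlet (m).
#' @return An object of class `channel_geometry`, with derived hydraulic
#'   diameters `D_h_spiral` and `D_h_straight`.
#' @export
channel_geometry <- function(name = "custom",
                             spiral_width = 500e-6,
                             straight_width = 1e-3,
                             height = 100e-6,
                             first_radius = 10e-3,
                             loops = 2,
                             gap = 500e-6,
                             straight_length = 8e-3,
                             n_outlets = 5L,
                             outlet_width = 120e-6) {
  lens <- c(spiral_width, straight_width, height, first_radius, gap,
            straight_length, outlet_width)
  if (any(!is.finite(lens)) || any(lens <= 0) || loops < 1) {
    stop("invalid geometry: all dimensions must be strictly positive",
         call. = FALSE)
  }
  if (straight_width <= spiral_width) {
    stop("invalid geometry: straight_width must exceed spiral_width",
         call. = FALSE)
  }
  if (n_outlets * outlet_width > straight_width) {
    stop("invalid geometry: outlets wider than the straight section",
         call. = FALSE)
  }
  g <- list(
    name = name,
    spiral_width = spiral_width,
    straight_width = straight_width,
    height = height,
    first_radius = first_radius,
    loops = loops,
    gap = gap,
    pitch = spiral_width + gap,   # centerline pitch per turn
    straight_length = straight_length,
    n_outlets = as.integer(n_outlets),
    outlet_width = outlet_width,
    D_h_spiral = hydraulic_diameter(spiral_width, height),
    D_h_straight = hydraulic_diameter(straight_width, height)
  )
  structure(g, class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %s\n", x$name))
  cat(sprintf("  spiral:   w=%g um, h=%g um, r_x=%g mm, %d loops, pitch=%g mm (D_h=%.2f um)\n",
              x$spiral_width * 1e6, x$height * 1e6, x$first_radius * 1e3,
              x$loops, x$pitch * 1e3, x$D_h_spiral * 1e6))
  cat(sprintf("  straight: w=%g mm, L=%g mm (D_h=%.2f um), %d outlets x %g um\n",
              x$straight_width * 1e3, x$straight_length * 1e3,
              x$D_h_straight * 1e6, x$n_outlets, x$outlet_width * 1e6))
  invisible(x)
}

#' Build a channel from a catalogued preset or explicit dimensions
#'
#' @param preset One of `"S1"`, `"S2"`, `"S3"`, `"S4"`, or `NULL` to pass
#'   explicit dimensions through `...`.
#' @param ... Arguments forwarded to [channel_geometry()] (override preset
#'   values when both are given).
#' @return A [channel_geometry()].
#' @export
#' @examples
#' build_channel("S4") # h = 70 um, first radius 5 mm
build_channel <- function(preset = NULL, ...) {
  if (is.null(preset)) return(channel_geometry(...))
  key <- toupper(preset)
  base <- switch(key,
    S1 = list(height = 100e-6, first_radius = 10e-3),
    S2 = list(height = 100e-6, first_radius = 5e-3),
    S3 = list(height = 70e-6,  first_radius = 10e-3),
    S4 = list(height = 70e-6,  first_radius = 5e-3),
    stop(sprintf("unknown channel preset '%s'", preset), call. = FALSE))
  args <- utils::modifyList(c(list(name = key), base), list(...))
  do.call(channel_geometry, args)
}

#' Centerline path parametrization
#'
#' Arc-length parametrization of the device centerline: an Archimedean
#' spiral from radius `first_radius` to `first_radius + loops * pitch`,
#' followed by the straight outlet section. The spiral is traversed
#' outward (flow enters at the inner end).
#'
#' @param geom A [channel_geometry()].
#' @param n Number of quadrature samples along the spiral used to build the
#'   arc-length <-> angle lookup (path length is invariant to `n` well below
#'   1e-6 relative).
#' @return An object of class `spiral_path` with fields `spiral_length`,
#'   `total_length` and vectorised samplers `radius_at(s)` (local curvature
#'   radius, `Inf` on the straight section), `width_at(s)` and
#'   `section_at(s)` (`"spiral"` or `"straight"`).
#' @export
build_spiral_path <- function(geom, n = 4096L) {
  stopifnot(inherits(geom, "channel_geometry"))
  b <- geom$pitch / (2 * pi)             # radial growth per radian
  theta_end <- geom$loops * 2 * pi
  theta <- seq(0, theta_end, length.out = n)
  r <- geom$first_radius + b * theta
  # exact Archimedean arc-length integrand, integrated cumulatively
  integrand <- sqrt(r^2 + b^2)
  ds <- diff(theta) * (integrand[-1] + integrand[-n]) / 2
  s_grid <- c(0, cumsum(ds))
  spiral_length <- s_grid[n]
  total_length <- spiral_length + geom$straight_length
  theta_of_s <- stats::approxfun(s_grid, theta, rule = 2)

  radius_at <- function(s) {
    th <- theta_of_s(pmin(s, spiral_length))
    rr <- geom$first_radius + b * th
    # curvature radius of the Archimedean spiral
    R <- (rr^2 + b^2)^1.5 / (rr^2 + 2 * b^2)
    R[s > spiral_length] <- Inf
    R
  }
  width_at <- function(s) {
    ifelse(s <= spiral_length, geom$spiral_width, geom$straight_width)
  }
  section_at <- function(s) {
    ifelse(s <= spiral_length, "spiral", "straight")
  }
  structure(list(
    geometry = geom,
    spiral_length = spiral_length,
    total_length = total_length,
    radius_at = radius_at,
    width_at = width_at,
    section_at = section_at
  ), class = "spiral_path")
}

#' @export
print.spiral_path <- function(x, ...) {
  cat(sprintf("<spiral_path> %s: spiral %.2f mm + straight %.2f mm = %.2f mm\n",
              x$geometry$name, x$spiral_length * 1e3,
              x$geometry$straight_length * 1e3, x$total_length * 1e3))
  invisible(x)
}

#' Export a sampled path as a data frame
#'
#' @param path A [build_spiral_path()] result.
#' @param n Number of samples.
#' @return A data frame with columns `s`, `R`, `section`, `width` suitable
#'   for CSV export or plotting.
#' @export
path_profile <- function(path, n = 500L) {
  s <- seq(0, path$total_length, length.out = n)
  data.frame(s = s, R = path$radius_at(s), section = path$section_at(s),
             width = path$width_at(s))
}

#' Outlet layout across the straight-section width
#'
#' The five outlets span the width edge-to-edge with equal internal gaps:
#' for the default 1 mm width and 120 um outlets the intervals are
#' \[0,120\], \[220,340\], \[440,560\], \[660,780\], \[880,1000\] um.
#' Outlet 1 sits at the spiral's inner-wall side (y = 0).
#'
#' @param geom A [channel_geometry()].
#' @return A data frame with columns `outlet`, `lower`, `upper`, `center` (m).
#' @export
outlet_layout <- function(geom) {
  stopifnot(inherits(geom, "channel_geometry"))
  n <- geom$n_outlets
  wo <- geom$outlet_width
  gap <- (geom$straight_width - n * wo) / (n - 1)
  lower <- (seq_len(n) - 1) * (wo + gap)
  data.frame(outlet = seq_len(n), lower = lower, upper = lower + wo,
             center = lower + wo / 2)
}

#' Assign a lateral position to an outlet
#'
#' Positions inside an outlet interval map to that outlet; positions in a
#' gap map to the nearest outlet center, ties going to the lower index.
#'
#' @param y Lateral position(s) (m), in `[0, straight_width]`.
#' @param layout An [outlet_layout()] data frame.
#' @return Integer outlet indices.
#' @export
#' @examples
#' geom <- build_channel("S4")
#' assign_outlet(500e-6, outlet_layout(geom)) # 3
assign_outlet <- function(y, layout) {
  w_t <- layout$upper[nrow(layout)]
  if (any(y < -1e-12) || any(y > w_t + 1e-12)) {
    stop("lateral position outside the channel", call. = FALSE)
  }
  vapply(y, function(yi) {
    inside <- which(yi >= layout$lower & yi <= layout$upper)
    if (length(inside)) return(as.integer(inside[1]))
    d <- abs(layout$center - yi)
    as.integer(which(d <= min(d) + 1e-15)[1])  # tie -> lower index
  }, integer(1))
}
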