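# Seeded cell ensembles and run fixtures: every stage is testable without
# any external data.

#' Generate a seeded cell ensemble
#'
#' Places cells of each type in a rectangular cross-section (the release
#' plane), inset from every wall by one particle radius. `"uniform"`
#' placement emulates release from the common inlet; `"grid"` emulates a
#' mesh-based initialisation (a near-square lattice over the admissible
#' area); `"point"` releases all cells of a type at the section center.
#' Regeneration with the same seed is bit-identical.
#'
#' @param counts Named integer vector, e.g. `c(CTC = 50, WBC = 50, RBC = 50)`.
#'   Names must be cell presets understood by [cell_preset()].
#' @param width,height Cross-section dimensions of the release plane (m).
#' @param placement One of `"uniform"`, `"grid"`, `"point"`.
#' @param seed Integer seed (only `"uniform"` consumes randomness, but the
#'   seed is recorded for provenance in all cases).
#' @param cells Optional named list of [cell_type()] objects overriding the
#'   presets (e.g. to change compressibility).
#' @return An object of class `cell_ensemble`: a data frame `particles`
#'   with columns `id`, `type`, `y0`, `z0`, `vy0`, `vz0` plus the generator
#'   parameters (`seed`, `placement`, `width`, `height`) and the `cells`
#'   list.
#' @export
#' @examples
#' ens <- make_cell_ensemble(c(CTC = 5, RBC = 5), 500e-6, 70e-6, seed = 1)
#' nrow(ens$particles)
make_cell_ensemble <- function(counts, width, height,
                               placement = c("uniform", "grid", "point"),
                               seed = 1L, cells = NULL) {
  placement <- match.arg(placement)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("no cells requested", call. = FALSE)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of cell types", call. = FALSE)
  }
  if (is.null(cells)) {
    cells <- lapply(names(counts), cell_preset)
    names(cells) <- names(counts)
  }
  rows <- vector("list", length(counts))
  rng <- local({
    set.seed(as.integer(seed))
    function(n, lo, hi) stats::runif(n, lo, hi)
  })
  for (i in seq_along(counts)) {
    type <- names(counts)[i]
    n_i <- as.integer(counts[i])
    inset <- cells[[type]]$radius
    if (2 * inset >= width || 2 * inset >= height) {
      stop(sprintf("capacity error: %s diameter exceeds the release section",
                   type), call. = FALSE)
    }
    pos <- switch(placement,
      uniform = cbind(rng(n_i, inset, width - inset),
                      rng(n_i, inset, height - inset)),
      grid = {
        aspect <- (width - 2 * inset) / (height - 2 * inset)
        ny <- max(1L, ceiling(sqrt(n_i * aspect)))
        nz <- ceiling(n_i / ny)
        gy <- seq(inset, width - inset, length.out = max(ny, 2L))[seq_len(ny)]
        gz <- seq(inset, height - inset, length.out = max(nz, 2L))[seq_len(nz)]
        g <- as.matrix(expand.grid(gy, gz))[seq_len(n_i), , drop = FALSE]
        g
      },
      point = cbind(rep(width / 2, n_i), rep(height / 2, n_i))
    )
    rows[[i]] <- data.frame(type = type, y0 = pos[, 1], z0 = pos[, 2],
                            vy0 = 0, vz0 = 0, stringsAsFactors = FALSE)
  }
  particles <- do.call(rbind, rows)
  particles <- cbind(id = seq_len(nrow(particles)), particles)
  rownames(particles) <- NULL
  structure(list(
    particles = particles, cells = cells, seed = as.integer(seed),
    placement = placement, width = width, height = height
  ), class = "cell_ensemble")
}

#' @export
print.cell_ensemble <- function(x, ...) {
  tab <- table(x$particles$type)
  cat(sprintf("<cell_ensemble> %d particles (%s), %s placement, seed %d\n",
              nrow(x$particles),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
              x$placement, x$seed))
  invisible(x)
}

#' Ensemble with clinically proportioned cell counts
#'
#' Draws the cell-type composition from a multinomial with probabilities
#' proportional to the clinical blood concentrations of the three classes
#' (defaults: CTC 5.5/mL, WBC 7.5e6/mL, RBC 7e9/mL — midpoints of the
#' reported ranges 1-10, 5-10e6 and 5-9e9 per mL). At least one CTC is
#' always included so downstream stages have a target cell to follow.
#'
#' @param total Total cell count (>= 10).
#' @param width,height Release-plane dimensions (m).
#' @param seed Integer seed.
#' @param concentrations Named numeric vector of per-mL concentrations.
#' @param ... Forwarded to [make_cell_ensemble()].
#' @return A [make_cell_ensemble()] result; the drawn composition is in
#'   `attr(, "composition")`.
#' @export
clinical_ratio_ensemble <- function(total, width = 1e-3, height = 70e-6,
                                    seed = 1L,
                                    concentrations = c(CTC = 5.5,
                                                       WBC = 7.5e6,
                                                       RBC = 7e9),
                                    ...) {
  if (total < 10) stop("total must be at least 10", call. = FALSE)
  p <- concentrations / sum(concentrations)
  set.seed(as.integer(seed))
  draw <- stats::rmultinom(1, total, p)[, 1]
  names(draw) <- names(concentrations)
  if (draw["CTC"] < 1) {       # guarantee a target cell
    donor <- names(which.max(draw))
    draw[donor] <- draw[donor] - 1L
    draw["CTC"] <- 1L
  }
  ens <- make_cell_ensemble(draw, width, height, seed = seed, ...)
  attr(ens, "composition") <- draw
  ens
}

#' Catalogued run fixtures
#'
#' Fully populated run configurations for the catalogued study conditions:
#' `"S1@Re40"` ... `"S4@Re65"` (passive spiral runs at the two studied
#' Reynolds numbers) and `"SAW-default"` (the standing-wave study in the
#' straight section: 3.3 MHz drive, 1500 m/s sound speed, 5 mm transducer,
#' zero flow, mesh-based release with zero initial velocity).
#'
#' @param name Fixture name.
#' @return A [run_config()].
#' @export
#' @examples
#' device_fixture("S4@Re65")$Re
device_fixture <- function(name) {
  if (toupper(name) == "SAW-DEFAULT") {
    return(run_config(channel = "S4", Re = 0, stage = "active",
                      placement = "grid", counts = c(CTC = 50, WBC = 50,
                                                     RBC = 50),
                      duration = 3, seed = 42L, name = "SAW-default"))
  }
  m <- regmatches(name, regexec("^(S[1-4])@Re([0-9]+)$", name,
                                ignore.case = TRUE))[[1]]
  if (length(m) != 3) {
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
  }
  run_config(channel = toupper(m[2]), Re = as.numeric(m[3]),
             stage = "passive", placement = "uniform",
             counts = c(CTC = 50, WBC = 50, RBC = 50), seed = 42L,
             name = name)
}
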