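#' Register section observations in the block frame
#'
#' Re-expresses per-section 2D observations relative to the positioning-plate
#' X-axis and the perpendicular Y-axis through the frame origin, and undoes
#' the mirror flip that bottom-first cutting imposes on section images. For
#' the canonical frame (plate edge along y = 0 from the origin) and
#' `mirror = FALSE` this is the identity.
#'
#' @param obs Observation tibble as produced by [simulate_cut()] (columns
#'   `section_index`, `advance_um`, `target`, `present`, `x_um`, `y_um`, ...).
#' @param frame A [block_frame()].
#' @param mirror Whether the observations were read off mirrored images.
#' @return The observations with `x_um`, `y_um` in the registered block frame.
#' @export
register_observations <- function(obs, frame, mirror = FALSE) {
  stopifnot(inherits(frame, "block_frame"))
  obs <- tibble::as_tibble(obs)
  need <- c("x_um", "y_um", "present")
  if (!all(need %in% names(obs))) {
    stop("observations need columns x_um, y_um, present", call. = FALSE)
  }
  u <- frame$plate_edge[2, ] - frame$plate_edge[1, ]
  u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1]) # perpendicular; oriented so the footprint interior has y > 0
  ctr <- c(frame$footprint_x, frame$footprint_y) / 2
  if (sum(v * (ctr - frame$origin)) < 0) v <- -v
  px <- obs$x_um - frame$origin[1]
  py <- obs$y_um - frame$origin[2]
  x <- px * u[1] + py * u[2]
  y <- px * v[1] + py * v[2]
  if (mirror) x <- -x # undo the reflection across the Y-Z plane at the origin
  pres <- which(obs$present)
  bad <- pres[
    x[pres] < -.tol_geom | x[pres] > frame$footprint_x + .tol_geom |
      y[pres] < -.tol_geom | y[pres] > frame$footprint_y + .tol_geom
  ]
  if (length(bad) > 0) {
    stop(
      sprintf(
        "registration error: %d observation(s) fall outside the frame",
        length(bad)
      ),
      call. = FALSE
    )
  }
  obs$x_um <- x
  obs$y_um <- y
  obs
}

#' Quantize a measurement to a grid
#'
#' Coordinates are read off grid paper: values snap to the nearest multiple
#' of the grid spacing, ties rounding away from zero. The quantization error
#' is at most half the grid.
#'
#' @param value Numeric vector, µm.
#' @param grid_um Grid spacing, µm (> 0; default 100).
#' @return `value` snapped to the grid.
#' @examples
#' quantize_measurement(c(1951, 1950, -1950)) # 2000, 2000, -2000
#' @export
quantize_measurement <- function(value, grid_um = 100) {
  stopifnot(is.numeric(value), grid_um > 0)
  sign(value) * floor(abs(value) / grid_um + 0.5) * grid_um
}

#' Estimate 3D target centers from a registered section stack
#'
#' Per target, the arithmetic mean of the per-section centroid coordinates
#' over the sections where the target is present; the Z estimate is the mean
#' of the section mid-plane advances. Sections far from the center (small
#' cross-sections) enter unweighted. Targets never observed are dropped with
#' a warning.
#'
#' @param obs Registered observation tibble (see [register_observations()]).
#' @return A tibble `target`, `x_um`, `y_um`, `z_um`, `x_sd_um`, `y_sd_um`,
#'   `z_sd_um`, `n_sections`, one row per observed target.
#' @examples
#' blk <- three_target_model()
#' obs <- simulate_cut(blk, face_plane(blk$frame), plan_serial_survey(blk$frame$height))
#' estimate_centers(obs)
#' @export
estimate_centers <- function(obs) {
  obs <- tibble::as_tibble(obs)
  need <- c("target", "present", "x_um", "y_um", "advance_um")
  if (!all(need %in% names(obs))) {
    stop("observations need columns target, present, x_um, y_um, advance_um",
      call. = FALSE
    )
  }
  all_targets <- unique(obs$target)
  hit <- dplyr::filter(obs, .data$present)
  missing <- setdiff(all_targets, unique(hit$target))
  if (length(missing) > 0) {
    warning(
      sprintf("target(s) never observed: %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  if (nrow(hit) == 0) {
    stop("no present observations to localize", call. = FALSE)
  }
  out <- hit |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      x_sd_um = stats::sd(.data$x_um),
      y_sd_um = stats::sd(.data$y_um),
      z_sd_um = stats::sd(.data$advance_um),
      x_um = mean(.data$x_um),
      y_um = mean(.data$y_um),
      z_um = mean(.data$advance_um),
      .groups = "drop"
    )
  out[, c(
    "target", "x_um", "y_um", "z_um",
    "x_sd_um", "y_sd_um", "z_sd_um", "n_sections"
  )]
}
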