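#' Virtual tissue block with spherical targets
#'
#' A synthetic embedding block: a [block_frame()] plus spherical targets
#' (center + radius). Targets must lie entirely inside the frame.
#'
#' @param frame A [block_frame()].
#' @param targets Data frame with `name`, `x_um`, `y_um`, `z_um`,
#'   `radius_um`.
#' @return An object of class `virtual_block`.
#' @examples
#' three_target_model()
#' @export
virtual_block <- function(frame, targets) {
  stopifnot(inherits(frame, "block_frame"))
  targets <- as_targets(targets)
  if (!"radius_um" %in% names(targets)) {
    stop("virtual_block targets need a radius_um column", call. = FALSE)
  }
  if (any(targets$radius_um <= 0)) {
    stop("target radii must be strictly positive", call. = FALSE)
  }
  r <- targets$radius_um
  inside <- targets$x_um - r >= -.tol_geom &
    targets$x_um + r <= frame$footprint_x + .tol_geom &
    targets$y_um - r >= -.tol_geom &
    targets$y_um + r <= frame$footprint_y + .tol_geom &
    targets$z_um - r >= -.tol_geom &
    targets$z_um + r <= frame$height + .tol_geom
  if (!all(inside)) {
    stop(
      sprintf(
        "target spheres not fully inside the frame: %s",
        paste(targets$name[!inside], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  structure(list(frame = frame, targets = targets), class = "virtual_block")
}

#' @export
print.virtual_block <- function(x, ...) {
  print(x$frame)
  print(x$targets)
  invisible(x)
}

#' Blade plane at the block face
#'
#' The untilted blade position coincident with the face that is cut first
#' (z = 0): the natural advance-zero reference for a perpendicular serial
#' survey.
#'
#' @param frame A [block_frame()] (unused beyond its class; kept for symmetry).
#' @return A [cutting_plane()] with normal `(0, 0, 1)` through the origin.
#' @export
face_plane <- function(frame) {
  stopifnot(inherits(frame, "block_frame"))
  cutting_plane(c(0, 0, 1), c(0, 0, 0))
}

#' Simulate serial sectioning of a virtual block
#'
#' For every collect event of the plan, evaluates each target sphere against
#' the section's mid-plane: the target is present iff the unsigned distance
#' from its center to the mid-plane is smaller than its radius; the reported
#' 2D centroid is the orthogonal projection of the center onto the mid-plane
#' and the cross-section radius is `sqrt(r^2 - d^2)`. The given `plane` is the
#' blade position at advance zero; each event advances it along the feed axis.
#'
#' @param block A [virtual_block()].
#' @param plane A [cutting_plane()]: blade orientation and advance-zero
#'   position.
#' @param plan A `section_plan` ([plan_schedule()] / [plan_serial_survey()]).
#' @param mirror If `TRUE`, centroids are reported in the mirrored section
#'   frame (bottom-first cutting flips section images; see [mirror_x()]).
#' @return A tibble with one row per collect section and target:
#'   `section_index` (1-based in advance order), `advance_um` (mid-plane),
#'   `target`, `present`, `x_um`, `y_um`, `radius_um` (`NA` when absent).
#' @examples
#' blk <- three_target_model()
#' obs <- simulate_cut(blk, face_plane(blk$frame), plan_serial_survey(blk$frame$height))
#' @export
simulate_cut <- function(block, plane, plan, mirror = FALSE) {
  stopifnot(
    inherits(block, "virtual_block"), inherits(plane, "cutting_plane"),
    inherits(plan, "section_plan")
  )
  if (tilt_angle(plane) >= 90 - .tol_geom) {
    stop("blade tilt must be below 90 degrees", call. = FALSE)
  }
  collects <- plan[plan$kind == "collect", ]
  tg <- block$targets
  centers <- target_matrix(tg)
  # signed distance of each center to the advance-zero blade plane
  d0 <- plane_distance(plane, centers)
  nz <- plane$normal[3]
  grid <- tidyr::expand_grid(
    sec = seq_len(nrow(collects)),
    tgt = seq_len(nrow(tg))
  )
  mid <- collects$advance_start_um + collects$thickness_um / 2
  d <- d0[grid$tgt] - mid[grid$sec] * nz
  present <- abs(d) < tg$radius_um[grid$tgt]
  proj <- centers[grid$tgt, , drop = FALSE] -
    outer(d, plane$normal)
  x <- ifelse(present, proj[, 1], NA_real_)
  if (mirror) x <- 2 * block$frame$origin[1] - x
  obs <- tibble::tibble(
    section_index = grid$sec,
    advance_um = mid[grid$sec],
    target = tg$name[grid$tgt],
    present = present,
    x_um = x,
    y_um = ifelse(present, proj[, 2], NA_real_),
    radius_um = ifelse(
      present,
      sqrt(pmax(tg$radius_um[grid$tgt]^2 - d^2, 0)),
      NA_real_
    )
  )
  dplyr::arrange(obs, .data$section_index, .data$target)
}

#' Advance at which the blade mid-plane passes each target center
#'
#' @param block A [virtual_block()].
#' @param plane A [cutting_plane()]: blade orientation and advance-zero
#'   position (defaults semantics: pass [face_plane()] for a perpendicular
#'   survey or the planner's virtual plane for a planned cut).
#' @return A tibble `target`, `advance_um`.
#' @examples
#' blk <- three_target_model()
#' actual_hit_advances(blk, face_plane(blk$frame))
#' @export
actual_hit_advances <- function(block, plane) {
  stopifnot(inherits(block, "virtual_block"), inherits(plane, "cutting_plane"))
  d0 <- plane_distance(plane, target_matrix(block$targets))
  tibble::tibble(
    target = block$targets$name,
    advance_um = d0 / plane$normal[3]
  )
}
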