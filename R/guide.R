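#' Virtual sectioning plane and needle-guide model
#'
#' The expected sectioning plane runs through the target centers inside the
#' block, where the blade cannot be aligned directly. It is therefore
#' mirrored outside the block: with `Zb` the maximal target depth, the plane
#' is raised by `Zb` to the suppositional plane (which meets the bottom face
#' at the deepest target's footprint) and by `Zb` again to the virtual
#' sectioning plane. The virtual plane is realized physically by needles of
#' height `2 * Zb - Zi` erected at each target's footprint `(x_i, y_i)` on a
#' dummy block; aligning the blade to the three needle tips sets the cutting
#' angle.
#'
#' @param targets Data frame with columns `name`, `x_um`, `y_um`, `z_um`
#'   (>= 3 rows). `z_um` is the depth along the cutting-forward direction.
#' @return An object of class `guide_plan`: a list with elements
#'   `expected`, `suppositional`, `virtual` (parallel [cutting_plane()]s with
#'   equal spacing `z_deep`), `guide` (tibble `name`, `base_x_um`,
#'   `base_y_um`, `tip_height_um`), `z_deep` (µm), and `deepest` (target
#'   name).
#' @examples
#' vp <- virtual_plane(three_target_model()$targets)
#' vp$guide
#' @export
virtual_plane <- function(targets) {
  targets <- as_targets(targets)
  expected <- if (nrow(targets) == 3) {
    plane_through_targets(targets)
  } else {
    fit_plane(targets)
  }
  # first target attaining the maximal depth is "b"; only the depth value
  # enters the tip formula, so ties do not change the result
  i_deep <- which.max(targets$z_um)
  z_deep <- targets$z_um[i_deep]
  guide <- tibble::tibble(
    name = targets$name,
    base_x_um = targets$x_um,
    base_y_um = targets$y_um,
    tip_height_um = 2 * z_deep - targets$z_um
  )
  if (any(guide$tip_height_um < -.tol_geom)) {
    stop("internal consistency error: negative needle tip height", call. = FALSE)
  }
  structure(
    list(
      expected = expected,
      suppositional = translate_plane(expected, -z_deep),
      virtual = translate_plane(expected, -2 * z_deep),
      guide = guide,
      z_deep = z_deep,
      deepest = targets$name[i_deep]
    ),
    class = "guide_plan"
  )
}

#' @export
print.guide_plan <- function(x, ...) {
  cat(sprintf(
    "<guide_plan> deepest target %s at %g um; plane spacing %g um; tilt %.3f deg\n",
    x$deepest, x$z_deep, x$z_deep, tilt_angle(x$expected)
  ))
  print(x$guide)
  invisible(x)
}

#' Complete sectioning plan for a set of target centers
#'
#' Runs the planning steps end to end: expected plane through the centers,
#' virtual plane and needle-guide model, cryostat feasibility check,
#' cutting-forward distances (to the bottom mark of the deepest target and to
#' the target plane itself, both from the virtual-plane start position), and
#' the trim/collect schedule.
#'
#' @inheritParams virtual_plane
#' @param frame A [block_frame()].
#' @param capacity_deg Cryostat cutting-angle capacity, degrees.
#' @param trim_thickness_um,fine_thickness_um,approach_margin_um Schedule
#'   parameters, see [plan_schedule()].
#' @param allow_infeasible If `FALSE` (default), planning stops with an error
#'   of class `planecut_infeasible` when the tilt exceeds capacity.
#' @return An object of class `cut_plan`: list with `targets`, `frame`,
#'   `planes` (the [virtual_plane()] result), `feasibility`, `mark` (2-vector,
#'   bottom footprint of the deepest target), `advance_to_mark_um`,
#'   `expected_advance_um` (advance from the virtual plane to the target
#'   plane), and `schedule` (a [plan_schedule()] tibble).
#' @examples
#' blk <- three_target_model()
#' plan_cut(blk$targets, blk$frame)
#' @export
plan_cut <- function(targets, frame, capacity_deg = 20,
                     trim_thickness_um = 20, fine_thickness_um = 7,
                     approach_margin_um = 1000, allow_infeasible = FALSE) {
  targets <- as_targets(targets)
  stopifnot(inherits(frame, "block_frame"))
  if (any(targets$z_um > frame$height + .tol_geom)) {
    stop("target depth exceeds block height", call. = FALSE)
  }
  planes <- virtual_plane(targets)
  feas <- check_feasibility(planes$expected, capacity_deg)
  if (!feas$feasible && !allow_infeasible) {
    stop(
      structure(
        class = c("planecut_infeasible", "error", "condition"),
        list(
          message = sprintf(
            "plane tilt %.2f deg exceeds cryostat capacity %g deg; pre-trim a %.2f deg wedge or re-embed",
            feas$tilt_deg, capacity_deg, feas$wedge_deg
          ),
          call = NULL
        )
      )
    )
  }
  i_deep <- which(targets$name == planes$deepest)[1]
  mark <- c(targets$x_um[i_deep], targets$y_um[i_deep])
  advance_to_mark <- cutting_forward_distance(
    planes$expected, mark, frame,
    start = planes$virtual
  )
  expected_advance <- advance_between_planes(planes$virtual, planes$expected)
  schedule <- plan_schedule(
    expected_advance,
    trim_thickness_um = trim_thickness_um,
    fine_thickness_um = fine_thickness_um,
    approach_margin_um = approach_margin_um
  )
  structure(
    list(
      targets = targets,
      frame = frame,
      planes = planes,
      feasibility = feas,
      mark = mark,
      advance_to_mark_um = advance_to_mark,
      expected_advance_um = expected_advance,
      schedule = schedule
    ),
    class = "cut_plan"
  )
}

#' @export
print.cut_plan <- function(x, ...) {
  f <- x$feasibility
  cat(sprintf(
    "<cut_plan> %d targets; tilt %.3f deg (%s, capacity %g deg)\n",
    nrow(x$targets), f$tilt_deg, if (f$feasible) "feasible" else "INFEASIBLE",
    f$capacity_deg
  ))
  cat(sprintf(
    "  advance to bottom mark %.1f um; expected advance to target plane %.1f um\n",
    x$advance_to_mark_um, x$expected_advance_um
  ))
  cat(sprintf(
    "  schedule: %d trims + %d fine sections\n",
    sum(x$schedule$kind == "trim"), sum(x$schedule$kind == "collect")
  ))
  invisible(x)
}
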