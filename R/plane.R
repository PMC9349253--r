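# Geometric predicates use an absolute tolerance of 1e-6 um; unit normals are
# exact to 1e-9. The plane normal is always oriented with a positive Z
# component (pointing against the cutting-forward direction), so planes with a
# vertical orientation (normal perpendicular to Z) are rejected.

.tol_geom <- 1e-6
.tol_unit <- 1e-9

#' Oriented cutting plane
#'
#' A blade plane relative to the block, stored as a unit normal and a point on
#' the plane (µm). The normal is normalized and flipped so that its Z
#' component is positive.
#'
#' @param normal Numeric 3-vector; need not be unit length.
#' @param point Numeric 3-vector on the plane, µm.
#' @return An object of class `cutting_plane`.
#' @examples
#' cutting_plane(c(0, 0, 2), c(0, 0, 5000))
#' @export
cutting_plane <- function(normal, point) {
  normal <- as.numeric(normal)
  point <- as.numeric(point)
  stopifnot(length(normal) == 3, length(point) == 3)
  nn <- sqrt(sum(normal^2))
  if (nn < .tol_unit) stop("degenerate plane normal", call. = FALSE)
  normal <- normal / nn
  if (abs(normal[3]) < .tol_unit) {
    stop("vertical cutting plane (normal perpendicular to Z) is unsupported",
      call. = FALSE
    )
  }
  if (normal[3] < 0) normal <- -normal
  structure(list(normal = normal, point = point), class = "cutting_plane")
}

#' @export
print.cutting_plane <- function(x, ...) {
  cat(sprintf(
    "<cutting_plane> normal (%.6f, %.6f, %.6f), point (%g, %g, %g) um, tilt %.3f deg\n",
    x$normal[1], x$normal[2], x$normal[3],
    x$point[1], x$point[2], x$point[3], tilt_angle(x)
  ))
  invisible(x)
}

#' @rdname cutting_plane
#' @param x A `cutting_plane`.
#' @param ... Unused.
#' @method tidy cutting_plane
#' @export
tidy.cutting_plane <- function(x, ...) {
  tibble::tibble(
    nx = x$normal[1], ny = x$normal[2], nz = x$normal[3],
    px = x$point[1], py = x$point[2], pz = x$point[3],
    tilt_deg = tilt_angle(x)
  )
}

# signed point-plane distance along the (Z-positive) normal, vectorized over
# rows of a 3-column matrix
plane_distance <- function(plane, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  drop(sweep(pts, 2, plane$point) %*% plane$normal)
}

# translate a plane along the feed axis (Z) by `advance` um
translate_plane <- function(plane, advance) {
  cutting_plane(plane$normal, plane$point + c(0, 0, advance))
}

planes_parallel <- function(a, b, tol_rad = 1e-6) {
  d <- abs(sum(a$normal * b$normal))
  d <- min(d, 1)
  acos(d) < tol_rad
}

# advance along Z that carries `start` onto `target` (both parallel)
advance_between_planes <- function(start, target) {
  stopifnot(planes_parallel(start, target))
  sum(target$normal * (target$point - start$point)) / target$normal[3]
}

# accept either `name` or `target` as the identifier column and require
# coordinate columns in um
as_targets <- function(targets) {
  targets <- tibble::as_tibble(targets)
  if (!"name" %in% names(targets) && "target" %in% names(targets)) {
    targets <- dplyr::rename(targets, name = "target")
  }
  need <- c("name", "x_um", "y_um", "z_um")
  if (!all(need %in% names(targets))) {
    stop(
      "targets must have columns name (or target), x_um, y_um, z_um",
      call. = FALSE
    )
  }
  if (any(!is.finite(targets$x_um) | !is.finite(targets$y_um) |
    !is.finite(targets$z_um))) {
    stop("target coordinates must be finite", call. = FALSE)
  }
  if (any(targets$x_um < 0 | targets$y_um < 0 | targets$z_um < 0)) {
    stop("target coordinates are stored as positive magnitudes", call. = FALSE)
  }
  targets
}

target_matrix <- function(targets) {
  unname(as.matrix(targets[, c("x_um", "y_um", "z_um")]))
}

#' Plane through three target centers
#'
#' Constructs the expected sectioning plane: the unique plane containing the
#' three target centers that the delivered section must hit.
#'
#' @param targets Data frame with columns `name`, `x_um`, `y_um`, `z_um`
#'   (positive magnitudes, µm) and exactly three rows.
#' @return A [cutting_plane()] containing all three centers.
#' @examples
#' plane_through_targets(three_target_model()$targets)
#' @export
plane_through_targets <- function(targets) {
  targets <- as_targets(targets)
  if (nrow(targets) != 3) {
    stop("plane_through_targets needs exactly three targets; use fit_plane() for more",
      call. = FALSE
    )
  }
  m <- target_matrix(targets)
  v1 <- m[2, ] - m[1, ]
  v2 <- m[3, ] - m[1, ]
  n <- c(
    v1[2] * v2[3] - v1[3] * v2[2],
    v1[3] * v2[1] - v1[1] * v2[3],
    v1[1] * v2[2] - v1[2] * v2[1]
  )
  scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)), 1)
  if (sqrt(sum(n^2)) < .tol_geom * scale) {
    stop(
      sprintf(
        "degenerate geometry: targets %s are collinear or coincident",
        paste(targets$name, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  cutting_plane(n, colMeans(m))
}

#' Orthogonal least-squares plane through target centers
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to `n >=
#' 3` target centers (total least squares via SVD). With exactly three targets
#' this is the plane through them.
#'
#' @inheritParams plane_through_targets
#' @return A [cutting_plane()].
#' @examples
#' fit_plane(three_target_model()$targets)
#' @export
fit_plane <- function(targets) {
  targets <- as_targets(targets)
  if (nrow(targets) < 3) stop("fit_plane needs at least three targets", call. = FALSE)
  m <- target_matrix(targets)
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr))
  scale <- max(sv$d[1], 1)
  if (sv$d[2] < .tol_geom * scale) {
    stop(
      sprintf(
        "degenerate geometry: targets %s are collinear",
        paste(targets$name, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  cutting_plane(sv$v[, 3], ctr)
}

#' Tilt of a cutting plane relative to the block bottom
#'
#' The angle, in degrees, between the plane and the block bottom face
#' (equivalently between the plane normal and the feed axis Z). Always in
#' `[0, 90)`.
#'
#' @param plane A [cutting_plane()].
#' @return Angle in degrees.
#' @examples
#' tilt_angle(cutting_plane(c(0, 0, 1), c(0, 0, 0))) # 0
#' @export
tilt_angle <- function(plane) {
  stopifnot(inherits(plane, "cutting_plane"))
  acos(min(abs(plane$normal[3]), 1)) * 180 / pi
}

#' Cryostat feasibility of a cutting plane
#'
#' A cryostat can only be set to a limited cutting angle between the blade
#' plane and the block face (0-20 degrees for the instrument modelled here).
#' A plane is feasible iff its tilt does not exceed the capacity (boundary
#' inclusive). When infeasible, the suggested remedy is a pre-trim wedge (an
#' inclined face cut) of `tilt - capacity` degrees, after which the residual
#' tilt falls within capacity.
#'
#' @param plane A [cutting_plane()].
#' @param capacity_deg Cutting-angle capacity in degrees, in (0, 90).
#' @return A one-row tibble with `tilt_deg`, `capacity_deg`, `feasible`,
#'   `wedge_deg`.
#' @examples
#' check_feasibility(plane_through_targets(three_target_model()$targets))
#' @export
check_feasibility <- function(plane, capacity_deg = 20) {
  stopifnot(inherits(plane, "cutting_plane"))
  if (!is.numeric(capacity_deg) || length(capacity_deg) != 1 ||
    capacity_deg <= 0 || capacity_deg >= 90) {
    stop("capacity_deg must lie in (0, 90)", call. = FALSE)
  }
  tilt <- tilt_angle(plane)
  tibble::tibble(
    tilt_deg = tilt,
    capacity_deg = capacity_deg,
    feasible = tilt <= capacity_deg,
    wedge_deg = max(0, tilt - capacity_deg)
  )
}

#' Cutting-forward distance to a marked bottom point
#'
#' The specimen is advanced along the feed axis (Z) in fixed-thickness steps;
#' the cutting-forward distance is the advance from a start blade position
#' until the blade plane passes through a point marked on the block bottom
#' face. For a blade tilted by `theta` it equals the point-to-start-plane
#' distance divided by `cos(theta)`.
#'
#' @param plane Target [cutting_plane()] orientation (must be parallel to
#'   `start`).
#' @param mark Numeric 2-vector `(x, y)` µm: the marked point on the block
#'   bottom face (z = 0).
#' @param frame A [block_frame()]; the mark must lie within its footprint.
#' @param start A [cutting_plane()]: the blade position at advance zero
#'   (typically the virtual sectioning plane).
#' @return Nonnegative advance in µm.
#' @examples
#' fr <- block_frame(10000, 8000, 8000)
#' pl <- cutting_plane(c(0, 0, 1), c(0, 0, 0))
#' cutting_forward_distance(pl, c(5000, 4000), fr, translate_to <- cutting_plane(c(0, 0, 1), c(0, 0, -6000)))
#' @export
cutting_forward_distance <- function(plane, mark, frame, start) {
  stopifnot(
    inherits(plane, "cutting_plane"), inherits(start, "cutting_plane"),
    inherits(frame, "block_frame")
  )
  mark <- as.numeric(mark)
  stopifnot(length(mark) == 2)
  if (!planes_parallel(plane, start)) {
    stop("start and target planes are not parallel", call. = FALSE)
  }
  if (mark[1] < -.tol_geom || mark[1] > frame$footprint_x + .tol_geom ||
    mark[2] < -.tol_geom || mark[2] > frame$footprint_y + .tol_geom) {
    stop("mark does not lie on the block bottom face", call. = FALSE)
  }
  p <- c(mark, 0)
  adv <- sum(start$normal * (p - start$point)) / start$normal[3]
  if (adv < -.tol_geom) {
    stop("mark lies behind the start plane (negative advance)", call. = FALSE)
  }
  max(adv, 0)
}
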