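#' Block coordinate frame
#'
#' The coordinate frame of an embedding block is anchored to a fiducial
#' positioning plate inset in the block: the plate border is the X-axis, the
#' perpendicular through one end of the plate (the origin) is the Y-axis, and
#' the cutting-forward (specimen feed) direction is the Z-axis. All lengths
#' are in micrometres. Target coordinates are stored as positive magnitudes;
#' depth (`z_um`) increases along the cutting-forward direction from the face
#' that is cut first.
#'
#' @param footprint_x,footprint_y Block footprint along the plate axis and its
#'   perpendicular, in micrometres.
#' @param height Block extent along the cutting-forward (Z) axis, µm.
#' @param plate_edge Two-row matrix (or 2-column data frame) with the 2D
#'   endpoints of the positioning-plate border segment, µm. Defaults to the
#'   full lower edge of the footprint.
#' @param origin 2D point taken as the frame origin (the plate end). Defaults
#'   to the first `plate_edge` endpoint.
#' @return An object of class `block_frame`.
#' @examples
#' block_frame(10000, 8000, 8000)
#' @export
block_frame <- function(footprint_x, footprint_y, height,
                        plate_edge = NULL, origin = NULL) {
  stopifnot(is.numeric(footprint_x), is.numeric(footprint_y), is.numeric(height))
  if (footprint_x <= 0 || footprint_y <= 0 || height <= 0) {
    stop("block_frame dimensions must be strictly positive", call. = FALSE)
  }
  if (is.null(plate_edge)) {
    plate_edge <- rbind(c(0, 0), c(footprint_x, 0))
  }
  plate_edge <- as.matrix(plate_edge)
  if (!all(dim(plate_edge) == c(2L, 2L))) {
    stop("plate_edge must be two 2D endpoints", call. = FALSE)
  }
  if (sqrt(sum((plate_edge[1, ] - plate_edge[2, ])^2)) < 1e-9) {
    stop("plate_edge endpoints must be distinct", call. = FALSE)
  }
  inside <- function(p) {
    p[1] >= -1e-9 && p[1] <= footprint_x + 1e-9 &&
      p[2] >= -1e-9 && p[2] <= footprint_y + 1e-9
  }
  if (!inside(plate_edge[1, ]) || !inside(plate_edge[2, ])) {
    stop("plate_edge endpoints must lie within the footprint", call. = FALSE)
  }
  if (is.null(origin)) origin <- plate_edge[1, ]
  origin <- as.numeric(origin)
  structure(
    list(
      footprint_x = as.numeric(footprint_x),
      footprint_y = as.numeric(footprint_y),
      height = as.numeric(height),
      plate_edge = unname(plate_edge),
      origin = unname(origin)
    ),
    class = "block_frame"
  )
}

#' @export
print.block_frame <- function(x, ...) {
  cat(sprintf(
    "<block_frame> %g x %g x %g um (footprint x, footprint y, height)\n",
    x$footprint_x, x$footprint_y, x$height
  ))
  cat(sprintf(
    "  plate edge (%g, %g) -- (%g, %g), origin (%g, %g)\n",
    x$plate_edge[1, 1], x$plate_edge[1, 2],
    x$plate_edge[2, 1], x$plate_edge[2, 2],
    x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' Mirror coordinates for bottom-first cutting
#'
#' When the block is reverted so that its bottom face is cut first, section
#' images are flipped mirror-style about the plate axis before coordinates are
#' read off. `mirror_x()` applies that reflection: the X coordinate is negated
#' relative to the frame origin (reflection across the Y-Z plane through the
#' origin); Y and Z are untouched. Applying it twice is the identity.
#'
#' @param x A data frame with an `x_um` column, a `cutting_plane`, or a
#'   numeric 3-vector.
#' @param frame A [block_frame()]; its origin fixes the mirror axis.
#' @return The mirrored counterpart of `x`, same type as the input.
#' @examples
#' fr <- block_frame(10000, 8000, 8000)
#' pts <- tibble::tibble(name = "a", x_um = 2000, y_um = 1000, z_um = 4000)
#' mirror_x(mirror_x(pts, fr), fr) # identity
#' @export
mirror_x <- function(x, frame) UseMethod("mirror_x")

#' @export
mirror_x.data.frame <- function(x, frame) {
  stopifnot(inherits(frame, "block_frame"), "x_um" %in% names(x))
  x$x_um <- 2 * frame$origin[1] - x$x_um
  x
}

#' @export
mirror_x.numeric <- function(x, frame) {
  stopifnot(inherits(frame, "block_frame"), length(x) >= 2)
  x[1] <- 2 * frame$origin[1] - x[1]
  x
}

#' @export
mirror_x.cutting_plane <- function(x, frame) {
  stopifnot(inherits(frame, "block_frame"))
  n <- x$normal
  n[1] <- -n[1]
  p <- x$point
  p[1] <- 2 * frame$origin[1] - p[1]
  cutting_plane(n, p)
}
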