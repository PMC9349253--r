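# Phantom generators. The three-target model is the reference phantom of the
# validation study: colored spherical targets at known positions in an OCT
# block, measured on 100 um grid paper. Organ presets carry the study's block
# dimensions with synthetic in-frame target placements.

#' Reference three-target phantom
#'
#' A block with three colored spherical targets at the known validation
#' positions (µm magnitudes): Red (2000, 1000, 4000), Green (8000, 3000,
#' 5000), Blue (5000, 7000, 6000). Blue is the deepest target. The frame is
#' sized to contain all targets with margin.
#'
#' @param radius_um Target sphere radius, µm (default 500, so a 100 µm survey
#'   interval yields about ten positive sections per target).
#' @return A [virtual_block()].
#' @examples
#' three_target_model()$targets
#' @export
three_target_model <- function(radius_um = 500) {
  frame <- block_frame(10000, 8000, 8000)
  targets <- tibble::tibble(
    name = c("Red", "Green", "Blue"),
    x_um = c(2000, 8000, 5000),
    y_um = c(1000, 3000, 7000),
    z_um = c(4000, 5000, 6000),
    radius_um = radius_um
  )
  virtual_block(frame, targets)
}

#' Random phantom block
#'
#' Draws `n_targets` sphere targets uniformly inside the frame (with a
#' clearance of one radius from every face), rejecting target sets that are
#' nearly collinear or overlapping so that the plane construction is well
#' conditioned. Reproducible for a fixed seed.
#'
#' @param n_targets Number of targets (>= 3).
#' @param frame A [block_frame()] (default: the three-target model frame).
#' @param radius_range Min/max sphere radius, µm.
#' @param seed Integer seed.
#' @param min_height_um Minimum distance of each target from the line through
#'   any other two (collinearity margin), µm.
#' @return A [virtual_block()]; the seed is recorded in attribute `seed`.
#' @examples
#' random_block(seed = 1)$targets
#' @export
random_block <- function(n_targets = 3, frame = block_frame(10000, 8000, 8000),
                         radius_range = c(250, 500), seed = 1,
                         min_height_um = 300) {
  stopifnot(n_targets >= 3, length(radius_range) == 2, all(radius_range > 0))
  draw <- function() {
    r <- stats::runif(n_targets, radius_range[1], radius_range[2])
    tibble::tibble(
      name = paste0("T", seq_len(n_targets)),
      x_um = stats::runif(n_targets, r, frame$footprint_x - r),
      y_um = stats::runif(n_targets, r, frame$footprint_y - r),
      z_um = stats::runif(n_targets, r, frame$height - r),
      radius_um = r
    )
  }
  ok <- function(tg) {
    m <- target_matrix(tg)
    # pairwise separation
    d <- as.matrix(stats::dist(m))
    diag(d) <- Inf
    if (min(d) < sum(range(tg$radius_um))) {
      return(FALSE)
    }
    # distance of each point to the line through every other pair
    idx <- utils::combn(n_targets, 3)
    for (k in seq_len(ncol(idx))) {
      p <- m[idx[, k], , drop = FALSE]
      v <- p[2, ] - p[1, ]
      w <- p[3, ] - p[1, ]
      cr <- c(
        v[2] * w[3] - v[3] * w[2],
        v[3] * w[1] - v[1] * w[3],
        v[1] * w[2] - v[2] * w[1]
      )
      h <- sqrt(sum(cr^2)) / sqrt(sum(v^2))
      if (h < min_height_um) {
        return(FALSE)
      }
    }
    TRUE
  }
  blk <- withr::with_seed(seed, {
    tg <- NULL
    for (i in 1:1000) {
      cand <- draw()
      if (ok(cand)) {
        tg <- cand
        break
      }
    }
    if (is.null(tg)) {
      stop("could not place targets after 1000 attempts", call. = FALSE)
    }
    virtual_block(frame, tg)
  })
  attr(blk, "seed") <- seed
  blk
}

#' Organ-scale phantom presets
#'
#' Blocks at the three organ scales of the application study: aortic root
#' (6 x 6 x 5 mm, three valve-midpoint targets), orbit (12 x 8 x 6 mm, the
#' two endpoints of the intraorbital optic nerve: in the optic duct and at
#' the connection with the eyeball) and thorax (25 x 25 x 17 mm, the
#' tracheal center at the first-rib level and the tracheal bifurcation).
#' Frame dimensions are the study's; target placements are plausible
#' synthetic geometry, not anatomical measurements.
#'
#' @param name One of `"aortic_root"`, `"orbit"`, `"thorax"`.
#' @return A [virtual_block()].
#' @examples
#' organ_preset("aortic_root")$frame
#' @export
organ_preset <- function(name = c("aortic_root", "orbit", "thorax")) {
  name <- match.arg(name)
  switch(name,
    aortic_root = virtual_block(
      block_frame(6000, 6000, 5000),
      tibble::tibble(
        name = c("left_valve", "right_valve", "posterior_valve"),
        x_um = 3000 + 900 * cos(2 * pi * (0:2) / 3 + pi / 2),
        y_um = 3000 + 900 * sin(2 * pi * (0:2) / 3 + pi / 2),
        z_um = c(2400, 2600, 2500),
        radius_um = 250
      )
    ),
    orbit = virtual_block(
      block_frame(12000, 8000, 6000),
      tibble::tibble(
        name = c("nerve_duct", "nerve_eyeball"),
        x_um = c(2500, 9000),
        y_um = c(4200, 3800),
        z_um = c(2600, 3200),
        radius_um = 300
      )
    ),
    thorax = virtual_block(
      block_frame(25000, 25000, 17000),
      tibble::tibble(
        name = c("trachea_first_rib", "trachea_bifurcation"),
        x_um = c(12500, 12800),
        y_um = c(13500, 12000),
        z_um = c(5000, 9500),
        radius_um = 600
      )
    )
  )
}

#' Add measurement noise to section observations
#'
#' Emulates reading coordinates off 100 µm grid paper: Gaussian jitter on the
#' in-plane centroid coordinates followed by quantization to the grid; the
#' advance (Z) readout is quantized without jitter. Seeded and reproducible.
#'
#' @param obs Observation tibble (see [simulate_cut()]).
#' @param grid_um Measurement grid, µm (default 100).
#' @param jitter_sd_um Standard deviation of the in-plane jitter, µm.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param quantize_advance Whether to quantize `advance_um` too (default
#'   TRUE).
#' @return The observations with noisy, grid-quantized coordinates.
#' @export
add_measurement_noise <- function(obs, grid_um = 100, jitter_sd_um = 50,
                                  seed = NULL, quantize_advance = TRUE) {
  stopifnot(grid_um > 0, jitter_sd_um >= 0)
  obs <- tibble::as_tibble(obs)
  apply_noise <- function() {
    i <- which(obs$present)
    obs$x_um[i] <- quantize_measurement(
      obs$x_um[i] + stats::rnorm(length(i), 0, jitter_sd_um), grid_um
    )
    obs$y_um[i] <- quantize_measurement(
      obs$y_um[i] + stats::rnorm(length(i), 0, jitter_sd_um), grid_um
    )
    if (quantize_advance) {
      obs$advance_um <- quantize_measurement(obs$advance_um, grid_um)
    }
    obs
  }
  if (is.null(seed)) apply_noise() else withr::with_seed(seed, apply_noise())
}

#' Render a section observation as a raster image
#'
#' Draws the section as a grid-overlay figure: white background, red grid
#' lines every millimetre, and filled disks for each present target at its
#' centroid and cross-section radius. Deterministic for identical input.
#'
#' @param obs Observation tibble for a single section (one `section_index`).
#' @param frame A [block_frame()].
#' @param um_per_px Image scale, µm per pixel (default 50).
#' @param grid_um Grid spacing, µm (default 1000).
#' @return An `height x width x 3` RGB array in `[0, 1]`; write it with
#'   `png::writePNG()` if a file is needed.
#' @export
render_section <- function(obs, frame, um_per_px = 50, grid_um = 1000) {
  stopifnot(inherits(frame, "block_frame"), um_per_px > 0, grid_um > 0)
  obs <- tibble::as_tibble(obs)
  if ("section_index" %in% names(obs) &&
    length(unique(obs$section_index)) > 1) {
    stop("render_section expects a single section", call. = FALSE)
  }
  w <- ceiling(frame$footprint_x / um_per_px) + 1
  h <- ceiling(frame$footprint_y / um_per_px) + 1
  img <- array(1, dim = c(h, w, 3))
  # red grid (image row 1 = y 0 at the plate edge)
  gx <- round(seq(0, frame$footprint_x, by = grid_um) / um_per_px) + 1
  gy <- round(seq(0, frame$footprint_y, by = grid_um) / um_per_px) + 1
  img[gy, , 2:3] <- 0.75
  img[, gx, 2:3] <- 0.75
  palette <- c("#d62728", "#2ca02c", "#1f77b4", "#9467bd", "#8c564b", "#e377c2")
  hit <- obs[obs$present %in% TRUE, ]
  if (nrow(hit) > 0) {
    cols <- grDevices::col2rgb(
      palette[(match(hit$target, unique(hit$target)) - 1) %% length(palette) + 1]
    ) / 255
    xs <- (seq_len(w) - 1) * um_per_px
    ys <- (seq_len(h) - 1) * um_per_px
    for (k in seq_len(nrow(hit))) {
      dx <- outer(rep(1, h), xs - hit$x_um[k])
      dy <- outer(ys - hit$y_um[k], rep(1, w))
      disk <- dx^2 + dy^2 <= hit$radius_um[k]^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[disk] <- cols[ch, k]
        img[, , ch] <- plane
      }
    }
  }
  img
}
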