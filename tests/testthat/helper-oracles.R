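# Independent oracles used across the suite: plain arithmetic, no calls into
# the geometry under test.

# unsigned point-plane distance from the Hessian normal form
dist_oracle <- function(normal, point_on_plane, p) {
  n <- normal / sqrt(sum(normal^2))
  abs(sum(n * (p - point_on_plane)))
}

# tilt from an explicit cross product of two in-plane vectors
tilt_oracle_deg <- function(p1, p2, p3) {
  v <- p2 - p1
  w <- p3 - p1
  n <- c(
    v[2] * w[3] - v[3] * w[2],
    v[3] * w[1] - v[1] * w[3],
    v[1] * w[2] - v[2] * w[1]
  )
  acos(abs(n[3]) / sqrt(sum(n^2))) * 180 / pi
}

# sum of squared orthogonal residuals of points to the plane (normal, d0)
sse_oracle <- function(normal, offset, pts) {
  n <- normal / sqrt(sum(normal^2))
  sum((pts %*% n - offset)^2)
}

targets_df <- function(m, names = paste0("P", seq_len(nrow(m))), radius = NULL) {
  df <- tibble::tibble(
    name = names, x_um = m[, 1], y_um = m[, 2], z_um = m[, 3]
  )
  if (!is.null(radius)) df$radius_um <- radius
  df
}

# one full localize -> plan -> cut pipeline run on a random phantom;
# returns TRUE when a single collected section contains all targets
run_recovery_pipeline <- function(seed, jitter_sd_um = 50, grid_um = 100,
                                  radius_range = c(250, 500)) {
  ok <- tryCatch(
    {
      blk <- random_block(seed = seed, radius_range = radius_range)
      survey <- plan_serial_survey(blk$frame$height)
      obs <- simulate_cut(blk, face_plane(blk$frame), survey, mirror = TRUE)
      noisy <- add_measurement_noise(
        obs,
        grid_um = grid_um, jitter_sd_um = jitter_sd_um, seed = seed + 10000L
      )
      reg <- register_observations(noisy, blk$frame, mirror = TRUE)
      centers <- estimate_centers(reg)
      plan <- plan_cut(centers, blk$frame, allow_infeasible = TRUE)
      cut_obs <- simulate_cut(blk, plan$planes$virtual, plan$schedule)
      any(tapply(cut_obs$present, cut_obs$section_index, all))
    },
    error = function(e) FALSE
  )
  isTRUE(ok)
}
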