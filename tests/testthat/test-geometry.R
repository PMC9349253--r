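test_that("plane through three targets contains them and is Z-oriented", {
  tg <- three_target_model()$targets
  pl <- plane_through_targets(tg)
  m <- cbind(tg$x_um, tg$y_um, tg$z_um)
  for (i in 1:3) {
    expect_lt(dist_oracle(pl$normal, pl$point, m[i, ]), 1e-6)
  }
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-9)
  expect_gt(pl$normal[3], 0)
})

test_that("coplanar-with-bottom targets give a horizontal plane", {
  tg <- targets_df(rbind(
    c(1000, 1000, 5000), c(8000, 2000, 5000), c(4000, 7000, 5000)
  ))
  pl <- plane_through_targets(tg)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(tilt_angle(pl), 0)
})

test_that("degenerate target sets are rejected with the offending names", {
  col <- targets_df(rbind(c(0, 0, 0), c(1000, 0, 0), c(2000, 0, 0)),
    names = c("a", "b", "c")
  )
  expect_error(plane_through_targets(col), "degenerate.*a, b, c")
  expect_error(fit_plane(col), "degenerate")
  dup <- targets_df(rbind(c(1, 1, 1), c(1, 1, 1), c(5, 5, 5)))
  expect_error(plane_through_targets(dup), "degenerate")
})

test_that("fit_plane with n = 3 matches the exact construction", {
  tg <- three_target_model()$targets
  a <- plane_through_targets(tg)
  b <- fit_plane(tg)
  expect_lt(sum(abs(a$normal - b$normal)), 1e-9)
})

test_that("fit_plane recovers a known plane from exact points", {
  n <- c(1, 2, 5) / sqrt(30)
  offset <- 4000
  # four in-plane points: z chosen so n . p = offset
  xy <- rbind(c(500, 800), c(4000, 1000), c(2500, 6000), c(7000, 3000))
  z <- (offset - xy %*% n[1:2]) / n[3]
  pts <- cbind(xy, z)
  pl <- fit_plane(targets_df(pts))
  expect_lt(max(abs(pts %*% pl$normal - sum(pl$normal * pl$point))), 1e-6)
  expect_lt(acos(min(abs(sum(pl$normal * n)), 1)), 1e-9)
})

test_that("fit_plane is the orthogonal least-squares optimum under z-noise", {
  set.seed(42)
  n_true <- c(0.1, -0.2, 1)
  n_true <- n_true / sqrt(sum(n_true^2))
  offset <- 5000
  xy <- cbind(runif(100, 0, 10000), runif(100, 0, 8000))
  z <- (offset - xy %*% n_true[1:2]) / n_true[3]
  eps <- 25
  noise <- rep(c(eps, -eps), 50) # symmetric, mean zero
  pts <- cbind(xy, z + noise)
  pl <- fit_plane(targets_df(pts))
  # fitted normal close to truth
  ang <- acos(min(abs(sum(pl$normal * n_true)), 1))
  expect_lt(ang, 0.005)
  # brute force over a grid of candidate normals: none beats the fit
  fit_sse <- sse_oracle(pl$normal, sum(pl$normal * pl$point), pts)
  best <- Inf
  for (az in seq(0, 350, by = 10) * pi / 180) {
    for (el in seq(0, 30, by = 2) * pi / 180) {
      cand <- c(sin(el) * cos(az), sin(el) * sin(az), cos(el))
      off <- mean(pts %*% cand)
      best <- min(best, sse_oracle(cand, off, pts))
    }
  }
  expect_lte(fit_sse, best + 1e-9)
})

test_that("tilt angle matches constructed and oracle values", {
  expect_equal(tilt_angle(cutting_plane(c(0, 0, 1), c(0, 0, 0))), 0)
  p1 <- c(0, 0, 0)
  p2 <- c(10000, 0, 0)
  p3 <- c(0, 10000, tan(10 * pi / 180) * 10000)
  pl <- plane_through_targets(targets_df(rbind(p1, p2, p3)))
  expect_equal(tilt_angle(pl), 10, tolerance = 1e-9)
  tg <- three_target_model()$targets
  m <- cbind(tg$x_um, tg$y_um, tg$z_um)
  expect_equal(
    tilt_angle(plane_through_targets(tg)),
    tilt_oracle_deg(m[1, ], m[2, ], m[3, ]),
    tolerance = 1e-9
  )
})

test_that("tilt is invariant under normal flip and in-plane rotation about Z", {
  tg <- three_target_model()$targets
  pl <- plane_through_targets(tg)
  flipped <- cutting_plane(-pl$normal, pl$point)
  expect_equal(tilt_angle(flipped), tilt_angle(pl))
  th <- 37 * pi / 180
  rot <- tg
  rot$x_um <- tg$x_um * cos(th) - tg$y_um * sin(th) + 6000
  rot$y_um <- tg$x_um * sin(th) + tg$y_um * cos(th) + 2000
  expect_equal(
    tilt_angle(plane_through_targets(rot)), tilt_angle(pl),
    tolerance = 1e-9
  )
})

test_that("feasibility verdict follows the cryostat angle capacity", {
  flat <- cutting_plane(c(0, 0, 1), c(0, 0, 0))
  f <- check_feasibility(flat)
  expect_true(f$feasible)
  expect_equal(f$wedge_deg, 0)
  tilted29 <- cutting_plane(c(sin(29 * pi / 180), 0, cos(29 * pi / 180)), c(0, 0, 0))
  f29 <- check_feasibility(tilted29, capacity_deg = 20)
  expect_false(f29$feasible)
  expect_equal(f29$wedge_deg, 9, tolerance = 1e-9)
  tilted20 <- cutting_plane(c(sin(20 * pi / 180), 0, cos(20 * pi / 180)), c(0, 0, 0))
  expect_true(check_feasibility(tilted20, capacity_deg = 20)$feasible)
  expect_error(check_feasibility(flat, capacity_deg = 0), "capacity")
  expect_error(check_feasibility(flat, capacity_deg = 95), "capacity")
})

test_that("mirror transform is an involution preserving z and distances", {
  fr <- block_frame(10000, 8000, 8000)
  set.seed(7)
  pts <- tibble::tibble(
    name = paste0("p", 1:5),
    x_um = runif(5, 0, 10000),
    y_um = runif(5, 0, 8000),
    z_um = runif(5, 0, 8000)
  )
  mm <- mirror_x(mirror_x(pts, fr), fr)
  expect_equal(mm, pts)
  m1 <- mirror_x(pts, fr)
  expect_equal(m1$z_um, pts$z_um)
  expect_equal(m1$y_um, pts$y_um)
  d0 <- dist(cbind(pts$x_um, pts$y_um, pts$z_um))
  d1 <- dist(cbind(m1$x_um, m1$y_um, m1$z_um))
  expect_equal(as.numeric(d1), as.numeric(d0))
  # hand-computed reflection about the origin plane: x -> -x
  expect_equal(m1$x_um, -pts$x_um)
  on_axis <- tibble::tibble(name = "o", x_um = 0, y_um = 3, z_um = 9)
  expect_equal(mirror_x(on_axis, fr), on_axis)
})

test_that("cutting-forward distance follows the 1/cos(tilt) law", {
  fr <- block_frame(10000, 8000, 8000)
  flat <- cutting_plane(c(0, 0, 1), c(0, 0, -6000))
  target <- cutting_plane(c(0, 0, 1), c(0, 0, 0))
  expect_equal(cutting_forward_distance(target, c(5000, 4000), fr, flat), 6000)
  th <- 10 * pi / 180
  n <- c(sin(th), 0, cos(th))
  start <- cutting_plane(n, c(5000, 4000, 0) - 6000 * n)
  tgt <- cutting_plane(n, c(5000, 4000, 0))
  expect_equal(
    cutting_forward_distance(tgt, c(5000, 4000), fr, start),
    6000 / cos(th),
    tolerance = 1e-9
  )
  # non-parallel planes rejected
  other <- cutting_plane(c(0.2, 0, 1), c(0, 0, -6000))
  expect_error(cutting_forward_distance(target, c(5000, 4000), fr, other), "parallel")
  # mark behind the start plane rejected
  behind <- cutting_plane(c(0, 0, 1), c(0, 0, 500))
  expect_error(
    cutting_forward_distance(target, c(5000, 4000), fr, behind),
    "behind"
  )
  # mark must lie on the bottom face
  expect_error(
    cutting_forward_distance(target, c(-50, 4000), fr, flat),
    "bottom face"
  )
})
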