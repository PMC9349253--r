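test_that("sphere presence matches the depth-interval oracle under a flat survey", {
  fr <- block_frame(10000, 8000, 8000)
  blk <- virtual_block(fr, targets_df(rbind(c(5000, 4000, 6000)), "S", radius = 500))
  obs <- simulate_cut(blk, face_plane(fr), plan_serial_survey(8000))
  mids <- obs$advance_um
  expect_equal(obs$present, mids > 5500 & mids < 6500)
  hit <- obs[obs$present, ]
  expect_equal(hit$x_um, rep(5000, nrow(hit)))
  expect_equal(hit$radius_um, sqrt(500^2 - (hit$advance_um - 6000)^2))
  # presence interval length ~ 2 r within one survey step
  expect_equal(nrow(hit), 10, tolerance = 1)
})

test_that("a plane missing all spheres yields only absent observations", {
  fr <- block_frame(10000, 8000, 8000)
  blk <- virtual_block(fr, targets_df(rbind(c(5000, 4000, 6000)), "S", radius = 300))
  short <- plan_serial_survey(3000) # never reaches the sphere
  obs <- simulate_cut(blk, face_plane(fr), short)
  expect_true(all(!obs$present))
  expect_true(all(is.na(obs$x_um)))
})

test_that("aligned virtual plane delivers a section with all targets present", {
  blk <- three_target_model()
  plan <- plan_cut(blk$targets, blk$frame)
  obs <- simulate_cut(blk, plan$planes$virtual, plan$schedule)
  joint <- tapply(obs$present, obs$section_index, all)
  expect_true(any(joint))
  # and the joint section sits at the expected advance
  joint_mid <- unique(obs$advance_um[obs$section_index %in%
    names(joint)[joint]])
  expect_true(any(abs(joint_mid - plan$expected_advance_um) <= 3.5))
})

test_that("cross-section centroid equals the orthogonal projection of the center", {
  fr <- block_frame(10000, 8000, 8000)
  ctr <- c(5000, 4000, 5000)
  blk <- virtual_block(fr, targets_df(rbind(ctr), "S", radius = 400))
  th <- 12 * pi / 180
  n <- c(sin(th), 0, cos(th))
  blade0 <- cutting_plane(n, c(0, 0, 0))
  plan <- plan_schedule(6000, 20, 7, 1000)
  obs <- simulate_cut(blk, blade0, plan)
  hit <- obs[obs$present, ]
  for (i in seq_len(nrow(hit))) {
    mid_plane_point <- c(0, 0, hit$advance_um[i])
    d <- sum(n * (ctr - mid_plane_point)) # signed distance oracle
    proj <- ctr - d * n
    expect_equal(hit$x_um[i], proj[1], tolerance = 1e-9)
    expect_equal(hit$y_um[i], proj[2], tolerance = 1e-9)
    expect_equal(hit$radius_um[i], sqrt(400^2 - d^2), tolerance = 1e-9)
  }
})

test_that("actual hit advances match depths and the distance operation", {
  fr <- block_frame(10000, 8000, 8000)
  blk <- virtual_block(fr, targets_df(rbind(c(5000, 4000, 6000)), "S", radius = 300))
  hits <- actual_hit_advances(blk, face_plane(fr))
  expect_equal(hits$advance_um, 6000)
  # tilted blade: advance = mark advance + depth (footprint consistency)
  th <- 15 * pi / 180
  n <- c(sin(th) / sqrt(2), sin(th) / sqrt(2), cos(th))
  blade <- cutting_plane(n, c(0, 0, 0))
  tg3 <- three_target_model()
  hits3 <- actual_hit_advances(tg3$targets |> (\(d) virtual_block(fr, d))(), blade)
  for (i in 1:3) {
    mark_adv <- cutting_forward_distance(
      blade, c(tg3$targets$x_um[i], tg3$targets$y_um[i]), fr, blade
    )
    expect_equal(hits3$advance_um[i], mark_adv + tg3$targets$z_um[i],
      tolerance = 1e-9
    )
  }
  # perfectly aligned coplanar targets share one advance
  plan <- plan_cut(tg3$targets, tg3$frame)
  adv <- actual_hit_advances(tg3, plan$planes$virtual)
  expect_lt(diff(range(adv$advance_um)), 1e-9)
  expect_equal(adv$advance_um[1], plan$expected_advance_um, tolerance = 1e-9)
})

test_that("mirrored sections register back to block coordinates", {
  blk <- three_target_model()
  survey <- plan_serial_survey(blk$frame$height)
  plain <- simulate_cut(blk, face_plane(blk$frame), survey)
  mirrored <- simulate_cut(blk, face_plane(blk$frame), survey, mirror = TRUE)
  hit <- plain$present
  expect_equal(mirrored$x_um[hit], -plain$x_um[hit])
  back <- register_observations(mirrored, blk$frame, mirror = TRUE)
  expect_equal(back$x_um[hit], plain$x_um[hit])
  expect_equal(back$y_um[hit], plain$y_um[hit])
})

test_that("virtual blocks reject spheres poking out of the frame", {
  fr <- block_frame(10000, 8000, 8000)
  expect_error(
    virtual_block(fr, targets_df(rbind(c(200, 4000, 5000)), "S", radius = 300)),
    "inside the frame"
  )
  expect_error(
    virtual_block(fr, targets_df(rbind(c(5000, 4000, 5000)), "S", radius = 0)),
    "positive"
  )
})
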