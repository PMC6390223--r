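start <- study_layout()$start

test_that("visibility side is the acting-hand side of the long axis", {
  expect_equal(visibility_side(object_pose(theta = 0)), 1)
  expect_equal(visibility_side(object_pose(theta = 150)), -1)
  expect_equal(visibility_side(object_pose(theta = 60)), 1)
  expect_error(visibility_side(object_pose(theta = 90)), "undefined")
  # left hand prefers the opposite side
  expect_equal(visibility_side(object_pose(theta = 60), hand = "left"), -1)
})

test_that("reach side minimises the candidate-to-start distance", {
  expect_equal(reach_side(object_pose(theta = 150), start, 1.5), -1)
  expect_equal(reach_side(object_pose(theta = 60), start, 1.5), -1)
  expect_equal(reach_side(object_pose(theta = 0), start, 1.5), 1)
  expect_error(reach_side(object_pose(theta = 60), start, 0), "positive")
  # start on the midline plane of a y-aligned axis: equidistant candidates
  expect_error(reach_side(object_pose(theta = 90), c(26, 0, 0), 1), "equidistant")
})

test_that("predictions transfer the bias to the correct side of the midline", {
  pose60 <- object_pose(theta = 60)
  vis <- build_prediction("visibility", 2, pose60, start)
  rch <- build_prediction("reach", 2, pose60, start)
  expect_equal(vis$center, c(1.0, 1.7320508, 0), tolerance = 1e-7)
  expect_equal(rch$center, c(-1.0, -1.7320508, 0), tolerance = 1e-7)
  expect_equal(vis$u_offset, 2)
  expect_equal(rch$u_offset, -2)

  # hypotheses agree at the reference orientation
  pose150 <- object_pose(theta = 150)
  vis150 <- build_prediction("visibility", 2, pose150, start)
  rch150 <- build_prediction("reach", 2, pose150, start)
  expect_equal(vis150$center, c(1.7320508, -1.0, 0), tolerance = 1e-7)
  expect_equal(rch150$center, vis150$center)

  # zero bias: both at the object centre
  expect_equal(build_prediction("visibility", 0, pose60, start)$center, c(0, 0, 0))
  expect_equal(build_prediction("reach", 0, pose60, start)$center, c(0, 0, 0))

  # contacts satisfy the surface-contact contract
  expect_equal(sqrt(sum((vis$thumb - vis$index)^2)), 2 * pose60$radius)
  expect_equal(to_object_frame((vis$thumb + vis$index) / 2, pose60)[["u"]],
               vis$u_offset, tolerance = 1e-9)

  # bias_estimate container is accepted
  be <- bias_estimate(2, 150, "group")
  expect_equal(build_prediction("visibility", be, pose60, start)$center, vis$center)
})

test_that("predictions are scale-equivariant in the bias magnitude", {
  pose <- object_pose(theta = 60)
  for (hyp in c("visibility", "reach")) {
    u1 <- build_prediction(hyp, 1, pose, start)$u_offset
    for (b in c(0.5, 2, 3.7)) {
      expect_equal(build_prediction(hyp, b, pose, start)$u_offset, b * u1)
    }
  }
})

test_that("the study design decouples the hypotheses only at 60 degrees", {
  # at 150 degrees the predictions coincide; at 60 they are antipodal
  for (b in c(0.5, 1.5, 3)) {
    p150v <- build_prediction("visibility", b, object_pose(theta = 150), start)
    p150r <- build_prediction("reach", b, object_pose(theta = 150), start)
    expect_equal(p150v$center, p150r$center, tolerance = 1e-12)
    p60v <- build_prediction("visibility", b, object_pose(theta = 60), start)
    p60r <- build_prediction("reach", b, object_pose(theta = 60), start)
    expect_equal(p60v$u_offset, -p60r$u_offset, tolerance = 1e-12)
    expect_equal(p60v$center, -p60r$center, tolerance = 1e-12)
  }
})

test_that("mirror property: a left hand starting on the left sees mirrored geometry", {
  mirror_x <- function(p) c(-p[1], p[2], p[3])
  set.seed(61)
  for (i in 1:20) {
    theta <- stats::runif(1, 0, 180)
    if (abs(theta - 90) < 5) next
    pose <- object_pose(theta = theta)
    pose_m <- object_pose(theta = (180 - theta) %% 180)
    b <- stats::runif(1, 0.5, 3)
    vis <- build_prediction("visibility", b, pose, start, hand = "right")
    vis_m <- build_prediction("visibility", b, pose_m, mirror_x(start), hand = "left")
    expect_equal(vis_m$center, mirror_x(vis$center), tolerance = 1e-9)
    rch <- build_prediction("reach", b, pose, start)
    rch_m <- build_prediction("reach", b, pose_m, mirror_x(start))
    expect_equal(rch_m$center, mirror_x(rch$center), tolerance = 1e-9)
  }
})
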