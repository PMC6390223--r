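test_that("object_pose validates and normalises its inputs", {
  p <- object_pose(theta = 210)
  expect_equal(p$theta, 30)
  expect_error(object_pose(theta = 0, length = 2, radius = 1.25),
               "length must exceed")
  expect_error(object_pose(theta = 0, length = -1), "positive")
})

test_that("object-frame transform matches hand-computed projections", {
  pose <- object_pose(center = c(1, 2, 3), theta = 0)
  expect_equal(unname(to_object_frame(pose$center, pose)), c(0, 0, 0))
  expect_equal(to_object_frame(pose$center + c(2, 0, 0), pose)[["u"]], 2)

  pose60 <- object_pose(theta = 60)
  q <- to_object_frame(c(1.0, 1.7320508, 0), pose60)
  expect_equal(q[["u"]], 2.0, tolerance = 1e-7)
  expect_equal(q[["v"]], 0, tolerance = 1e-7)
})

test_that("object-frame round-trip is the identity for random points and poses", {
  set.seed(42)
  for (i in 1:50) {
    pose <- random_pose()
    pts <- matrix(stats::runif(60, -20, 20), ncol = 3)
    back <- from_object_frame(to_object_frame(pts, pose), pose)
    expect_lt(max(abs(back - pts)), 1e-9)
  }
})

test_that("the long axis is undirected: theta and theta + 180 agree", {
  set.seed(7)
  pts <- matrix(stats::runif(30, -10, 10), ncol = 3)
  for (theta in c(0, 30, 60, 150, 179.5)) {
    a <- object_pose(theta = theta)
    b <- object_pose(theta = theta + 180)
    expect_equal(to_object_frame(pts, a), to_object_frame(pts, b))
  }
})

test_that("grasp_summary computes centre, midline deviation and axis angle", {
  pose <- object_pose(theta = 0, length = 10, radius = 1.25)
  # symmetric perpendicular grasp about the centre
  r <- record_from_contacts(c(0, -1.25, 0), c(0, 1.25, 0))
  s <- grasp_summary(r, pose)
  expect_equal(s$u, 0)
  expect_equal(s$grasp_axis_angle, 90)
  expect_equal(c(s$center_x, s$center_y, s$center_z), c(0, 0, 0))

  # digits collinear with the long axis at u = 1 and u = 3
  r2 <- record_from_contacts(c(1, 0, 0), c(3, 0, 0))
  s2 <- grasp_summary(r2, pose)
  expect_equal(s2$u, 2)
  expect_equal(s2$grasp_axis_angle, 0)

  # theta = 150: contacts built at u = -1.5 round-trip through the summary
  pose150 <- object_pose(theta = 150)
  cc <- surface_contacts(pose150, u_offset = -1.5)
  s3 <- grasp_summary(record_from_contacts(cc$thumb, cc$index), pose150)
  expect_equal(s3$u, -1.5, tolerance = 1e-9)
  expect_equal(s3$grasp_axis_angle, 90, tolerance = 1e-9)
  expect_equal(c(s3$center_x, s3$center_y),
               c(1.299038, -0.75), tolerance = 1e-6)

  expect_error(grasp_summary(record_from_contacts(c(1, 1, 1), c(1, 1, 1)), pose),
               "degenerate grasp")
})

test_that("long-axis grasps are flagged by the angle threshold", {
  pose <- object_pose(theta = 0)
  perp <- record_from_contacts(c(0, -1.25, 0), c(0, 1.25, 0))
  along <- record_from_contacts(c(5, 0, 0), c(2.5, 0, 0))
  expect_false(is_long_axis_grasp(perp, pose))
  expect_true(is_long_axis_grasp(along, pose))
  # 30-degree grasp axis: flagged under the default 45-degree threshold
  a30 <- 30 * pi / 180
  oblique <- record_from_contacts(2 * c(cos(a30), sin(a30), 0),
                                  -2 * c(cos(a30), sin(a30), 0))
  expect_true(is_long_axis_grasp(oblique, pose))
  expect_false(is_long_axis_grasp(oblique, pose, angle_threshold = 20))
})

test_that("surface contacts sit diametrically opposite at the requested offset", {
  pose <- object_pose(theta = 0, radius = 1.25)
  cc <- surface_contacts(pose, 0)
  expect_equal(cc$thumb, c(0, -1.25, 0))
  expect_equal(cc$index, c(0, 1.25, 0))

  # theta = 90: equal y, tie broken toward smaller x for the thumb
  cc90 <- surface_contacts(object_pose(theta = 90, radius = 1.25), 0)
  expect_equal(cc90$thumb, c(-1.25, 0, 0))
  expect_equal(cc90$index, c(1.25, 0, 0))

  cc_far <- surface_contacts(pose, 0, thumb_side = "far")
  expect_equal(cc_far$thumb, cc$index)

  set.seed(11)
  for (i in 1:25) {
    pose_i <- random_pose()
    u_off <- stats::runif(1, -pose_i$length / 2, pose_i$length / 2)
    cc_i <- surface_contacts(pose_i, u_off)
    expect_equal(sqrt(sum((cc_i$thumb - cc_i$index)^2)), 2 * pose_i$radius,
                 tolerance = 1e-9)
    mid_u <- to_object_frame((cc_i$thumb + cc_i$index) / 2, pose_i)[["u"]]
    expect_equal(mid_u, u_off, tolerance = 1e-9)
    expect_lte(cc_i$thumb[2], cc_i$index[2] + 1e-12)
  }

  expect_error(surface_contacts(pose, 5.1), "off the object")
})

test_that("reach distance reproduces the study layout and metric axioms", {
  layout <- study_layout()
  expect_equal(round(reach_distance(layout$start, c(0, 0, 0))), 36)
  expect_equal(reach_distance(layout$start, c(0, 0, 0)), sqrt(1301))
  expect_equal(reach_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(reach_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(5)
  for (i in 1:200) {
    a <- stats::runif(3, -10, 10); b <- stats::runif(3, -10, 10); c0 <- stats::runif(3, -10, 10)
    expect_equal(reach_distance(a, b), reach_distance(b, a))
    expect_lte(reach_distance(a, c0),
               reach_distance(a, b) + reach_distance(b, c0) + 1e-12)
  }
})

test_that("reflection across the midline flips u and preserves v, w", {
  set.seed(9)
  pose <- random_pose()
  recs <- random_records(20)
  refl <- reflect_across_midline(recs, pose)
  s0 <- grasp_summary(recs, pose)
  s1 <- grasp_summary(refl, pose)
  expect_equal(s1$u, -s0$u, tolerance = 1e-9)
  expect_equal(s1$v, s0$v, tolerance = 1e-9)
  expect_equal(s1$w, s0$w, tolerance = 1e-9)
  expect_equal(s1$grasp_axis_angle, s0$grasp_axis_angle, tolerance = 1e-9)
  # involution
  expect_equal(as.data.frame(reflect_across_midline(refl, pose)),
               as.data.frame(recs), tolerance = 1e-9)
})
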