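test_that("segment masses conserve total body mass", {
  for (m in c(50, 75, 110)) {
    p <- build_pedestrian(1.75, m)
    expect_equal(sum(p$segments$mass), m, tolerance = 1e-12)
  }
})

test_that("segment lengths scale linearly with stature", {
  p1 <- build_pedestrian(1.75, 75)
  p2 <- build_pedestrian(1.925, 75)  # x 1.1
  expect_equal(p2$segments$length, p1$segments$length * 1.1,
               tolerance = 1e-12)
  # widths scale with stature too
  expect_equal(p2$segments$a, p1$segments$a * 1.1, tolerance = 1e-12)
})

test_that("walking posture puts the right leg forward, left leg back", {
  post <- posture_preset("walking_arms_in_pockets")
  expect_gt(post[["hip_r_flexion"]], 0)
  expect_lt(post[["hip_l_flexion"]], 0)
  # and the posed feet actually straddle the facing direction
  p <- build_pedestrian(1.75, 75)
  pose <- pedrecon:::.pose_pedestrian(p)
  idx <- setNames(seq_len(nrow(p$segments)), p$segments$name)
  expect_gt(pose$pos[idx[["leg_r"]], 1], pose$pos[idx[["leg_l"]], 1])
})

test_that("anthropometry outside the supported range is rejected", {
  expect_error(build_pedestrian(0.9, 75), "height")
  expect_error(build_pedestrian(2.5, 75), "height")
  expect_error(build_pedestrian(1.75, 20), "mass")
  expect_error(build_pedestrian(1.75, 200), "mass")
})

test_that("posture angles beyond a joint stop are rejected with the joint name", {
  expect_error(build_pedestrian(1.75, 75, posture = c(hip_r_flexion = 2.5)),
               "hip_r")
})

test_that("the model carries the four study markers on a kinematic tree", {
  p <- build_pedestrian(1.75, 75)
  expect_setequal(names(p$markers),
                  c("shoulder_r", "thigh_mid_r", "calf_mid_r", "head_vertex"))
  # tree: every segment except the root appears exactly once as a child
  children <- p$joints$child
  expect_equal(anyDuplicated(children), 0L)
  expect_equal(sort(c("pelvis", children)), sort(p$segments$name))
  expect_true(all(p$segments$a > 0 & p$segments$b > 0 & p$segments$cz > 0))
})

test_that("unknown posture presets are rejected", {
  expect_error(build_pedestrian(1.75, 75, posture = "sprinting"), "preset")
})
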