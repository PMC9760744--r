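# Integrator and contact-model checks against closed forms and mechanical
# invariants.

test_that("a free segment dropped from 2 m follows the free-fall closed form", {
  m <- pedrecon:::.single_segment_model(5, c(0.1, 0.1, 0.1), center_z = 2)
  sc <- scenario(m, vehicle = NULL, design = NULL, dt = 2e-5, t_end = 0.5,
                 settle = FALSE)
  res <- simulate_impact(sc)
  z_final <- res$pos[length(res$time), 3]
  expect_equal(z_final, 2 - 0.5 * 9.81 * 0.25, tolerance = 1e-3)
})

test_that("mechanical energy never increases during contact-free flight", {
  m <- pedrecon:::.single_segment_model(5, c(0.1, 0.08, 0.15), center_z = 10)
  sc <- scenario(m, vehicle = NULL, design = NULL, dt = 2e-5, t_end = 0.6,
                 settle = FALSE)
  res <- simulate_impact(sc)
  seg <- m$segments
  I <- c(seg$Ix, seg$Iy, seg$Iz)
  E <- vapply(seq_along(res$time), function(i) {
    v <- res$vel[i, 1:3]; w <- res$angvel[i, 1:3]
    0.5 * 5 * sum(v^2) + 5 * 9.81 * res$pos[i, 3] + 0.5 * sum(I * w^2)
  }, 0.0)
  # outputs are decimated; allow the per-step tolerance times the stride
  stride <- round(0.001 / sc$dt)
  expect_true(all(diff(E) <= 1e-6 * E[1] * stride))
})

test_that("no vehicle contact occurs when the vehicle is far and stationary", {
  p <- build_pedestrian(1.75, 75)
  v <- default_sedan(braking_decel = 0)
  b <- variable_bounds(c(V = -1, D = 0.14, alpha = 0.30, beta = -0.2,
                         gamma = -0.2),
                       c(V = 1, D = 0.54, alpha = 0.70, beta = 0.2,
                         gamma = 0.2))
  d <- design_vector(0, 0.3, 0.5, 0, 0, bounds = b)
  sc <- scenario(p, v, impact_environment(), d, dt = 5e-4, t_end = 0.3,
                 approach_gap = 30, bounds = b)
  res <- simulate_impact(sc)
  expect_false(any(res$events$surface != "ground"))
})

test_that("the default case scenario reproduces the wrap sequence", {
  p <- build_pedestrian(1.75, 75)
  d <- design_vector(17.3485, 0.3186, 0.6650, 0.0298, -0.1895)
  sc <- scenario(p, default_sedan(), impact_environment(), d,
                 dt = 1e-4, t_end = 1.8)
  res <- simulate_impact(sc)
  t_leg <- first_contact(res, "leg_r", "bumper")
  t_thigh <- first_contact(res, "thigh_r", "bonnet_front")
  t_shoulder <- first_contact(res, "upper_torso", "windscreen")
  t_head_ground <- first_contact(res, "head", "ground")
  # lower extremity first, then upper body on the glass, then head-ground
  expect_false(any(is.na(c(t_leg, t_thigh, t_shoulder, t_head_ground))))
  expect_lt(t_leg, t_shoulder)
  expect_lt(t_thigh, t_shoulder)
  expect_lt(t_shoulder, t_head_ground)
})

test_that("friction force never exceeds mu times the normal force", {
  p <- build_pedestrian(1.75, 75)
  d <- design_vector(18, 0.3, 0.5, 0, 0)
  sc <- scenario(p, default_sedan(), impact_environment(), d,
                 dt = 5e-4, t_end = 1.0)
  res <- simulate_impact(sc, record_forces = TRUE)
  fl <- res$force_log
  expect_gt(nrow(fl), 100)
  expect_true(all(fl$fn >= 0))
  expect_true(all(fl$ft <= fl$mu * fl$fn * (1 + 1e-9)))
})

test_that("the simulation is bit-reproducible", {
  p <- build_pedestrian(1.75, 75)
  d <- design_vector(18, 0.3, 0.5, 0, 0)
  sc <- scenario(p, default_sedan(), impact_environment(), d,
                 dt = 5e-4, t_end = 0.8)
  r1 <- simulate_impact(sc)
  r2 <- simulate_impact(sc)
  expect_identical(r1$pos, r2$pos)
  expect_identical(r1$events, r2$events)
})

test_that("halving and doubling dt moves the final head position < 5 mm", {
  p <- build_pedestrian(1.75, 75)
  # the default (initial-value) design: mid-range speed and offset
  d <- design_vector(18, 0.34, 0.5, 0, 0)
  hp <- lapply(c(4e-5, 2e-5, 1e-5), function(dt) {
    r <- simulate_impact(scenario(p, default_sedan(), impact_environment(),
                                  d, dt = dt, t_end = 1.8))
    tail(pedrecon:::.marker_track(r, "head_vertex"), 1)
  })
  expect_lt(sqrt(sum((hp[[1]] - hp[[2]])^2)), 5e-3)
  expect_lt(sqrt(sum((hp[[2]] - hp[[3]])^2)), 5e-3)
})

test_that("the standing posture is stable without vehicle contact", {
  p <- build_pedestrian(1.75, 75)
  sc <- scenario(p, vehicle = NULL, design = NULL, dt = 1e-4, t_end = 0.25)
  res <- simulate_impact(sc)
  hz <- pedrecon:::.marker_track(res, "head_vertex")[, 3]
  expect_gt(min(hz), 0.9 * hz[1])
})

test_that("first_contact returns the earliest event or NA", {
  fr <- fake_result(seq(0, 1, 0.01), function(t) c(t, 0, 1),
                    events = data.frame(
                      time = c(0.05, 0.02), segment = "body",
                      surface = "ground", x = 0, y = 0, z = 0,
                      peak_force = 1))
  expect_equal(first_contact(fr, "body", "ground"), 0.02)
  expect_true(is.na(first_contact(fr, "body", "bumper")))
  expect_error(first_contact(fr, "femur", "ground"), "unknown segment")
  expect_error(first_contact(fr, "body", "spoiler"), "unknown surface")
})

test_that("a scripted trajectory crossing the ground is detected near the crossing time", {
  # single segment released just above the ground from 1 m: closed-form
  # touch-down of the lowest point at sqrt(2*(1-0.1)/g) = 0.4285 s
  m <- pedrecon:::.single_segment_model(5, c(0.1, 0.1, 0.1), center_z = 1)
  sc <- scenario(m, vehicle = NULL, design = NULL, dt = 2e-4, t_end = 0.6,
                 settle = FALSE)
  res <- simulate_impact(sc)
  t_c <- first_contact(res, "body", "ground")
  expect_equal(t_c, sqrt(2 * 0.9 / 9.81), tolerance = 0.01)
})

test_that("an over-coarse time step triggers the stability warning", {
  p <- build_pedestrian(1.75, 75)
  sc <- scenario(p, vehicle = NULL, design = NULL, dt = 0.05, t_end = 0.2)
  expect_warning(try(simulate_impact(sc), silent = TRUE), "unstable")
})
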