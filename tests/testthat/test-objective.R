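# Objective module: marker distances at first-contact times, aggregation,
# feasibility band.

test_that("aggregate_distances reproduces the printed study sums", {
  # global optima rows: subobjective cells and their printed sums
  d_nsga2 <- c(I = 0.1047, II = 0.0493, III = 0.0142, IV = 0.0239)
  expect_equal(aggregate_distances(d_nsga2, c("I", "II", "III", "IV")),
               0.1921, tolerance = 1e-12)
  d_mopso <- c(I = 0.0612, II = 0.0387, III = 0.0111, IV = 0.1788)
  expect_equal(aggregate_distances(d_mopso, c("I", "II", "III", "IV")),
               0.2898, tolerance = 1e-12)
  # two-pair optimization group, printed cells cover all four pairs: the
  # full-evidence sum vs the group's own objective
  d_g1 <- c(I = 0.0033, II = 0.0352, III = 0.0098, IV = 1.7001)
  expect_equal(aggregate_distances(d_g1, c("I", "II", "III", "IV")),
               1.7484, tolerance = 1e-12)
  expect_equal(aggregate_distances(d_g1, c("I", "II")), 0.0385,
               tolerance = 1e-12)
})

test_that("aggregation is linear, permutation-invariant, and monotone", {
  d <- c(I = 1.0, II = 2.0, III = 0.25, IV = 0.5)
  expect_equal(aggregate_distances(d, c("I", "II")), 3.0)
  expect_equal(aggregate_distances(d, c("II", "I")),
               aggregate_distances(d, c("I", "II")))
  # adding a pair never decreases the sum
  expect_gte(aggregate_distances(d, c("I", "II", "III")),
             aggregate_distances(d, c("I", "II")))
  expect_error(aggregate_distances(d, character(0)), "empty")
  expect_error(aggregate_distances(d[1:2], c("I", "III")), "missing")
})

test_that("marker distance is the Euclidean norm at the first-contact time", {
  times <- seq(0, 1, 0.01)
  ev <- data.frame(time = 0.5, segment = "body", surface = "ground",
                   x = 0, y = 0, z = 0, peak_force = 1)
  # marker rides at the body origin; body fixed at (0,0,0)
  fr <- fake_result(times, function(t) c(0, 0, 0), events = ev)
  pair <- marker_pair("IV", "probe", c(1, 2, 2), frame = "world",
                      contact_segment = "body", contact_surface = "ground")
  md <- marker_distance(fr, pair)
  expect_true(md$contact_found)
  expect_equal(md$distance, 3.0)
  # coincident points give zero
  pair0 <- marker_pair("IV", "probe", c(0, 0, 0), frame = "world",
                       contact_segment = "body", contact_surface = "ground")
  expect_equal(marker_distance(fr, pair0)$distance, 0)
})

test_that("without the contact the minimum distance over time is returned", {
  times <- seq(0, 1, 0.01)
  # body sweeps past the mark at (5,0,0); closest approach at t = 0.5
  fr <- fake_result(times, function(t) c(10 * t, 3, 0))
  pair <- marker_pair("IV", "probe", c(5, 0, 0), frame = "world",
                      contact_segment = "body", contact_surface = "ground")
  md <- marker_distance(fr, pair)
  expect_false(md$contact_found)
  expect_equal(md$distance, 3, tolerance = 1e-9)
})

test_that("feasibility is the 0-2 m band with contacts found", {
  mk_res <- function(d, cf = rep(TRUE, length(d))) {
    feas <- cf & d >= 0 & d <= 2
    structure(list(d = d, F_sum = sum(d), feasible = feas,
                   contact_found = cf, overall_feasible = all(feas),
                   simulation_failed = FALSE), class = "objective_result")
  }
  r <- mk_res(c(I = 0.5, II = 1.9999, IV = 1.7001))
  expect_true(is_feasible(r)$feasible)
  r2 <- mk_res(c(I = 2.5, II = 0.5))
  f2 <- is_feasible(r2)
  expect_false(f2$feasible)
  expect_named(which(!f2$pairs), "I")
  # a missing contact is infeasible even at small distance
  r3 <- mk_res(c(I = 0.5), cf = FALSE)
  expect_false(is_feasible(r3)$feasible)
})

test_that("evaluating the truth against its own evidence is near-zero and feasible", {
  case <- shared_case()
  pairs <- default_marker_pairs(case$evidence)
  r <- evaluate_design(case$true_design, c("I", "II", "III", "IV"), pairs,
                       case$template)
  expect_true(r$overall_feasible)
  expect_lt(r$F_sum, 0.05)
  expect_equal(r$F_sum, aggregate_distances(r$d, c("I", "II", "III", "IV")),
               tolerance = 1e-12)
})

test_that("evaluation is deterministic", {
  case <- shared_case()
  pairs <- default_marker_pairs(case$evidence)
  x <- case$template$bounds$lower + 0.3 *
    (case$template$bounds$upper - case$template$bounds$lower)
  r1 <- evaluate_design(x, c("I", "IV"), pairs, case$template)
  r2 <- evaluate_design(x, c("I", "IV"), pairs, case$template)
  expect_identical(r1$d, r2$d)
})
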