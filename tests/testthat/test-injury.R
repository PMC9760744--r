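# HIC and femur-force banding.

test_that("HIC of a zero trace is zero and a constant pulse is closed-form", {
  t <- seq(0, 0.1, 1e-4)
  expect_equal(hic(t, rep(0, length(t)))$hic, 0)
  # constant 100 g: HIC = window * 100^2.5 with the full window optimal
  h <- hic(t, rep(100, length(t)), max_window = 0.015)
  expect_equal(h$hic, 100^2.5 * 0.015, tolerance = 1e-9)
  expect_equal(h$t2 - h$t1, 0.015, tolerance = 1e-9)
  expect_error(hic(numeric(0), numeric(0)), "empty")
})

test_that("windowed search equals the brute-force window scan", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(100:400, 1)
    t <- seq(0, by = 5e-4, length.out = n)
    # smooth random pulse
    centers <- runif(3, 0, max(t))
    a <- rowSums(vapply(centers, function(c0)
      runif(1, 50, 200) * exp(-((t - c0) / runif(1, 0.003, 0.02))^2),
      numeric(n)))
    h <- hic(t, a, max_window = 0.036)
    expect_equal(h$hic, brute_force_hic(t, a, 0.036),
                 tolerance = 1e-9)
  }
})

test_that("HIC is scale-covariant and monotone in the window and the trace", {
  t <- seq(0, 0.05, 1e-4)
  a <- 80 * exp(-((t - 0.02) / 0.005)^2)
  h1 <- hic(t, a)$hic
  expect_equal(hic(t, 3 * a)$hic, 3^2.5 * h1, tolerance = 1e-9)
  # trace-wise domination
  expect_gte(hic(t, a + 10)$hic, h1)
  # widening the window never decreases the maximum
  expect_gte(hic(t, a, max_window = 0.036)$hic,
             hic(t, a, max_window = 0.015)$hic)
})

test_that("femur force is banded against the 3-10 kN fracture range", {
  tr <- c(0, 5000, 10093, 2000)
  f <- femur_assessment(tr)
  expect_equal(f$peak_kN, 10.093)
  expect_equal(f$band, "above")
  expect_true(f$fracture_consistent)
  expect_equal(femur_assessment(c(0, 0, 0))$band, "below")
  # boundary conventions: 3 kN inclusive-within, 10 kN exclusive-above
  expect_equal(femur_assessment(3000)$band, "within")
  expect_equal(femur_assessment(10000)$band, "within")
  expect_equal(femur_assessment(-4000)$peak_kN, 4)
  expect_error(femur_assessment(numeric(0)), "empty")
})

test_that("injury_report runs on a simulated impact", {
  case <- shared_case()
  sc <- scenario(case$template$pedestrian, case$template$vehicle,
                 case$template$environment, case$true_design,
                 dt = 5e-4, t_end = 1.8)
  rep_ <- injury_report(simulate_impact(sc))
  expect_gt(rep_$hic$hic, 0)
  expect_true(rep_$femur$band %in% c("below", "within", "above"))
})
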