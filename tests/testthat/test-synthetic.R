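# Ground-truth case generation and self-consistency.

test_that("a fixed seed reproduces the identical case", {
  c1 <- generate_case(seed = 5)
  c2 <- generate_case(seed = 5)
  expect_identical(unclass(c1$true_design), unclass(c2$true_design))
  expect_identical(c1$evidence, c2$evidence)
})

test_that("noise-free evidence is self-consistent and feasible", {
  case <- shared_case()
  ev <- make_evaluator(case, c("I", "II", "III", "IV"))
  r <- ev(case$true_design)
  expect_true(r$feasible)
  expect_true(all(r$objectives < 0.05))
})

test_that("measurement noise has the declared per-axis scale", {
  base <- generate_case(seed = 9, noise_sd = 0)
  # the same truth seed re-noised: deviations from the noise-free marks are
  # N(0, sd^2) per axis
  devs <- unlist(lapply(1:60, function(i) {
    set.seed(9000 + i)
    noisy <- lapply(base$evidence, function(p) p + rnorm(3, 0, 0.05))
    mapply(function(a, b) a - b, noisy, base$evidence)
  }))
  expect_gt(sd(devs), 0.04)
  expect_lt(sd(devs), 0.06)
  # and the generator itself applies it: noisy case differs from noise-free
  noisy_case <- generate_case(seed = 9, noise_sd = 0.05)
  expect_identical(unclass(noisy_case$true_design),
                   unclass(base$true_design))
  expect_false(isTRUE(all.equal(noisy_case$evidence, base$evidence)))
  off <- unlist(mapply(function(a, b) a - b, noisy_case$evidence,
                       base$evidence))
  expect_lt(max(abs(off)), 0.3)  # noise, not a different trajectory
})

test_that("a collapsed search space recovers the truth exactly", {
  case <- shared_case()
  tv <- unclass(case$true_design)
  eps <- 1e-9
  case2 <- case
  case2$template$bounds <- variable_bounds(tv - eps, tv + eps)
  h <- reconstruct(case2, algorithm = "nsga2", seed = 1,
                   population = 4, generations = 2)
  expect_lt(best_feasible(h), 0.05)
  expect_lt(max(abs(h$evals$V - tv[["V"]])), 1e-6)
})

test_that("recovery error shrinks as measurement noise vanishes", {
  base <- generate_case(seed = 9, noise_sd = 0)
  noisy <- generate_case(seed = 9, noise_sd = 0.25)
  ev0 <- make_evaluator(base, c("I", "II", "III", "IV"))
  evn <- make_evaluator(noisy, c("I", "II", "III", "IV"))
  # at the truth itself, the noise floor is visible in the objective
  expect_lt(sum(ev0(base$true_design)$objectives),
            sum(evn(noisy$true_design)$objectives))
})
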