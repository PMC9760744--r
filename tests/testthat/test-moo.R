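# Dominance machinery and the three optimizers.

test_that("dominance follows the componentwise definition", {
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(1, 2), c(2, 3)))
  expect_false(dominates(c(1, 3), c(2, 2)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "dimension")
  # randomized agreement with the exhaustive definition
  set.seed(11)
  for (rep in 1:20) {
    a <- runif(4); b <- runif(4)
    expect_identical(dominates(a, b), all(a <= b) && any(a < b))
  }
})

test_that("fast nondominated sort matches the brute-force oracle", {
  # degenerate shapes
  O <- matrix(1, 5, 2)
  expect_equal(fast_nondominated_sort(O)$rank, rep(1L, 5))
  chain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(fast_nondominated_sort(chain)$rank, 1:3)
  # random populations against the O(n^2 m) peeling oracle
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    m <- sample(2:4, 1)
    O <- matrix(round(runif(n * m), 2), n, m)
    expect_equal(fast_nondominated_sort(O)$rank, brute_force_ranks(O))
  }
})

test_that("crowding distance follows the normalized-gap formula", {
  two <- rbind(c(0, 1), c(1, 0))
  expect_equal(crowding_distance(two), c(Inf, Inf))
  # one objective at 0, 0.25, 1.0: middle gets (1.0 - 0)/1 per objective
  one <- matrix(c(0, 0.25, 1.0), 3, 1)
  expect_equal(crowding_distance(one), c(Inf, 1.0, Inf))
  # zero range must not divide by zero
  flat <- matrix(1, 4, 2)
  d <- crowding_distance(flat)
  expect_true(all(is.finite(d[!is.infinite(d)])))
})

test_that("collapsed bounds give a constant population", {
  b <- variable_bounds(c(x = 1 - 1e-9), c(x = 1 + 1e-9))
  h <- nsga2(schaffer_eval, b, population = 4, generations = 3, seed = 1)
  expect_equal(nrow(h$evals), 12)
  expect_lt(diff(range(h$evals$F_sum)), 1e-6)
})

test_that("all three optimizers spend exactly population x generations evaluations", {
  b <- schaffer_bounds()
  for (f in list(nsga2, ncga)) {
    h <- f(schaffer_eval, b, population = 6, generations = 4, seed = 2)
    expect_equal(nrow(h$evals), 24)
  }
  h <- mopso(schaffer_eval, b, particles = 6, iterations = 4, seed = 2)
  expect_equal(nrow(h$evals), 24)
})

test_that("NSGA-II concentrates its final front on the Schaffer Pareto set", {
  h <- nsga2(schaffer_eval, schaffer_bounds(), 20, 20, seed = 3)
  x0 <- h$final$X[fast_nondominated_sort(h$final$obj)$rank == 1, 1]
  expect_gte(mean(x0 >= -0.05 & x0 <= 2.05), 0.9)
})

test_that("NCGA's archive lands on the Schaffer Pareto set", {
  h <- ncga(schaffer_eval, schaffer_bounds(), 20, 20, seed = 3)
  ax <- h$archive$X[, 1]
  expect_gte(mean(ax >= -0.05 & ax <= 2.05), 0.8)
})

test_that("MOPSO's repository spans the Schaffer front image", {
  h <- mopso(schaffer_eval, schaffer_bounds(), 20, 20, seed = 3)
  f1 <- h$archive$obj[, 1]
  expect_gte((max(f1) - min(f1)) / 4, 0.7)
})

test_that("identical seeds give identical histories for every algorithm", {
  b <- schaffer_bounds()
  expect_identical(nsga2(schaffer_eval, b, 8, 5, seed = 7)$evals,
                   nsga2(schaffer_eval, b, 8, 5, seed = 7)$evals)
  expect_identical(ncga(schaffer_eval, b, 8, 5, seed = 7)$evals,
                   ncga(schaffer_eval, b, 8, 5, seed = 7)$evals)
  expect_identical(mopso(schaffer_eval, b, 8, 5, seed = 7)$evals,
                   mopso(schaffer_eval, b, 8, 5, seed = 7)$evals)
})

test_that("generated designs always respect the variable bounds", {
  b <- schaffer_bounds()
  for (h in list(nsga2(schaffer_eval, b, 10, 8, seed = 9),
                 ncga(schaffer_eval, b, 10, 8, seed = 9),
                 mopso(schaffer_eval, b, 10, 8, seed = 9))) {
    expect_true(all(h$evals$x >= -5 & h$evals$x <= 10))
  }
})

test_that("NSGA-II's best feasible objective is non-increasing over generations", {
  h <- nsga2(schaffer_eval, schaffer_bounds(), 12, 10, seed = 13)
  best_by_gen <- tapply(h$evals$F_sum, h$evals$generation, min)
  running <- cummin(best_by_gen)
  # elitism: the cumulative best never worsens, and late generations track it
  expect_equal(unname(tail(cummin(best_by_gen), 1)), min(h$evals$F_sum))
  expect_true(all(diff(running) <= 0))
})

test_that("MOPSO collapses to a fixed point from a degenerate start", {
  b <- variable_bounds(c(x = 2 - 1e-9), c(x = 2 + 1e-9))
  h <- mopso(schaffer_eval, b, particles = 4, iterations = 4, seed = 1,
             pm0 = 0)
  expect_lt(diff(range(h$evals$x)), 1e-6)
  expect_lt(diff(range(h$archive$obj[, 1])), 1e-6)
})

test_that("history classification matches a hand-built dominance graph", {
  h <- pedrecon:::.new_history("manual", 1, 5, 1, 1, 2, "x")
  # generation 1: a dominates b; c infeasible beyond the band
  h$evals <- data.frame(
    x = 1:5,
    obj1 = c(0.1, 0.2, 2.5, 0.1, 0.3),
    obj2 = c(0.1, 0.2, 2.5, 0.2, 0.1),
    F_sum = c(0.2, 0.4, 5.0, 0.3, 0.4),
    feasible = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    violation = c(0, 0, 1, 0, 0),
    generation = c(1L, 1L, 1L, 2L, 2L),
    run_index = 1:5)
  cl <- classify_history(h)
  # nondominated: rows 1, 5 (0.1,0.1 dominates all but (0.3,0.1)? no:
  # (0.1,0.1) dominates (0.3,0.1); recompute: row1 dominates rows 2,3,4,5)
  expect_equal(cl$noninferior, 1)
  expect_equal(cl$inferior, 1)           # row 3 beyond 2 m
  # rows 4 and 5 are mutually nondominated within generation 2 but
  # globally dominated; row 2 is dominated already in generation 1
  expect_equal(cl$local_optimal, 2)
  expect_equal(cl$global_best$run_index, 1)
  # identical individuals: all noninferior, none inferior
  h2 <- h
  h2$evals[, c("obj1", "obj2")] <- 0.5
  h2$evals$feasible <- TRUE
  cl2 <- classify_history(h2)
  expect_equal(cl2$noninferior, 5)
  expect_equal(cl2$inferior, 0)
})
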