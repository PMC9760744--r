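# Shared fixtures: evaluators, brute-force oracles, and a cached
# ground-truth case (all built in code at test time).

# Schaffer bi-objective benchmark: f1 = x^2, f2 = (x-2)^2, Pareto set [0, 2]
schaffer_bounds <- function() variable_bounds(c(x = -5), c(x = 10))
schaffer_eval <- function(x) {
  list(objectives = c(x[["x"]]^2, (x[["x"]] - 2)^2),
       feasible = TRUE, violation = 0)
}

# O(n^2 m) brute-force nondomination ranks, independent of the package's
# fast sort: build the full pairwise domination matrix straight from the
# definition, then peel nondominated layers
brute_force_ranks <- function(O) {
  n <- nrow(O)
  LE <- matrix(TRUE, n, n)
  LT <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(O))) {
    LE <- LE & outer(O[, k], O[, k], `<=`)
    LT <- LT | outer(O[, k], O[, k], `<`)
  }
  D <- LE & LT  # D[q, p]: q dominates p
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    nd <- colSums(D[remaining, remaining, drop = FALSE]) == 0L
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  rank
}

# exhaustive HIC window search on a uniformly sampled trace: every (i, j)
# window enumerated, trapezoidal integral accumulated directly
brute_force_hic <- function(time, accel, max_window) {
  n <- length(time)
  dt <- time[2] - time[1]
  best <- 0
  for (i in seq_len(n - 1)) {
    integ <- 0
    for (j in (i + 1):n) {
      tw <- time[j] - time[i]
      if (tw > max_window + 1e-9) break
      integ <- integ + (accel[j - 1] + accel[j]) / 2 * dt
      v <- tw * (integ / tw)^2.5
      if (v > best) best <- v
    }
  }
  best
}

# one noise-free ground-truth case shared across test files (cached)
.case_cache <- new.env(parent = emptyenv())
shared_case <- function() {
  if (is.null(.case_cache$case)) {
    .case_cache$case <- generate_case(seed = 101)
  }
  .case_cache$case
}

# a minimal fake simulation result for marker-geometry unit tests: one
# "body" segment pinned on a straight-line trajectory
fake_result <- function(times, pos_fun, events = NULL, markers = NULL,
                        vehicle_x = NULL) {
  n <- length(times)
  pos <- t(vapply(times, pos_fun, numeric(3)))
  quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  if (is.null(markers)) {
    markers <- list(probe = list(segment = "body", offset = c(0, 0, 0)))
  }
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), segment = character(0),
                         surface = character(0), x = numeric(0),
                         y = numeric(0), z = numeric(0),
                         peak_force = numeric(0))
  }
  structure(list(
    time = times, pos = pos, quat = quat,
    segments = "body",
    head_accel = data.frame(time = times, accel = rep(0, n)),
    femur_force = data.frame(time = times, force = rep(0, n)),
    vehicle_x = if (is.null(vehicle_x)) rep(0, n) else vehicle_x,
    events = events, force_log = NULL,
    t_final = times[n], dt = times[2] - times[1],
    markers = markers
  ), class = "simulation_result")
}
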