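# From-scratch multiobjective optimizers over the bounded design space:
# NSGA-II, NCGA (neighbourhood cultivation), and MOPSO with an external
# adaptive-grid archive. All three log every evaluation and are
# deterministic given a seed.
#
# Evaluator contract: a function f(x) taking a named numeric design and
# returning list(objectives = numeric vector (minimized),
#                feasible = logical, violation = numeric >= 0).

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` iff `a <= b` componentwise with at least one strict
#' inequality.
#'
#' @param a,b numeric objective vectors of equal length
#' @return logical
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective dimension mismatch")
  all(a <= b) && any(a < b)
}

# constrained dominance (Deb): feasible beats infeasible; among infeasible,
# smaller violation wins; among feasible, Pareto dominance
.cdominates <- function(fa, va, oa, fb, vb, ob) {
  if (fa && !fb) return(TRUE)
  if (!fa && fb) return(FALSE)
  if (!fa && !fb) return(va < vb)
  dominates(oa, ob)
}

#' Fast nondominated sorting
#'
#' Partitions a population into nondomination fronts: front 1 is the
#' nondominated set; each later front is nondominated once earlier fronts
#' are removed.
#'
#' @param objectives numeric matrix, one row per individual
#' @return list with `fronts` (list of row-index vectors) and `rank`
#'   (integer per individual, 1-based)
#' @export
fast_nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) stop("empty population")
  S <- vector("list", n)
  ncount <- integer(n)
  rank <- integer(n)
  front <- list()
  f1 <- integer(0)
  for (p in seq_len(n)) {
    Sp <- integer(0)
    for (q in seq_len(n)) {
      if (p == q) next
      if (dominates(objectives[p, ], objectives[q, ])) {
        Sp <- c(Sp, q)
      } else if (dominates(objectives[q, ], objectives[p, ])) {
        ncount[p] <- ncount[p] + 1L
      }
    }
    S[[p]] <- Sp
    if (ncount[p] == 0L) { rank[p] <- 1L; f1 <- c(f1, p) }
  }
  front[[1]] <- f1
  i <- 1L
  while (length(front[[i]]) > 0) {
    nxt <- integer(0)
    for (p in front[[i]]) {
      for (q in S[[p]]) {
        ncount[q] <- ncount[q] - 1L
        if (ncount[q] == 0L) { rank[q] <- i + 1L; nxt <- c(nxt, q) }
      }
    }
    i <- i + 1L
    front[[i]] <- nxt
  }
  front[[length(front)]] <- NULL
  list(fronts = front, rank = rank)
}

#' Crowding distance within a front
#'
#' Boundary individuals on each objective receive infinite distance;
#' interior individuals the sum over objectives of normalized neighbour
#' gaps. A zero objective range contributes nothing.
#'
#' @param objectives numeric matrix, one row per front member
#' @return numeric vector of crowding distances
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) stop("empty front")
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    if (n > 2 && rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (o[ord[i + 1]] - o[ord[i - 1]]) / rng
      }
    }
  }
  d
}

# ---- internal GA machinery ----------------------------------------------

.sbx_crossover <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  k <- length(p1)
  c1 <- p1; c2 <- p2
  if (runif(1) <= pc) {
    for (j in seq_len(k)) {
      if (runif(1) <= 0.5 && abs(p1[j] - p2[j]) > 1e-14) {
        x1 <- min(p1[j], p2[j]); x2 <- max(p1[j], p2[j])
        u <- runif(1)
        beta <- 1 + 2 * (x1 - lower[j]) / (x2 - x1)
        alpha <- 2 - beta^(-(eta + 1))
        bq <- if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1)) else
          (1 / (2 - u * alpha))^(1 / (eta + 1))
        ch1 <- 0.5 * ((x1 + x2) - bq * (x2 - x1))
        beta <- 1 + 2 * (upper[j] - x2) / (x2 - x1)
        alpha <- 2 - beta^(-(eta + 1))
        bq <- if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1)) else
          (1 / (2 - u * alpha))^(1 / (eta + 1))
        ch2 <- 0.5 * ((x1 + x2) + bq * (x2 - x1))
        if (runif(1) <= 0.5) { c1[j] <- ch1; c2[j] <- ch2 }
        else { c1[j] <- ch2; c2[j] <- ch1 }
        c1[j] <- min(max(c1[j], lower[j]), upper[j])
        c2[j] <- min(max(c2[j], lower[j]), upper[j])
      }
    }
  }
  list(c1, c2)
}

.poly_mutation <- function(x, lower, upper, eta = 20, pm = NULL) {
  k <- length(x)
  if (is.null(pm)) pm <- 1 / k
  for (j in seq_len(k)) {
    if (runif(1) <= pm && upper[j] > lower[j]) {
      u <- runif(1)
      delta1 <- (x[j] - lower[j]) / (upper[j] - lower[j])
      delta2 <- (upper[j] - x[j]) / (upper[j] - lower[j])
      if (u <= 0.5) {
        dq <- (2 * u + (1 - 2 * u) * (1 - delta1)^(eta + 1))^(1 / (eta + 1)) - 1
      } else {
        dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - delta2)^(eta + 1))^(1 / (eta + 1))
      }
      x[j] <- min(max(x[j] + dq * (upper[j] - lower[j]), lower[j]), upper[j])
    }
  }
  x
}

# binary tournament with feasibility-first, then rank, then crowding
.tournament <- function(n, rank, crowd, feasible, violation) {
  i <- sample.int(n, 1); j <- sample.int(n, 1)
  better <- function(a, b) {
    if (feasible[a] != feasible[b]) return(feasible[a])
    if (!feasible[a]) return(violation[a] < violation[b])
    if (rank[a] != rank[b]) return(rank[a] < rank[b])
    crowd[a] > crowd[b]
  }
  if (better(i, j)) i else j
}

.eval_pop <- function(X, evaluator) {
  out <- lapply(seq_len(nrow(X)), function(i) {
    r <- evaluator(X[i, ])
    list(objectives = as.numeric(r$objectives),
         feasible = isTRUE(r$feasible),
         violation = if (is.null(r$violation)) 0 else r$violation)
  })
  list(
    obj = do.call(rbind, lapply(out, `[[`, "objectives")),
    feas = vapply(out, `[[`, TRUE, "feasible"),
    viol = vapply(out, `[[`, 0.0, "violation")
  )
}

# rank + crowding with constraint handling: infeasible individuals are
# ranked after all feasible fronts, ordered by violation
.crank <- function(obj, feas, viol) {
  n <- nrow(obj)
  rank <- integer(n)
  crowd <- numeric(n)
  fi <- which(feas)
  if (length(fi)) {
    fs <- fast_nondominated_sort(obj[fi, , drop = FALSE])
    rank[fi] <- fs$rank
    for (fr in fs$fronts) {
      crowd[fi[fr]] <- crowding_distance(obj[fi[fr], , drop = FALSE])
    }
    maxr <- max(fs$rank)
  } else maxr <- 0L
  ii <- which(!feas)
  if (length(ii)) {
    rank[ii] <- maxr + rank(viol[ii], ties.method = "first")
    crowd[ii] <- 0
  }
  list(rank = rank, crowd = crowd)
}

.new_history <- function(algorithm, seed, population, generations, k, m,
                         var_names) {
  structure(list(
    algorithm = algorithm, seed = seed, population = population,
    generations = generations, n_var = k, n_obj = m,
    var_names = var_names, evals = NULL
  ), class = "optimization_history")
}

.log_evals <- function(hist, X, ev, generation) {
  df <- as.data.frame(X)
  names(df) <- hist$var_names
  m <- ncol(ev$obj)
  obj <- as.data.frame(ev$obj)
  names(obj) <- paste0("obj", seq_len(m))
  df <- cbind(df, obj)
  df$F_sum <- rowSums(ev$obj)
  df$feasible <- ev$feas
  df$violation <- ev$viol
  df$generation <- generation
  start <- if (is.null(hist$evals)) 0L else nrow(hist$evals)
  df$run_index <- start + seq_len(nrow(df))
  hist$evals <- rbind(hist$evals, df)
  hist
}

#' @export
print.optimization_history <- function(x, ...) {
  cat("<optimization_history> ", x$algorithm, ", seed ", x$seed, ": ",
      if (is.null(x$evals)) 0 else nrow(x$evals), " evaluations (",
      x$population, " x ", x$generations, ")\n", sep = "")
  invisible(x)
}

# ---- NSGA-II -------------------------------------------------------------

#' NSGA-II over a bounded design space
#'
#' Real-coded elitist NSGA-II: binary tournament selection
#' (feasibility-first, then nondomination rank, then crowding), simulated
#' binary crossover, polynomial mutation, and (mu + lambda) environmental
#' selection. Exactly `population * generations` evaluations are performed
#' and logged.
#'
#' @param evaluator function of a named design vector returning
#'   `list(objectives, feasible, violation)`
#' @param bounds a [variable_bounds()]
#' @param population population size (even, >= 4); default 20
#' @param generations number of generations; default 20
#' @param seed RNG seed (determinism contract: same seed, same history)
#' @param eta_c,eta_m SBX and polynomial-mutation distribution indices
#' @param pc crossover probability
#' @return an `optimization_history`
#' @export
nsga2 <- function(evaluator, bounds, population = 20, generations = 20,
                  seed = 1, eta_c = 15, eta_m = 20, pc = 0.9) {
  if (population < 4 || population %% 2 != 0) {
    stop("population must be even and >= 4")
  }
  lower <- bounds$lower; upper <- bounds$upper
  k <- length(lower)
  set.seed(seed)
  X <- .init_pop(population, lower, upper)
  ev <- .eval_pop(X, evaluator)
  hist <- .new_history("nsga2", seed, population, generations, k,
                       ncol(ev$obj), names(lower))
  hist <- .log_evals(hist, X, ev, 1L)

  for (gen in seq_len(generations - 1)) {
    rc <- .crank(ev$obj, ev$feas, ev$viol)
    # offspring
    Y <- matrix(0, population, k, dimnames = list(NULL, names(lower)))
    for (i in seq(1, population, by = 2)) {
      a <- .tournament(population, rc$rank, rc$crowd, ev$feas, ev$viol)
      b <- .tournament(population, rc$rank, rc$crowd, ev$feas, ev$viol)
      ch <- .sbx_crossover(X[a, ], X[b, ], lower, upper, eta_c, pc)
      Y[i, ] <- .poly_mutation(ch[[1]], lower, upper, eta_m)
      Y[i + 1, ] <- .poly_mutation(ch[[2]], lower, upper, eta_m)
    }
    evY <- .eval_pop(Y, evaluator)
    hist <- .log_evals(hist, Y, evY, gen + 1L)
    # (mu + lambda) environmental selection
    Xall <- rbind(X, Y)
    evall <- list(obj = rbind(ev$obj, evY$obj),
                  feas = c(ev$feas, evY$feas),
                  viol = c(ev$viol, evY$viol))
    keep <- .environmental_selection(evall, population)
    X <- Xall[keep, , drop = FALSE]
    ev <- list(obj = evall$obj[keep, , drop = FALSE],
               feas = evall$feas[keep], viol = evall$viol[keep])
  }
  hist$final <- list(X = X, obj = ev$obj, feasible = ev$feas,
                     violation = ev$viol)
  hist
}

.init_pop <- function(n, lower, upper) {
  k <- length(lower)
  X <- matrix(runif(n * k), n, k)
  X <- sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(X) <- names(lower)
  X
}

# pick `n` survivors by constrained rank, filling the last front by crowding
.environmental_selection <- function(ev, n) {
  rc <- .crank(ev$obj, ev$feas, ev$viol)
  ord <- order(rc$rank, -rc$crowd)
  ord[seq_len(n)]
}

# ---- NCGA ----------------------------------------------------------------

#' Neighbourhood cultivation genetic algorithm
#'
#' As [nsga2()] but mating uses neighbourhood cultivation: each generation
#' the population is sorted along one objective (cycling through objectives
#' across generations) and adjacent individuals are paired for crossover.
#' An external archive of nondominated solutions is maintained and merged
#' into environmental selection.
#'
#' @inheritParams nsga2
#' @param archive_max maximum archive size
#' @return an `optimization_history`
#' @export
ncga <- function(evaluator, bounds, population = 20, generations = 20,
                 seed = 1, eta_c = 15, eta_m = 20, pc = 0.9,
                 archive_max = 100) {
  if (population < 4 || population %% 2 != 0) {
    stop("population must be even and >= 4")
  }
  lower <- bounds$lower; upper <- bounds$upper
  k <- length(lower)
  set.seed(seed)
  X <- .init_pop(population, lower, upper)
  ev <- .eval_pop(X, evaluator)
  hist <- .new_history("ncga", seed, population, generations, k,
                       ncol(ev$obj), names(lower))
  hist <- .log_evals(hist, X, ev, 1L)
  m <- ncol(ev$obj)

  arch <- .archive_update(NULL, X, ev, archive_max)

  for (gen in seq_len(generations - 1)) {
    sort_obj <- ((gen - 1) %% m) + 1
    ord <- order(ev$obj[, sort_obj])
    Y <- matrix(0, population, k, dimnames = list(NULL, names(lower)))
    for (i in seq(1, population, by = 2)) {
      a <- ord[i]; b <- ord[min(i + 1, population)]
      ch <- .sbx_crossover(X[a, ], X[b, ], lower, upper, eta_c, pc)
      Y[i, ] <- .poly_mutation(ch[[1]], lower, upper, eta_m)
      Y[i + 1, ] <- .poly_mutation(ch[[2]], lower, upper, eta_m)
    }
    evY <- .eval_pop(Y, evaluator)
    hist <- .log_evals(hist, Y, evY, gen + 1L)
    arch <- .archive_update(arch, Y, evY, archive_max)
    # merge parents, children and archive, select mu
    Xall <- rbind(X, Y, arch$X)
    evall <- list(obj = rbind(ev$obj, evY$obj, arch$obj),
                  feas = c(ev$feas, evY$feas, arch$feas),
                  viol = c(ev$viol, evY$viol, arch$viol))
    keep <- .environmental_selection(evall, population)
    X <- Xall[keep, , drop = FALSE]
    ev <- list(obj = evall$obj[keep, , drop = FALSE],
               feas = evall$feas[keep], viol = evall$viol[keep])
  }
  hist$final <- list(X = X, obj = ev$obj, feasible = ev$feas,
                     violation = ev$viol)
  hist$archive <- arch
  hist
}

# nondominated archive over feasible-first individuals, trimmed by crowding
.archive_update <- function(arch, X, ev, archive_max) {
  if (is.null(arch)) {
    AX <- X; Aobj <- ev$obj; Afeas <- ev$feas; Aviol <- ev$viol
  } else {
    AX <- rbind(arch$X, X)
    Aobj <- rbind(arch$obj, ev$obj)
    Afeas <- c(arch$feas, ev$feas)
    Aviol <- c(arch$viol, ev$viol)
  }
  if (any(Afeas)) {
    idx <- which(Afeas)
  } else {
    idx <- which(Aviol <= min(Aviol) + 1e-12)
  }
  O <- Aobj[idx, , drop = FALSE]
  nd <- idx[fast_nondominated_sort(O)$rank == 1L]
  if (length(nd) > archive_max) {
    cd <- crowding_distance(Aobj[nd, , drop = FALSE])
    nd <- nd[order(-cd)][seq_len(archive_max)]
  }
  list(X = AX[nd, , drop = FALSE], obj = Aobj[nd, , drop = FALSE],
       feas = Afeas[nd], viol = Aviol[nd])
}

# ---- MOPSO ---------------------------------------------------------------

#' Multiobjective particle swarm optimization
#'
#' Particle swarm with an external repository of nondominated solutions, an
#' adaptive grid over objective space (leaders drawn by roulette inversely
#' weighted by cell occupancy), velocity clamped to 20% of each variable
#' range, reflection at the bounds and uniform mutation with decaying
#' probability.
#'
#' @inheritParams nsga2
#' @param particles swarm size (>= 2)
#' @param iterations number of iterations
#' @param inertia,c_cog,c_soc inertia weight and cognitive/social factors
#' @param grid_div grid divisions per objective
#' @param archive_max repository capacity
#' @param pm0 initial mutation probability (decays quadratically to 0)
#' @return an `optimization_history`
#' @export
mopso <- function(evaluator, bounds, particles = 20, iterations = 20,
                  seed = 1, inertia = 0.4, c_cog = 1.5, c_soc = 1.5,
                  grid_div = 7, archive_max = 100, pm0 = 0.5) {
  if (particles < 2) stop("particles must be >= 2")
  lower <- bounds$lower; upper <- bounds$upper
  k <- length(lower)
  rng <- upper - lower
  vmax <- 0.2 * rng
  set.seed(seed)
  X <- .init_pop(particles, lower, upper)
  V <- matrix(0, particles, k)
  ev <- .eval_pop(X, evaluator)
  hist <- .new_history("mopso", seed, particles, iterations, k,
                       ncol(ev$obj), names(lower))
  hist <- .log_evals(hist, X, ev, 1L)

  pbX <- X
  pb <- ev
  rep_ <- .archive_update(NULL, X, ev, archive_max)

  for (it in seq_len(iterations - 1)) {
    leaders <- .grid_leaders(rep_$obj, particles, grid_div)
    pm <- pm0 * (1 - it / iterations)^2
    for (i in seq_len(particles)) {
      L <- rep_$X[leaders[i], ]
      r1 <- runif(k); r2 <- runif(k)
      V[i, ] <- inertia * V[i, ] + c_cog * r1 * (pbX[i, ] - X[i, ]) +
        c_soc * r2 * (L - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
      X[i, ] <- X[i, ] + V[i, ]
      # reflect at bounds
      for (j in seq_len(k)) {
        if (X[i, j] < lower[j]) { X[i, j] <- 2 * lower[j] - X[i, j]; V[i, j] <- -V[i, j] }
        if (X[i, j] > upper[j]) { X[i, j] <- 2 * upper[j] - X[i, j]; V[i, j] <- -V[i, j] }
        X[i, j] <- min(max(X[i, j], lower[j]), upper[j])
      }
      if (runif(1) < pm) {
        j <- sample.int(k, 1)
        X[i, j] <- runif(1, lower[j], upper[j])
      }
    }
    ev <- .eval_pop(X, evaluator)
    hist <- .log_evals(hist, X, ev, it + 1L)
    # personal bests (constrained dominance; keep old on mutual nondominance
    # with probability 1/2)
    for (i in seq_len(particles)) {
      new_better <- .cdominates(ev$feas[i], ev$viol[i], ev$obj[i, ],
                                pb$feas[i], pb$viol[i], pb$obj[i, ])
      old_better <- .cdominates(pb$feas[i], pb$viol[i], pb$obj[i, ],
                                ev$feas[i], ev$viol[i], ev$obj[i, ])
      if (new_better || (!old_better && runif(1) < 0.5)) {
        pbX[i, ] <- X[i, ]
        pb$obj[i, ] <- ev$obj[i, ]; pb$feas[i] <- ev$feas[i]; pb$viol[i] <- ev$viol[i]
      }
    }
    rep_ <- .archive_update(rep_, X, ev, archive_max)
  }
  hist$final <- list(X = X, obj = ev$obj, feasible = ev$feas,
                     violation = ev$viol)
  hist$archive <- rep_
  hist
}

# roulette leader selection from grid cells, weight 1/(occupancy)
.grid_leaders <- function(obj, n, grid_div) {
  nr <- nrow(obj)
  if (nr == 1) return(rep(1L, n))
  cell <- integer(nr)
  mult <- 1L
  for (m in seq_len(ncol(obj))) {
    o <- obj[, m]
    lo <- min(o); hi <- max(o)
    idx <- if (hi > lo) pmin(floor((o - lo) / (hi - lo) * grid_div), grid_div - 1)
    else rep(0L, nr)
    cell <- cell + as.integer(idx) * mult
    mult <- mult * grid_div
  }
  occ <- table(cell)
  w <- 1 / as.numeric(occ[as.character(cell)])
  sample.int(nr, n, replace = TRUE, prob = w)
}

# ---- history classification ---------------------------------------------

#' Classify an optimization history
#'
#' Noninferior solutions are Pareto-nondominated over the whole history;
#' inferior solutions have at least one subobjective beyond the feasibility
#' band (default 2 m); locally optimal solutions are nondominated within
#' their own generation but dominated globally. The global best is the
#' feasible evaluation with minimal summed objective.
#'
#' @param history an `optimization_history`
#' @param band feasibility band, default `c(0, 2)` m
#' @return list with counts and the `global_best` row
#' @export
classify_history <- function(history, band = c(0, 2)) {
  stopifnot(inherits(history, "optimization_history"))
  df <- history$evals
  if (is.null(df) || nrow(df) == 0) stop("empty history")
  m <- history$n_obj
  O <- as.matrix(df[, paste0("obj", seq_len(m)), drop = FALSE])
  glob_rank <- fast_nondominated_sort(O)$rank
  noninferior <- glob_rank == 1L
  inferior <- apply(O, 1, function(o) any(o < band[1] | o > band[2]))
  local_opt <- logical(nrow(df))
  for (g in unique(df$generation)) {
    sel <- which(df$generation == g)
    r <- fast_nondominated_sort(O[sel, , drop = FALSE])$rank
    local_opt[sel] <- r == 1L & !noninferior[sel]
  }
  feas <- df$feasible
  gb <- NULL
  if (any(feas)) {
    gi <- which(feas)[which.min(df$F_sum[feas])]
    gb <- df[gi, ]
  }
  list(
    noninferior = sum(noninferior),
    inferior = sum(inferior),
    local_optimal = sum(local_opt),
    global_best = gb
  )
}

#' Best feasible objective value of a history
#' @param history an `optimization_history`
#' @return minimal feasible `F_sum`, or `Inf` if no feasible evaluation
#' @export
best_feasible <- function(history) {
  df <- history$evals
  if (!any(df$feasible)) return(Inf)
  min(df$F_sum[df$feasible])
}
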