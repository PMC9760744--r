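# Ground-truth case generator and recovery experiments: build a scenario
# from a known design vector, record the "accident evidence" (marker world
# positions at the contact instants), and reconstruct it back.

#' Generate a synthetic ground-truth case
#'
#' Samples a true design uniformly within the study bounds, runs the
#' forward simulation, and records the four contact marks the way a scene
#' investigator would: the world position of each pedestrian marker at its
#' pair's first-contact instant, converted to the vehicle frame for the
#' vehicle-borne marks (pairs I-III) and kept in world coordinates for the
#' head-ground mark (pair IV). Designs for which any of the four contacts
#' never occurs are resampled (bounded retries).
#'
#' @param seed RNG seed; fixes both the sampled truth and the noise
#' @param noise_sd isotropic per-axis measurement noise SD, m
#' @param dt,t_end simulation step and horizon, s (default 5e-4 and 1.8; the
#'   reconstruction studies use the same reduced step)
#' @param height,mass pedestrian anthropometry
#' @param bounds sampling bounds, default the study ranges
#' @param max_retries resample attempts before giving up
#' @return a `ground_truth_case`: `true_design`, `template` scenario,
#'   `evidence`, `noise_sd`, contact times and retry count
#' @export
generate_case <- function(seed = 1, noise_sd = 0, dt = 5e-4, t_end = 1.8,
                          height = 1.75, mass = 75,
                          bounds = variable_bounds(), max_retries = 50) {
  set.seed(seed)
  ped <- build_pedestrian(height, mass)
  veh <- default_sedan()
  env <- impact_environment()
  rules <- list(I = c("upper_torso", "windscreen"),
                II = c("thigh_r", "bonnet_front"),
                III = c("leg_r", "bumper"),
                IV = c("head", "ground"))
  for (try in seq_len(max_retries)) {
    x <- bounds$lower + runif(length(bounds$lower)) *
      (bounds$upper - bounds$lower)
    des <- design_vector(x[["V"]], x[["D"]], x[["alpha"]], x[["beta"]],
                         x[["gamma"]], bounds = bounds)
    sc <- scenario(ped, veh, env, design = des, dt = dt, t_end = t_end,
                   bounds = bounds)
    res <- tryCatch(simulate_impact(sc), error = function(e) NULL)
    if (is.null(res)) next
    t_c <- vapply(rules, function(r) first_contact(res, r[1], r[2]), 0.0)
    if (any(is.na(t_c))) next
    markers <- c(I = "shoulder_r", II = "thigh_mid_r", III = "calf_mid_r",
                 IV = "head_vertex")
    evidence <- list()
    for (id in names(rules)) {
      p <- .marker_at_time(res, markers[[id]], t_c[[id]])
      if (id != "IV") {
        p[1] <- p[1] - .vehicle_x_at_time(res, t_c[[id]])
      }
      if (noise_sd > 0) p <- p + rnorm(3, 0, noise_sd)
      evidence[[id]] <- p
    }
    template <- scenario(ped, vehicle = NULL, environment = env,
                         design = NULL, dt = dt, t_end = t_end,
                         bounds = bounds)
    template$vehicle <- veh  # template keeps the full context, design empty
    return(structure(list(
      true_design = des, template = template, evidence = evidence,
      noise_sd = noise_sd, contact_times = t_c, retries = try - 1L,
      seed = seed
    ), class = "ground_truth_case"))
  }
  stop("no valid ground-truth case after ", max_retries, " retries ",
       "(some of the four contacts never occurred); inspect the scenario ",
       "geometry or widen the bounds")
}

#' @export
print.ground_truth_case <- function(x, ...) {
  cat("<ground_truth_case> truth: ",
      paste(names(x$true_design), signif(unclass(x$true_design), 4),
            sep = "=", collapse = ", "),
      "; noise_sd = ", x$noise_sd, " m\n", sep = "")
  invisible(x)
}

#' Build a reconstruction evaluator for a case
#'
#' Wraps [evaluate_design()] over the case's evidence into the evaluator
#' contract the optimizers consume: objectives are the group's subobjective
#' distances, feasibility is the 0-2 m band with contacts found, and the
#' violation is the summed band excess plus a 2 m surcharge per missing
#' contact.
#'
#' @param case a [generate_case()] case (or any object with `template` and
#'   `evidence`)
#' @param group character vector of pair ids
#' @return an evaluator function
#' @export
make_evaluator <- function(case, group) {
  pairs <- default_marker_pairs(case$evidence)
  if (!all(group %in% names(pairs))) stop("evidence does not cover the group")
  template <- case$template
  force(group)
  function(x) {
    r <- evaluate_design(x, group, pairs, template)
    viol <- sum(pmax(0, r$d - 2)) + 2 * sum(!r$contact_found)
    list(objectives = unname(r$d[group]), feasible = r$overall_feasible,
         violation = viol, result = r)
  }
}

#' Reconstruct a case with one optimizer run
#'
#' @param case a [generate_case()] case
#' @param group pair ids forming the objective
#' @param algorithm `"nsga2"`, `"ncga"` or `"mopso"`
#' @param seed optimizer seed
#' @param population,generations budget (default 20 x 20 = 400 evaluations)
#' @return an `optimization_history`
#' @export
reconstruct <- function(case, group = c("I", "II", "III", "IV"),
                        algorithm = c("nsga2", "ncga", "mopso"), seed = 1,
                        population = 20, generations = 20) {
  algorithm <- match.arg(algorithm)
  ev <- make_evaluator(case, group)
  bounds <- case$template$bounds
  switch(algorithm,
    nsga2 = nsga2(ev, bounds, population, generations, seed),
    ncga = ncga(ev, bounds, population, generations, seed),
    mopso = mopso(ev, bounds, particles = population,
                  iterations = generations, seed = seed))
}

#' Parameter-recovery experiment
#'
#' Runs the optimizer against the case's evidence once per seed and reports
#' the per-variable absolute recovery error of the best feasible design,
#' its objective value, and the head-ground impact-point error of the
#' recovered design against the case's ground mark.
#'
#' @param case a [generate_case()] case
#' @param algorithm optimizer name
#' @param group pair ids used for the reconstruction objective
#' @param seeds one optimizer run per seed
#' @param population,generations budget per run
#' @return data.frame, one row per seed, with `best_F`, `err_V`, `err_D`,
#'   `err_alpha`, `err_beta`, `err_gamma`, `head_ground_error`
#' @export
recovery_experiment <- function(case, algorithm = "nsga2",
                                group = c("I", "II", "III", "IV"),
                                seeds = 1:5, population = 20,
                                generations = 20) {
  truth <- case$true_design
  rows <- lapply(seeds, function(sd) {
    h <- reconstruct(case, group, algorithm, seed = sd,
                     population = population, generations = generations)
    cl <- classify_history(h)
    gb <- cl$global_best
    if (is.null(gb)) {
      # no feasible evaluation: fall back to minimal F_sum
      i <- which.min(h$evals$F_sum)
      gb <- h$evals[i, ]
      bf <- Inf
    } else bf <- gb$F_sum
    xr <- unlist(gb[c("V", "D", "alpha", "beta", "gamma")])
    hg <- .head_ground_error(case, xr)
    data.frame(seed = sd, best_F = bf,
               err_V = abs(xr[["V"]] - truth[["V"]]),
               err_D = abs(xr[["D"]] - truth[["D"]]),
               err_alpha = abs(xr[["alpha"]] - truth[["alpha"]]),
               err_beta = abs(xr[["beta"]] - truth[["beta"]]),
               err_gamma = abs(xr[["gamma"]] - truth[["gamma"]]),
               head_ground_error = hg)
  })
  do.call(rbind, rows)
}

# distance between the recovered design's head-ground impact point and the
# case's recorded ground mark (NA if the recovered design never grounds the
# head)
.head_ground_error <- function(case, x) {
  tpl <- case$template
  des <- tryCatch(design_vector(x[["V"]], x[["D"]], x[["alpha"]], x[["beta"]],
                                x[["gamma"]], bounds = tpl$bounds),
                  error = function(e) NULL)
  if (is.null(des)) return(NA_real_)
  sc <- scenario(tpl$pedestrian, tpl$vehicle, tpl$environment, design = des,
                 dt = tpl$dt, t_end = tpl$t_end, bounds = tpl$bounds)
  res <- tryCatch(simulate_impact(sc), error = function(e) NULL)
  if (is.null(res)) return(NA_real_)
  t_c <- first_contact(res, "head", "ground")
  if (is.na(t_c)) return(NA_real_)
  p <- .marker_at_time(res, "head_vertex", t_c)
  sqrt(sum((p - case$evidence$IV)^2))
}
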