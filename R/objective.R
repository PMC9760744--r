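# Reconstruction objective: per-pair marker distances at first-contact
# times, the 0-2 m feasibility band, and the summed objective.

.pair_ids <- c("I", "II", "III", "IV")

#' Define a collision marker pair
#'
#' A pair couples a pedestrian-body marker with a physical mark on the
#' vehicle or the ground. Pair I: windscreen spiderweb centre vs right
#' shoulder; II: bumper mark near the left headlight vs right mid-thigh;
#' III: lower-left bumper vs outer right calf; IV: head-ground impact point
#' vs head vertex. The pair's subobjective is the Euclidean distance between
#' the two points at the first contact of `contact_segment` with
#' `contact_surface`.
#'
#' @param id one of `"I", "II", "III", "IV"`
#' @param human_marker pedestrian marker name (see [build_pedestrian()])
#' @param surface_point numeric xyz of the physical mark
#' @param frame `"vehicle"` (mark moves with the vehicle) or `"world"`
#' @param contact_segment,contact_surface the (segment, surface) pair whose
#'   first contact defines the evaluation time
#' @return a `marker_pair` object
#' @export
marker_pair <- function(id, human_marker, surface_point,
                        frame = c("vehicle", "world"),
                        contact_segment, contact_surface) {
  id <- match.arg(id, .pair_ids)
  frame <- match.arg(frame)
  if (id == "IV" && frame != "world") {
    stop("pair IV's surface mark is on the ground and must be world-frame")
  }
  structure(list(id = id, human_marker = human_marker,
                 surface_point = as.numeric(surface_point), frame = frame,
                 contact_segment = contact_segment,
                 contact_surface = contact_surface),
            class = "marker_pair")
}

#' Default pair definitions for an evidence set
#'
#' @param evidence named list (`I`..`IV`) of xyz marks; pairs I-III are
#'   vehicle-frame, IV is world-frame
#' @return named list of [marker_pair()] objects
#' @export
default_marker_pairs <- function(evidence) {
  defs <- list(
    I   = list(hm = "shoulder_r",  seg = "upper_torso", surf = "windscreen"),
    II  = list(hm = "thigh_mid_r", seg = "thigh_r",     surf = "bonnet_front"),
    III = list(hm = "calf_mid_r",  seg = "leg_r",       surf = "bumper"),
    IV  = list(hm = "head_vertex", seg = "head",        surf = "ground")
  )
  out <- list()
  for (id in intersect(.pair_ids, names(evidence))) {
    d <- defs[[id]]
    out[[id]] <- marker_pair(id, d$hm, evidence[[id]],
                             frame = if (id == "IV") "world" else "vehicle",
                             contact_segment = d$seg,
                             contact_surface = d$surf)
  }
  out
}

#' Marker-pair distance at first contact
#'
#' If the pair's designated (segment, surface) contact occurs, returns the
#' Euclidean distance between the pedestrian marker and the physical mark at
#' the first-contact time (vehicle-frame marks are converted to world
#' coordinates using the vehicle position at that time). If the contact
#' never occurs before `t_end`, returns the minimum marker distance over
#' all logged times, flagged `contact_found = FALSE`.
#'
#' @param result a [simulate_impact()] result
#' @param pair a [marker_pair()]
#' @return list with `distance` (m) and `contact_found` (logical)
#' @export
marker_distance <- function(result, pair) {
  stopifnot(inherits(pair, "marker_pair"))
  t_c <- first_contact(result, pair$contact_segment, pair$contact_surface)
  if (!is.na(t_c)) {
    hm <- .marker_at_time(result, pair$human_marker, t_c)
    sp <- pair$surface_point
    if (pair$frame == "vehicle") {
      sp <- sp + c(.vehicle_x_at_time(result, t_c), 0, 0)
    }
    return(list(distance = sqrt(sum((hm - sp)^2)), contact_found = TRUE))
  }
  # fallback: minimum distance over the logged trajectory
  trk <- .marker_track(result, pair$human_marker)
  sp <- matrix(pair$surface_point, nrow(trk), 3, byrow = TRUE)
  if (pair$frame == "vehicle") sp[, 1] <- sp[, 1] + result$vehicle_x
  dmin <- sqrt(min(rowSums((trk - sp)^2)))
  list(distance = dmin, contact_found = FALSE)
}

#' Sum subobjective distances over a group
#'
#' The aggregate objective is the plain sum of the group's subobjective
#' distances.
#'
#' @param d named numeric of per-pair distances (m)
#' @param group character vector of pair ids to include
#' @return the summed objective in metres
#' @export
aggregate_distances <- function(d, group) {
  group <- as.character(group)
  if (length(group) == 0) stop("empty group")
  missing <- setdiff(group, names(d))
  if (length(missing)) {
    stop("missing subobjective(s): ", paste(missing, collapse = ", "))
  }
  sum(d[group])
}

#' Evaluate a design against the evidence
#'
#' Instantiates a scenario from the design, runs the forward simulation and
#' computes every pair's marker distance. If the simulation fails
#' numerically, all distances are set to the penalty value and the result is
#' infeasible.
#'
#' @param design a [design_vector()] or named numeric
#' @param group character vector of pair ids forming the objective
#' @param pairs named list of [marker_pair()]s covering at least `group`
#' @param template a [scenario()] supplying pedestrian, vehicle, environment,
#'   dt and t_end (its design slot is replaced)
#' @param penalty distance assigned to every pair when the simulation
#'   aborts, m
#' @return an `objective_result`: per-pair distances `d`, `F_sum`, per-pair
#'   and overall feasibility, and `contact_found` flags
#' @export
evaluate_design <- function(design, group, pairs, template, penalty = 10) {
  design <- .as_design(design)
  group <- as.character(group)
  if (!all(group %in% names(pairs))) {
    stop("pairs must cover the whole group")
  }
  sc <- scenario(template$pedestrian, template$vehicle, template$environment,
                 design = design, dt = template$dt, t_end = template$t_end,
                 approach_gap = template$approach_gap, bounds = template$bounds)
  res <- tryCatch(simulate_impact(sc), error = function(e) NULL)
  if (is.null(res)) {
    d <- setNames(rep(penalty, length(group)), group)
    return(structure(list(
      design = design, d = d, F_sum = sum(d),
      feasible = setNames(rep(FALSE, length(group)), group),
      contact_found = setNames(rep(FALSE, length(group)), group),
      overall_feasible = FALSE, simulation_failed = TRUE
    ), class = "objective_result"))
  }
  d <- numeric(0); cf <- logical(0)
  for (id in group) {
    md <- marker_distance(res, pairs[[id]])
    d[id] <- md$distance
    cf[id] <- md$contact_found
  }
  feas <- cf & d >= 0 & d <= 2
  structure(list(
    design = design, d = d, F_sum = aggregate_distances(d, group),
    feasible = feas, contact_found = cf,
    overall_feasible = all(feas), simulation_failed = FALSE
  ), class = "objective_result")
}

#' Feasibility of an objective result
#'
#' A pair is feasible when its contact occurred and its distance lies in the
#' 0-2 m band; the design is feasible when all pairs are.
#'
#' @param result an `objective_result`
#' @return list with `feasible` (overall) and `pairs` (per-pair flags)
#' @export
is_feasible <- function(result) {
  stopifnot(inherits(result, "objective_result"))
  list(feasible = result$overall_feasible, pairs = result$feasible)
}

#' @export
print.objective_result <- function(x, ...) {
  cat("<objective_result> F_sum = ", format(x$F_sum), " m (",
      paste(names(x$d), "=", signif(x$d, 4), collapse = ", "), "); ",
      if (x$overall_feasible) "feasible" else "infeasible", "\n", sep = "")
  invisible(x)
}
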