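# Scenario assembly and the forward simulation wrapper around the compiled
# fixed-step integrator.

#' Assemble a collision scenario
#'
#' Coordinate convention: right-handed world frame, x = vehicle travel
#' direction, z up, ground plane z = 0. The pedestrian stands at
#' (0, D, 0); the vehicle approaches along x with its foremost point
#' `approach_gap` metres behind the pedestrian at t = 0 and moves at the
#' design speed V. The pedestrian's facing direction is `alpha - pi/2`
#' (crossing the road, angled towards the oncoming vehicle); beta and gamma
#' are composed onto the head-neck joint.
#'
#' @param pedestrian a [build_pedestrian()] model
#' @param vehicle a [build_vehicle()] model, or `NULL` for no vehicle
#' @param environment an [impact_environment()]
#' @param design a [design_vector()], or `NULL` when no vehicle is present
#' @param dt integration time step, s (default 2e-5)
#' @param t_end termination time, s (default 1.8)
#' @param approach_gap initial clearance between the vehicle's foremost
#'   point and the pedestrian, m
#' @param bounds bounds used to validate `design`
#' @param settle drop the pedestrian so its lowest support point starts
#'   1 mm above the ground (disable for free-flight tests)
#' @return an object of class `scenario`
#' @export
scenario <- function(pedestrian, vehicle = default_sedan(),
                     environment = impact_environment(), design = NULL,
                     dt = 2e-5, t_end = 1.8, approach_gap = 2.5,
                     bounds = variable_bounds(), settle = TRUE) {
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= 0) stop("t_end must be > 0")
  if (!is.null(vehicle) && is.null(design)) {
    stop("a design vector is required when a vehicle is present")
  }
  if (!is.null(design)) {
    design <- design_vector(design[["V"]], design[["D"]], design[["alpha"]],
                            design[["beta"]], design[["gamma"]], bounds = bounds)
  }
  structure(list(
    pedestrian = pedestrian, vehicle = vehicle, environment = environment,
    design = design, dt = dt, t_end = t_end, approach_gap = approach_gap,
    bounds = bounds, settle = settle
  ), class = "scenario")
}

# pack a scenario into the flat arrays the compiled core consumes
.pack_scenario <- function(sc) {
  ped <- sc$pedestrian
  seg <- ped$segments
  des <- sc$design

  if (!is.null(des)) {
    yaw <- des[["alpha"]] - pi / 2
    base <- c(0, des[["D"]], 0)
    qhead <- .quat_mul(.quat_from_axis(c(0, 1, 0), des[["beta"]]),
                       .quat_from_axis(c(0, 0, 1), des[["gamma"]]))
  } else {
    yaw <- 0; base <- c(0, 0, 0); qhead <- c(1, 0, 0, 0)
  }
  pose <- .pose_pedestrian(ped, yaw = yaw, base = base, extra_head = qhead)

  # settle: drop the lowest support point to 1 mm above the ground
  semi <- cbind(seg$a, seg$b, seg$cz)
  if (isTRUE(sc$settle)) {
    lowest <- Inf
    for (i in seq_len(nrow(seg))) {
      nb <- .quat_rot(.quat_conj(pose$quat[i, ]), c(0, 0, 1))
      h <- sqrt(sum((semi[i, ] * nb)^2))
      lowest <- min(lowest, pose$pos[i, 3] - h)
    }
    pose$pos[, 3] <- pose$pos[, 3] - lowest + 0.001
  }

  bodies <- list(
    mass = seg$mass,
    inertia = cbind(seg$Ix, seg$Iy, seg$Iz),
    semi = semi,
    pos = pose$pos, quat = pose$quat,
    vel = matrix(0, nrow(seg), 3), angvel = matrix(0, nrow(seg), 3)
  )
  njo <- length(pose$parent)
  joints <- if (njo == 0) list(parent = integer(0)) else {
    js <- ped$joints
    # Penalty-joint gains capped by the semi-implicit Euler stability limits
    # of both the translational (force/mass) and rotational (force x lever /
    # inertia) channels at the design step dt_ref. The model constants are
    # therefore independent of the actual dt and stable for dt <= dt_ref.
    dt_ref <- 5e-4
    Imin <- pmin(seg$Ix, seg$Iy, seg$Iz)
    ktrans <- numeric(njo); ctrans <- numeric(njo)
    krot <- numeric(njo); crot <- numeric(njo); krot_max <- numeric(njo)
    for (j in seq_len(njo)) {
      p <- pose$parent[j]; c_ <- pose$child[j]
      rp <- sqrt(sum(pose$anchor_parent[j, ]^2))
      rc <- sqrt(sum(pose$anchor_child[j, ]^2))
      m_eff <- min(seg$mass[p], seg$mass[c_],
                   if (rp > 1e-6) Imin[p] / rp^2 else Inf,
                   if (rc > 1e-6) Imin[c_] / rc^2 else Inf)
      ktrans[j] <- min(2e5, (0.3 / dt_ref)^2 * m_eff)
      ctrans[j] <- min(2 * sqrt(ktrans[j] * m_eff), 0.5 * m_eff / dt_ref)
      I_eff <- min(Imin[p], Imin[c_])
      krot[j] <- min(js$krot[j], (0.3 / dt_ref)^2 * I_eff)
      krot_max[j] <- 0.5 * (0.3 / dt_ref)^2 * I_eff
      crot[j] <- min(js$crot[j], 0.25 * I_eff / dt_ref)
    }
    list(parent = as.integer(pose$parent), child = as.integer(pose$child),
         anchor_parent = pose$anchor_parent, anchor_child = pose$anchor_child,
         qrel0 = pose$qrel0, krot = krot, crot = crot, stop = js$stop,
         krot_max = krot_max, ktrans = ktrans, ctrans = ctrans)
  }

  env <- sc$environment
  veh <- sc$vehicle
  if (is.null(veh)) {
    vehicle <- list(present = FALSE)
  } else {
    prof <- veh$profile
    np <- nrow(prof) - 1
    patches <- cbind(prof[seq_len(np), 1], prof[seq_len(np), 2],
                     prof[seq_len(np) + 1, 1], prof[seq_len(np) + 1, 2],
                     seq_len(np))
    V <- if (!is.null(des)) des[["V"]] else veh$speed_initial
    x0 <- -sc$approach_gap - max(prof[, 1])
    decel <- veh$braking_decel
    if (is.na(decel)) decel <- env$mu_vehicle_ground * env$gravity
    t_brake <- if (decel > 0 && V > 0) sc$approach_gap / V else 0
    vehicle <- list(
      present = TRUE, patches = patches,
      zones = lapply(veh$zones, function(z)
        list(curve = as.matrix(z$curve), damping = z$damping)),
      x0 = x0, speed = V, decel = decel, t_brake = t_brake,
      half_width = veh$half_width
    )
  }

  envl <- list(g = env$gravity, mu_ped_ground = env$mu_pedestrian_ground,
               mu_ped_vehicle = env$mu_pedestrian_vehicle,
               k_ground = env$k_ground, c_ground = env$c_ground)

  head_idx <- match("head", seg$name)
  if (is.na(head_idx)) head_idx <- 1L
  femur_idx <- match("thigh_r", seg$name)
  if (is.na(femur_idx)) femur_idx <- -1L

  list(bodies = bodies, joints = joints, vehicle = vehicle, env = envl,
       head_idx = head_idx, femur_idx = femur_idx,
       seg_names = seg$name,
       surf_names = if (is.null(veh)) "ground" else
         c(vapply(veh$zones, `[[`, "", "name"), "ground"))
}

#' Run the forward simulation
#'
#' Fixed-step semi-implicit Euler advance of all pedestrian segments to
#' `t_end`, with penalty contact (zone force-deflection curves plus linear
#' damping for the vehicle, linear stiffness for the ground) and Coulomb
#' friction regularized by a tanh slip-velocity law. The vehicle follows a
#' prescribed motion (constant speed, then optional braking). Output is
#' decimated to roughly 1 kHz.
#'
#' @param scenario a [scenario()]
#' @param record_forces log per-step contact normal and friction forces
#'   (at the output rate) for diagnostics
#' @return an object of class `simulation_result` with sampled trajectories,
#'   contact events, head-acceleration (g) and right-femur axial force (N)
#'   traces
#' @export
simulate_impact <- function(scenario, record_forces = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  pk <- .pack_scenario(scenario)
  stride <- max(1L, as.integer(round(0.001 / scenario$dt)))
  # crude stability heuristic: stiffest spring vs lightest segment
  kmax <- max(pk$env$k_ground,
              if (length(pk$joints$parent)) max(pk$joints$ktrans) else 0)
  wmax <- sqrt(kmax / min(pk$bodies$mass))
  if (scenario$dt * wmax > 1.0) {
    warning("dt = ", scenario$dt, " s may be unstable for the stiffest ",
            "contact/joint (characteristic frequency ", round(wmax, 1),
            " rad/s)")
  }
  raw <- .sim_run(pk$bodies, pk$joints, pk$vehicle, pk$env,
                  scenario$dt, scenario$t_end, stride,
                  pk$head_idx, pk$femur_idx, record_forces)
  if (raw$status != 0) {
    stop("simulation blew up (non-finite or runaway state) at step ",
         raw$blow_step, " of ", raw$n_steps)
  }
  ev <- as.data.frame(raw$events)
  if (nrow(ev)) {
    ev$segment <- pk$seg_names[ev$body + 1]
    ev$surface <- pk$surf_names[ev$surface + 1]
  } else {
    ev$segment <- character(0); ev$surface <- character(0)
  }
  ev <- ev[, c("time", "segment", "surface", "x", "y", "z", "peak_force")]
  fl <- NULL
  if (record_forces) {
    fl <- as.data.frame(raw$force_log)
    if (nrow(fl)) {
      fl$segment <- pk$seg_names[fl$body + 1]
      fl$surface <- pk$surf_names[fl$surface + 1]
    }
  }
  structure(list(
    time = as.numeric(raw$time),
    pos = raw$pos, quat = raw$quat,
    vel = raw$vel, angvel = raw$angvel,
    segments = pk$seg_names,
    head_accel = data.frame(time = as.numeric(raw$time),
                            accel = as.numeric(raw$head_accel)),
    femur_force = data.frame(time = as.numeric(raw$time),
                             force = as.numeric(raw$femur_force)),
    vehicle_x = as.numeric(raw$vehicle_x),
    events = ev, force_log = fl,
    t_final = raw$t_final, dt = scenario$dt,
    markers = scenario$pedestrian$markers
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$time), " samples to t = ",
      round(x$t_final, 4), " s; ", nrow(x$events), " contact events\n", sep = "")
  invisible(x)
}

#' First contact time of a segment with a surface
#'
#' @param result a [simulate_impact()] result
#' @param segment pedestrian segment name
#' @param surface vehicle zone name or `"ground"`
#' @return earliest contact time in seconds, or `NA_real_` if the pair never
#'   touches before `t_end`
#' @export
first_contact <- function(result, segment, surface) {
  stopifnot(inherits(result, "simulation_result"))
  if (!segment %in% result$segments) {
    stop("unknown segment '", segment, "'")
  }
  known_surf <- c(unique(result$events$surface),
                  "ground", "bumper", "bonnet_front", "bonnet_mid",
                  "bonnet_rear", "windscreen")
  if (!surface %in% known_surf) stop("unknown surface '", surface, "'")
  sel <- result$events$segment == segment & result$events$surface == surface
  if (!any(sel)) return(NA_real_)
  min(result$events$time[sel])
}

# world position of a named pedestrian marker at output sample i
.marker_world <- function(result, marker, i) {
  mk <- result$markers[[marker]]
  if (is.null(mk)) stop("unknown marker '", marker, "'")
  si <- match(mk$segment, result$segments)
  p <- result$pos[i, (si - 1) * 3 + 1:3]
  q <- result$quat[i, (si - 1) * 4 + 1:4]
  p + .quat_rot(q, mk$offset)
}

# marker world positions at every output sample (n x 3)
.marker_track <- function(result, marker) {
  mk <- result$markers[[marker]]
  if (is.null(mk)) stop("unknown marker '", marker, "'")
  si <- match(mk$segment, result$segments)
  P <- result$pos[, (si - 1) * 3 + 1:3, drop = FALSE]
  Q <- result$quat[, (si - 1) * 4 + 1:4, drop = FALSE]
  off <- mk$offset
  t(vapply(seq_len(nrow(P)), function(i) P[i, ] + .quat_rot(Q[i, ], off),
           numeric(3)))
}

# linear interpolation of a marker position at arbitrary time
.marker_at_time <- function(result, marker, t) {
  tv <- result$time
  i <- findInterval(t, tv, all.inside = TRUE)
  w <- (t - tv[i]) / (tv[i + 1] - tv[i])
  w <- min(max(w, 0), 1)
  (1 - w) * .marker_world(result, marker, i) +
    w * .marker_world(result, marker, i + 1)
}

.vehicle_x_at_time <- function(result, t) {
  approx(result$time, result$vehicle_x, xout = t, rule = 2)$y
}
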