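# Zoned vehicle front: planar profile polyline (x forward, z up, vehicle
# frame) extruded laterally, each span carrying a piecewise-linear
# force-deflection curve in the style of EuroNCAP subsystem impact tests.

.zone_names <- c("bumper", "bonnet_front", "bonnet_mid", "bonnet_rear", "windscreen")

#' Build a vehicle front model
#'
#' The front structure is an ordered polyline in the vehicle frame (x
#' forward, z up, origin at the foremost bumper point, ground at z = 0).
#' Consecutive profile points delimit zone spans; each zone carries a
#' piecewise-linear force--deflection curve (F(0) = 0, non-decreasing) and a
#' linear contact damping coefficient.
#'
#' @param profile numeric matrix (n x 2) of profile points, columns x and z,
#'   ordered from the lower bumper edge upward/rearward
#' @param zone_specs list of zone specifications, one per profile span, each
#'   a list with `name`, `curve` (k x 2 matrix: deflection m, force N) and
#'   `damping` (N s/m)
#' @param half_width lateral half-extent of the front surface, m
#' @param markers named list of vehicle-frame marker points (m)
#' @param speed_initial initial forward speed, m/s
#' @param braking_decel braking deceleration, m/s^2; `NA` means "use
#'   mu_vehicle_ground * g from the environment", 0 disables braking
#' @return an object of class `vehicle_model`
#' @export
build_vehicle <- function(profile, zone_specs, half_width = 0.85,
                          markers = list(), speed_initial = 0,
                          braking_decel = 0) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 2) stop("profile needs at least 2 points")
  if (length(zone_specs) != nrow(profile) - 1) {
    stop("need one zone spec per profile span (", nrow(profile) - 1,
         "), got ", length(zone_specs))
  }
  if (!is.na(speed_initial) && speed_initial < 0) {
    stop("speed_initial must be >= 0")
  }
  for (zs in zone_specs) {
    curve <- as.matrix(zs$curve)
    if (nrow(curve) < 2) stop("zone '", zs$name, "': curve needs >= 2 knots")
    if (abs(curve[1, 1]) > 1e-12 || abs(curve[1, 2]) > 1e-12) {
      stop("zone '", zs$name, "': force-deflection curve must start at F(0) = 0")
    }
    if (any(diff(curve[, 1]) <= 0)) {
      stop("zone '", zs$name, "': deflection knots must be strictly increasing")
    }
    if (any(diff(curve[, 2]) < 0)) {
      stop("zone '", zs$name, "': force-deflection curve must be non-decreasing")
    }
  }
  nm <- vapply(zone_specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("overlapping zone spans: duplicated zone name ",
                              nm[duplicated(nm)][1])
  structure(list(
    profile = profile, zones = zone_specs, half_width = half_width,
    markers = markers, speed_initial = speed_initial,
    braking_decel = braking_decel
  ), class = "vehicle_model")
}

#' Default sedan front
#'
#' A generic small-sedan front profile with five zones (bumper, bonnet
#' leading edge, bonnet middle, bonnet rear, windscreen) and default
#' piecewise-linear stiffness curves in the ranges of the EuroNCAP legform
#' (bumper), upper-legform (bonnet leading edge) and headform (bonnet and
#' windscreen) subsystem tests. Marker points: `A` windscreen spiderweb
#' centre, `C` bumper near the left headlight, `E` lower-left bumper.
#'
#' @param braking_decel see [build_vehicle()]; default `NA` brakes at
#'   mu_vehicle_ground * g from the nominal impact instant
#' @return a `vehicle_model`
#' @export
default_sedan <- function(braking_decel = NA) {
  profile <- rbind(
    c(0.00, 0.30),   # lower bumper edge
    c(0.06, 0.66),   # bumper top
    c(0.00, 0.80),   # bonnet leading edge top
    c(-0.45, 0.90),  # bonnet mid
    c(-0.90, 1.00),  # bonnet rear / windscreen base
    c(-1.55, 1.44)   # windscreen top
  )
  # damping near critical for the struck segment masses: body-panel impacts
  # are close to plastic (restitution well below 0.3)
  zones <- list(
    list(name = "bumper",
         curve = rbind(c(0, 0), c(0.04, 6000), c(0.12, 14000)), damping = 2000),
    list(name = "bonnet_front",
         curve = rbind(c(0, 0), c(0.05, 5000), c(0.15, 10000)), damping = 1500),
    list(name = "bonnet_mid",
         curve = rbind(c(0, 0), c(0.05, 3500), c(0.20, 8000)), damping = 1200),
    list(name = "bonnet_rear",
         curve = rbind(c(0, 0), c(0.05, 4000), c(0.20, 9000)), damping = 1200),
    list(name = "windscreen",
         curve = rbind(c(0, 0), c(0.02, 2000), c(0.10, 4500), c(0.30, 7000)),
         damping = 800)
  )
  markers <- list(
    A = c(-1.05, 0.35, 1.08),  # windscreen spiderweb centre (lower left)
    C = c(0.03, 0.55, 0.72),   # bonnet leading edge by the left headlight
    E = c(0.01, 0.65, 0.35)    # lower-left front bumper
  )
  build_vehicle(profile, zones, half_width = 0.85, markers = markers,
                speed_initial = 0, braking_decel = braking_decel)
}

#' Evaluate a zone's force-deflection curve
#'
#' Linear interpolation between knots; beyond the last knot the final slope
#' is extrapolated. Deflection <= 0 gives zero force.
#'
#' @param vehicle a `vehicle_model`
#' @param zone zone name
#' @param deflection deflection in metres (vectorized)
#' @return contact force in N
#' @export
zone_force <- function(vehicle, zone, deflection) {
  nm <- vapply(vehicle$zones, `[[`, "", "name")
  i <- match(zone, nm)
  if (is.na(i)) stop("unknown zone '", zone, "'")
  curve <- as.matrix(vehicle$zones[[i]]$curve)
  k <- nrow(curve)
  slope_end <- (curve[k, 2] - curve[k - 1, 2]) / (curve[k, 1] - curve[k - 1, 1])
  vapply(deflection, function(d) {
    if (d <= 0) return(0)
    if (d >= curve[k, 1]) return(curve[k, 2] + slope_end * (d - curve[k, 1]))
    approx(curve[, 1], curve[, 2], xout = d)$y
  }, 0.0)
}

#' @export
print.vehicle_model <- function(x, ...) {
  cat("<vehicle_model> ", length(x$zones), " zones: ",
      paste(vapply(x$zones, `[[`, "", "name"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Impact environment
#'
#' Gravity, the ground plane z = 0, the friction triplet and ground contact
#' stiffness. Default friction is the wet-asphalt triplet
#' (mu_vehicle_ground, mu_pedestrian_ground, mu_pedestrian_vehicle) =
#' (0.55, 0.6, 0.3).
#'
#' @param mu_vehicle_ground,mu_pedestrian_ground,mu_pedestrian_vehicle
#'   dimensionless friction coefficients, all >= 0
#' @param gravity m/s^2, downward
#' @param k_ground,c_ground ground penalty stiffness (N/m) and damping (N s/m)
#' @return an object of class `impact_environment`
#' @export
impact_environment <- function(mu_vehicle_ground = 0.55,
                               mu_pedestrian_ground = 0.6,
                               mu_pedestrian_vehicle = 0.3,
                               gravity = 9.81,
                               k_ground = 3e5, c_ground = 1500) {
  mus <- c(mu_vehicle_ground, mu_pedestrian_ground, mu_pedestrian_vehicle)
  if (any(mus < 0)) stop("friction coefficients must be >= 0")
  structure(list(
    mu_vehicle_ground = mu_vehicle_ground,
    mu_pedestrian_ground = mu_pedestrian_ground,
    mu_pedestrian_vehicle = mu_pedestrian_vehicle,
    gravity = gravity, k_ground = k_ground, c_ground = c_ground
  ), class = "impact_environment")
}
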