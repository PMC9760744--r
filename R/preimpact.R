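# Pre-impact evidence utilities: vehicle speed from surveillance video
# frames, speed-variable bounds, and friction defaults.

#' Vehicle speed from video frames
#'
#' speed = distance / ((frame_end - frame_start) / fps): the reference
#' distance travelled between two video frames divided by the elapsed time.
#'
#' @param distance reference distance between the two vehicle positions, m
#' @param frame_start,frame_end frame numbers (integers, end > start)
#' @param fps video frame rate, frames/s
#' @return speed in m/s
#' @export
speed_from_video <- function(distance, frame_start, frame_end, fps) {
  if (fps <= 0) stop("fps must be > 0")
  if (distance < 0) stop("distance must be >= 0")
  if (frame_end <= frame_start) {
    stop("frame_end must be greater than frame_start")
  }
  distance / ((frame_end - frame_start) / fps)
}

#' Speed-variable bounds from a video estimate
#'
#' [estimate - half_width, estimate + half_width], with each bound snapped
#' to the nearest point of a 1 m/s grid (so the video estimate 17.96 m/s
#' with half-width 2 yields the study range [16, 20] m/s).
#'
#' @param estimate speed estimate, m/s
#' @param half_width half-width of the search range, m/s
#' @param grid rounding grid, m/s
#' @return numeric c(lower, upper)
#' @export
speed_bounds <- function(estimate, half_width = 2, grid = 1) {
  if (estimate <= half_width && half_width > 0) {
    stop("estimate must exceed half_width (non-positive lower bound)")
  }
  lo <- round((estimate - half_width) / grid) * grid
  hi <- round((estimate + half_width) / grid) * grid
  if (lo <= 0 && half_width > 0) stop("non-positive lower bound after rounding")
  c(lower = lo, upper = hi)
}

#' Friction-coefficient defaults by surface condition
#'
#' Returns the triplet (mu_vehicle_ground, mu_pedestrian_ground,
#' mu_pedestrian_vehicle). The wet-asphalt condition is (0.55, 0.6, 0.3).
#'
#' @param condition surface condition name
#' @return named numeric triplet
#' @export
friction_defaults <- function(condition = "wet_asphalt") {
  tab <- list(
    wet_asphalt = c(mu_vehicle_ground = 0.55, mu_pedestrian_ground = 0.6,
                    mu_pedestrian_vehicle = 0.3),
    dry_asphalt = c(mu_vehicle_ground = 0.75, mu_pedestrian_ground = 0.7,
                    mu_pedestrian_vehicle = 0.3)
  )
  if (!condition %in% names(tab)) {
    stop("unknown condition '", condition, "'; known: ",
         paste(names(tab), collapse = ", "))
  }
  tab[[condition]]
}
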