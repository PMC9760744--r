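# Injury-criterion post-processing: HIC and femur axial-force banding.

#' Head Injury Criterion
#'
#' HIC = max over windows [t1, t2] with t2 - t1 <= `max_window` of
#' (t2 - t1) * (mean resultant acceleration over the window)^2.5, with the
#' acceleration in g and time in seconds. The window mean uses the
#' trapezoidal integral of the sampled trace; the search is over all sample
#' pairs, accelerated by a cumulative integral.
#'
#' @param time strictly increasing, uniformly sampled times, s
#' @param accel resultant head CG acceleration, g (values >= 0)
#' @param max_window maximum window length, s (default 0.036; 0.015 for
#'   HIC15)
#' @return list with `hic`, `t1`, `t2`
#' @export
hic <- function(time, accel, max_window = 0.036) {
  n <- length(time)
  if (n == 0 || length(accel) != n) stop("empty or mismatched trace")
  if (max_window <= 0) stop("max_window must be > 0")
  if (n == 1) return(list(hic = 0, t1 = time[1], t2 = time[1]))
  dtv <- diff(time)
  if (any(dtv <= 0)) stop("time must be strictly increasing")
  if (diff(range(dtv)) > 1e-9 * mean(dtv)) {
    stop("trace must be uniformly sampled")
  }
  if (any(accel < 0)) stop("acceleration values must be >= 0")
  dt <- dtv[1]
  # cumulative trapezoidal integral
  cum <- c(0, cumsum((accel[-n] + accel[-1]) / 2 * dt))
  wmax <- max(1L, floor(max_window / dt + 1e-9))
  best <- 0; b1 <- time[1]; b2 <- time[min(2, n)]
  for (i in seq_len(n - 1)) {
    jmax <- min(n, i + wmax)
    js <- (i + 1):jmax
    tw <- time[js] - time[i]
    amean <- (cum[js] - cum[i]) / tw
    v <- tw * amean^2.5
    jbest <- which.max(v)
    if (v[jbest] > best) {
      best <- v[jbest]; b1 <- time[i]; b2 <- time[js[jbest]]
    }
  }
  list(hic = best, t1 = b1, t2 = b2)
}

#' Femur axial-force assessment
#'
#' Peak absolute axial force converted to kN, banded against the published
#' femur-fracture force range 3-10 kN: `"below"` (< 3 kN), `"within"`
#' ([3, 10] kN, boundaries inclusive) or `"above"` (> 10 kN). Forces at or
#' above the lower band boundary are flagged as consistent with fracture.
#'
#' @param force axial force trace in N (sign ignored)
#' @param time optional time vector to report the peak instant
#' @return list with `peak_kN`, `band`, `fracture_consistent`, `t_peak`
#' @export
femur_assessment <- function(force, time = NULL) {
  if (length(force) == 0) stop("empty force trace")
  af <- abs(force)
  i <- which.max(af)
  peak <- af[i] / 1000
  band <- if (peak < 3) "below" else if (peak <= 10) "within" else "above"
  list(peak_kN = peak, band = band,
       fracture_consistent = peak >= 3,
       t_peak = if (is.null(time)) NA_real_ else time[i])
}

#' Injury report for a simulation result
#'
#' @param result a [simulate_impact()] result
#' @param max_window HIC window, s
#' @return list with the HIC result and the femur assessment
#' @export
injury_report <- function(result, max_window = 0.036) {
  stopifnot(inherits(result, "simulation_result"))
  h <- hic(result$head_accel$time, result$head_accel$accel, max_window)
  f <- femur_assessment(result$femur_force$force, result$femur_force$time)
  list(hic = h, femur = f)
}
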