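# The five pre-impact parameters and their search bounds.

#' Design-variable bounds
#'
#' Defaults are the study ranges: V in [16, 20] m/s, D in [0.14, 0.54] m,
#' alpha in [0.30, 0.70] rad, beta and gamma in [-0.20, 0.20] rad.
#'
#' @param lower,upper named numeric vectors over `V, D, alpha, beta, gamma`
#' @return object of class `variable_bounds` (list with `lower`, `upper`)
#' @export
variable_bounds <- function(lower = c(V = 16, D = 0.14, alpha = 0.30,
                                      beta = -0.20, gamma = -0.20),
                            upper = c(V = 20, D = 0.54, alpha = 0.70,
                                      beta = 0.20, gamma = 0.20)) {
  if (!identical(names(lower), names(upper))) {
    stop("lower and upper must share variable names")
  }
  bad <- names(lower)[lower >= upper]
  if (length(bad)) {
    stop("invalid bounds (lower >= upper) for: ", paste(bad, collapse = ", "))
  }
  structure(list(lower = lower, upper = upper), class = "variable_bounds")
}

#' Construct a design vector
#'
#' The five pre-impact parameters: vehicle impact speed `V` (m/s),
#' pedestrian lateral offset from the vehicle's longitudinal axis `D` (m),
#' pedestrian yaw relative to the vehicle heading `alpha` (rad), head
#' up-down angle `beta` (rad) and head left-right angle `gamma` (rad).
#'
#' @param V,D,alpha,beta,gamma the parameters
#' @param bounds a [variable_bounds()]; components are checked against it
#' @return named numeric vector of class `design_vector`
#' @export
design_vector <- function(V, D, alpha, beta, gamma,
                          bounds = variable_bounds()) {
  x <- c(V = V, D = D, alpha = alpha, beta = beta, gamma = gamma)
  if (!is.null(bounds)) {
    lo <- bounds$lower[names(x)]
    hi <- bounds$upper[names(x)]
    bad <- names(x)[x < lo - 1e-12 | x > hi + 1e-12]
    if (length(bad)) {
      stop("design out of bounds for: ", paste(bad, collapse = ", "))
    }
  }
  structure(x, class = "design_vector")
}

.as_design <- function(x, bounds = NULL) {
  if (inherits(x, "design_vector")) return(x)
  x <- x[c("V", "D", "alpha", "beta", "gamma")]
  structure(x, class = "design_vector")
}
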