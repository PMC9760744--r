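# Configuration and result serialization: scenario YAML, evaluation-history
# JSONL, run manifests.

#' Load a scenario from a YAML file
#'
#' Missing sections fall back to the package defaults (dt 2e-5 s, t_end
#' 1.8 s, the study variable bounds, wet-asphalt friction, default sedan,
#' 1.75 m / 75 kg pedestrian). Recognized top-level keys: `pedestrian`
#' (height, mass, posture), `vehicle` (`"default_sedan"` or profile +
#' zones), `environment`, `design` (V, D, alpha, beta, gamma), `bounds`
#' (per-variable [lower, upper]), `dt`, `t_end`, `approach_gap`,
#' `evidence` (per-pair xyz marks, for case files).
#'
#' @param path YAML file path
#' @return a [scenario()]; any `evidence` block is attached as attribute
#'   `"evidence"`
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  pcfg <- cfg$pedestrian
  ped <- build_pedestrian(
    height = pcfg$height %||% 1.75,
    mass = pcfg$mass %||% 75,
    posture = pcfg$posture %||% "walking_arms_in_pockets")
  veh <- if (is.null(cfg$vehicle) || identical(cfg$vehicle, "default_sedan")) {
    default_sedan()
  } else {
    vc <- cfg$vehicle
    build_vehicle(
      profile = do.call(rbind, vc$profile),
      zone_specs = lapply(vc$zones, function(z)
        list(name = z$name, curve = do.call(rbind, z$curve),
             damping = z$damping %||% 200)),
      half_width = vc$half_width %||% 0.85,
      markers = vc$markers %||% list(),
      speed_initial = vc$speed_initial %||% 0,
      braking_decel = vc$braking_decel %||% 0)
  }
  ecfg <- cfg$environment
  env <- impact_environment(
    mu_vehicle_ground = ecfg$mu_vehicle_ground %||% 0.55,
    mu_pedestrian_ground = ecfg$mu_pedestrian_ground %||% 0.6,
    mu_pedestrian_vehicle = ecfg$mu_pedestrian_vehicle %||% 0.3,
    gravity = ecfg$gravity %||% 9.81)
  bounds <- if (is.null(cfg$bounds)) variable_bounds() else {
    bl <- cfg$bounds
    req <- c("V", "D", "alpha", "beta", "gamma")
    for (v in names(bl)) {
      if (bl[[v]][1] >= bl[[v]][2]) {
        stop("invalid bounds for ", v, ": lower ", bl[[v]][1],
             " >= upper ", bl[[v]][2])
      }
    }
    lo <- vapply(req, function(v) bl[[v]][1] %||% variable_bounds()$lower[[v]], 0.0)
    hi <- vapply(req, function(v) bl[[v]][2] %||% variable_bounds()$upper[[v]], 0.0)
    variable_bounds(setNames(lo, req), setNames(hi, req))
  }
  des <- if (is.null(cfg$design)) NULL else {
    dc <- cfg$design
    design_vector(dc$V, dc$D, dc$alpha, dc$beta, dc$gamma, bounds = bounds)
  }
  sc <- scenario(ped, veh, env, design = des,
                 dt = cfg$dt %||% 2e-5, t_end = cfg$t_end %||% 1.8,
                 approach_gap = cfg$approach_gap %||% 2.5, bounds = bounds)
  if (!is.null(cfg$evidence)) {
    attr(sc, "evidence") <- lapply(cfg$evidence, as.numeric)
  }
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scenario to YAML
#'
#' Round-trips with [load_scenario()] (up to the scenario hash).
#'
#' @param sc a [scenario()]
#' @param path output file
#' @param evidence optional named list of per-pair marks to embed
#' @export
save_scenario <- function(sc, path, evidence = NULL) {
  stopifnot(inherits(sc, "scenario"))
  veh <- sc$vehicle
  cfg <- list(
    pedestrian = list(height = sc$pedestrian$total_height,
                      mass = sc$pedestrian$total_mass,
                      posture = "walking_arms_in_pockets"),
    vehicle = list(
      profile = apply(veh$profile, 1, as.list),
      zones = lapply(veh$zones, function(z)
        list(name = z$name, curve = apply(as.matrix(z$curve), 1, as.list),
             damping = z$damping)),
      half_width = veh$half_width,
      speed_initial = veh$speed_initial,
      braking_decel = veh$braking_decel),
    environment = list(
      mu_vehicle_ground = sc$environment$mu_vehicle_ground,
      mu_pedestrian_ground = sc$environment$mu_pedestrian_ground,
      mu_pedestrian_vehicle = sc$environment$mu_pedestrian_vehicle,
      gravity = sc$environment$gravity),
    bounds = setNames(lapply(names(sc$bounds$lower), function(v)
      c(sc$bounds$lower[[v]], sc$bounds$upper[[v]])), names(sc$bounds$lower)),
    dt = sc$dt, t_end = sc$t_end, approach_gap = sc$approach_gap
  )
  if (!is.null(sc$design)) {
    cfg$design <- as.list(setNames(as.numeric(sc$design), names(sc$design)))
  }
  ev <- evidence %||% attr(sc, "evidence")
  if (!is.null(ev)) cfg$evidence <- lapply(ev, as.numeric)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Stable hash of a scenario configuration
#'
#' Canonicalizes the configuration (recursive key sort) before hashing, so
#' the hash is invariant under key reordering.
#'
#' @param sc a [scenario()]
#' @return md5 hex string
#' @export
scenario_hash <- function(sc) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(nzchar(names(x)))) {
        x <- x[order(names(x))]
      }
      lapply(x, canon)
    } else x
  }
  core <- canon(list(
    pedestrian = list(h = sc$pedestrian$total_height,
                      m = sc$pedestrian$total_mass,
                      posture = as.list(sc$pedestrian$posture)),
    vehicle = if (is.null(sc$vehicle)) NULL else list(
      profile = as.numeric(sc$vehicle$profile),
      zones = lapply(sc$vehicle$zones, function(z)
        list(name = z$name, curve = as.numeric(as.matrix(z$curve)),
             damping = z$damping)),
      half_width = sc$vehicle$half_width,
      braking = sc$vehicle$braking_decel),
    environment = unclass(sc$environment),
    design = if (is.null(sc$design)) NULL else as.numeric(sc$design),
    bounds = list(lo = as.numeric(sc$bounds$lower),
                  hi = as.numeric(sc$bounds$upper)),
    dt = sc$dt, t_end = sc$t_end, gap = sc$approach_gap
  ))
  txt <- paste(deparse(core), collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Write an optimization history as JSONL
#'
#' One JSON object per evaluation, full float precision.
#'
#' @param history an `optimization_history`
#' @param path output file
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "optimization_history"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(algorithm = history$algorithm, seed = history$seed,
               population = history$population,
               generations = history$generations, n_var = history$n_var,
               n_obj = history$n_obj, var_names = history$var_names)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
  df <- history$evals
  if (!is.null(df)) {
    for (i in seq_len(nrow(df))) {
      # 17 significant digits round-trips IEEE doubles exactly
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = I(17)), con)
    }
  }
  invisible(path)
}

#' Read an optimization history written by [write_history()]
#'
#' @param path JSONL file
#' @return an `optimization_history`
#' @export
read_history <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty history file: ", path)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e) stop("corrupt history line ", i, " in ",
                                      path, ": ", conditionMessage(e),
                                      call. = FALSE))
  }
  meta <- parse_line(1)
  hist <- .new_history(meta$algorithm, meta$seed, meta$population,
                       meta$generations, meta$n_var, meta$n_obj,
                       meta$var_names)
  if (length(lines) > 1) {
    rows <- lapply(seq(2, length(lines)), function(i) {
      as.data.frame(parse_line(i), stringsAsFactors = FALSE)
    })
    hist$evals <- do.call(rbind, rows)
  }
  hist
}

#' Write a run manifest
#'
#' @param path output JSON file
#' @param scenario the [scenario()] used
#' @param algorithm,settings,seed run configuration
#' @param outputs character vector of produced files
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(path, scenario, algorithm = NA, settings = list(),
                           seed = NA, outputs = character(0)) {
  manifest <- list(
    tool = "pedrecon",
    version = as.character(utils::packageVersion("pedrecon")),
    scenario_hash = scenario_hash(scenario),
    algorithm = algorithm, settings = settings, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
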