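# Design of experiments over marker-pair subsets: group enumeration,
# algorithm x group campaigns, and summary statistics.

#' Enumerate marker-pair groups
#'
#' All subsets of the pair ids of at least `min_size` members, ordered by
#' size then lexicographically, each labelled by contact class:
#' `vehicle-pedestrian-ground` when pair IV (the head-ground pair) is
#' included, `vehicle-pedestrian` otherwise. Four pairs with `min_size = 2`
#' give the 11 study groups (6 pairs + 4 triples + 1 quadruple).
#'
#' @param pair_ids character vector of pair ids (default the four pairs)
#' @param min_size minimum subset size (default 2)
#' @return list of `group_spec` objects (`id`, `pair_ids`, `contact_class`)
#' @export
enumerate_groups <- function(pair_ids = c("I", "II", "III", "IV"),
                             min_size = 2) {
  pair_ids <- as.character(pair_ids)
  if (min_size > length(pair_ids)) {
    stop("min_size (", min_size, ") exceeds the number of pair ids (",
         length(pair_ids), ")")
  }
  out <- list()
  gid <- 0L
  for (k in seq(min_size, length(pair_ids))) {
    subs <- combn(sort(pair_ids), k, simplify = FALSE)
    # lexicographic within size
    key <- vapply(subs, paste, "", collapse = ",")
    for (s in subs[order(key)]) {
      gid <- gid + 1L
      out[[gid]] <- structure(list(
        id = gid, pair_ids = s,
        contact_class = if ("IV" %in% s) "vehicle-pedestrian-ground"
        else "vehicle-pedestrian"
      ), class = "group_spec")
    }
  }
  out
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square ratio and its F-distribution tail
#' probability. With zero within-group variance and equal group means the
#' statistic is defined as 0.
#'
#' @param samples list of >= 2 numeric vectors, each of length >= 2
#' @return list with `F`, `p`, `df` (c(between, within))
#' @export
anova_oneway <- function(samples) {
  if (!is.list(samples) || length(samples) < 2) {
    stop("need at least 2 groups")
  }
  if (any(vapply(samples, length, 0L) < 2)) {
    stop("every group needs at least 2 values")
  }
  ni <- vapply(samples, length, 0L)
  n <- sum(ni)
  k <- length(samples)
  means <- vapply(samples, mean, 0.0)
  grand <- sum(ni * means) / n
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum(vapply(samples, function(x) sum((x - mean(x))^2), 0.0))
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0) {
    Fv <- if (ssb == 0) 0 else Inf
  } else {
    Fv <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(Fv)) 0 else pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df = c(df1, df2))
}

#' Remove outliers by Tukey fences
#'
#' One pass of the 1.5 x IQR rule: values outside
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR] are removed.
#'
#' @param values numeric vector of length >= 4
#' @return list with `kept` (values) and `removed` (indices into `values`)
#' @export
remove_outliers <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  q <- quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  rm <- which(values < lo | values > hi)
  list(kept = if (length(rm)) values[-rm] else values, removed = rm)
}

#' Run an algorithm x group x seed reconstruction campaign
#'
#' Executes every combination against a ground-truth case's evidence,
#' collects per-run best objective values and solution counts, removes
#' outliers by the Tukey rule, and compares algorithms by one-way ANOVA on
#' per-seed best objective values.
#'
#' @param case a [generate_case()] ground-truth case
#' @param groups list of group specs from [enumerate_groups()] (or character
#'   vectors of pair ids)
#' @param algorithms subset of `c("nsga2", "ncga", "mopso")`
#' @param seeds integer vector of seeds (one run per seed)
#' @param population,generations optimizer budget per run
#' @param keep_histories retain the full histories (memory heavy)
#' @return a `campaign_summary`
#' @export
run_campaign <- function(case, groups, algorithms = c("nsga2", "ncga", "mopso"),
                         seeds = 1:3, population = 20, generations = 20,
                         keep_histories = FALSE) {
  stopifnot(length(groups) >= 1, length(algorithms) >= 1, length(seeds) >= 1)
  algorithms <- match.arg(algorithms, c("nsga2", "ncga", "mopso"),
                          several.ok = TRUE)
  rows <- list()
  best <- list()
  histories <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    pair_ids <- if (inherits(g, "group_spec")) g$pair_ids else as.character(g)
    gl <- paste(pair_ids, collapse = ",")
    for (alg in algorithms) {
      per_seed <- numeric(0)
      best_row <- NULL
      counts_acc <- c(noninferior = 0, inferior = 0, local_optimal = 0)
      for (sd in seeds) {
        h <- tryCatch(
          reconstruct(case, group = pair_ids, algorithm = alg, seed = sd,
                      population = population, generations = generations),
          error = function(e) NULL)
        if (is.null(h)) {
          per_seed <- c(per_seed, NA_real_)
          next
        }
        cl <- classify_history(h)
        counts_acc <- counts_acc + c(cl$noninferior, cl$inferior, cl$local_optimal)
        bf <- best_feasible(h)
        per_seed <- c(per_seed, bf)
        if (!is.null(cl$global_best) &&
            (is.null(best_row) || cl$global_best$F_sum < best_row$F_sum)) {
          best_row <- cl$global_best
          best_row$seed <- sd
        }
        if (keep_histories) {
          histories[[paste(gl, alg, sd, sep = "|")]] <- h
        }
      }
      ok <- per_seed[is.finite(per_seed)]
      flt <- if (length(ok) >= 4) remove_outliers(ok) else list(kept = ok, removed = integer(0))
      rows[[paste(gl, alg, sep = "|")]] <- data.frame(
        group = gl, algorithm = alg,
        n_runs = length(seeds), n_ok = length(ok),
        best_F = if (length(ok)) min(ok) else NA_real_,
        mean_F = if (length(flt$kept)) mean(flt$kept) else NA_real_,
        median_F = if (length(flt$kept)) median(flt$kept) else NA_real_,
        n_outliers = length(flt$removed),
        noninferior = counts_acc[["noninferior"]],
        inferior = counts_acc[["inferior"]],
        local_optimal = counts_acc[["local_optimal"]],
        stringsAsFactors = FALSE
      )
      best[[paste(gl, alg, sep = "|")]] <-
        list(group = gl, algorithm = alg, best = best_row,
             per_seed_best = per_seed)
    }
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  # ANOVA across algorithms on per-seed bests, pooled over groups
  anova <- NULL
  if (length(algorithms) >= 2) {
    samples <- lapply(algorithms, function(alg) {
      v <- unlist(lapply(best[grepl(paste0("\\|", alg, "$"), names(best))],
                         function(b) b$per_seed_best))
      v[is.finite(v)]
    })
    names(samples) <- algorithms
    if (all(vapply(samples, length, 0L) >= 2)) {
      pooled <- lapply(samples, function(v)
        if (length(v) >= 4) remove_outliers(v)$kept else v)
      anova <- anova_oneway(pooled)
    }
  }
  structure(list(summary = summary_df, best = best, anova = anova,
                 histories = if (keep_histories) histories else NULL,
                 seeds = seeds),
            class = "campaign_summary")
}

#' @export
print.campaign_summary <- function(x, ...) {
  cat("<campaign_summary> ", nrow(x$summary), " (group x algorithm) cells, ",
      length(x$seeds), " seeds each\n", sep = "")
  print(x$summary)
  if (!is.null(x$anova)) {
    cat(sprintf("one-way ANOVA across algorithms: F = %.4g, p = %.3g\n",
                x$anova$F, x$anova$p))
  }
  invisible(x)
}
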