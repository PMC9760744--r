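# Group enumeration, ANOVA, outlier rule, campaign bookkeeping.

test_that("four pairs enumerate to the 11 study groups", {
  g <- enumerate_groups(c("I", "II", "III", "IV"), min_size = 2)
  expect_length(g, 11)
  sizes <- vapply(g, function(x) length(x$pair_ids), 0L)
  expect_equal(unname(table(sizes)), c(6L, 4L, 1L), ignore_attr = TRUE)
  # the ground class is exactly membership of pair IV
  for (x in g) {
    expect_identical(x$contact_class == "vehicle-pedestrian-ground",
                     "IV" %in% x$pair_ids)
  }
  # deterministic ordering: by size then lexicographic
  expect_identical(vapply(g[1:3], function(x) paste(x$pair_ids, collapse = ","), ""),
                   c("I,II", "I,III", "I,IV"))
})

test_that("group counts follow the binomial sum", {
  expect_length(enumerate_groups(c("I", "II", "III"), 2), 4)
  expect_length(enumerate_groups(c("I", "II"), 2), 1)
  expect_length(enumerate_groups(c("I", "II", "III", "IV"), 1), 15)
  expect_error(enumerate_groups(c("I", "II"), 3), "min_size")
})

test_that("one-way ANOVA matches the hand computation and base R", {
  a <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a$F, 13.5)
  expect_equal(a$df, c(1, 4))
  # two identical groups
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  # zero within-group variance, equal means
  expect_equal(anova_oneway(list(c(2, 2), c(2, 2)))$F, 0)
  # cross-implementation oracle on random normal groups
  set.seed(31)
  for (rep in 1:5) {
    g <- lapply(1:3, function(i) rnorm(30, mean = i * 0.2))
    a <- anova_oneway(g)
    df <- data.frame(y = unlist(g),
                     grp = factor(rep(1:3, each = 30)))
    ref <- anova(aov(y ~ grp, data = df))
    expect_equal(a$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(a$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
  expect_error(anova_oneway(list(c(1, 2), 3)), "at least 2 values")
})

test_that("Tukey fences remove gross outliers once and are idempotent", {
  r <- remove_outliers(c(1, 1, 1, 1, 100))
  expect_equal(r$removed, 5L)
  expect_equal(r$kept, rep(1, 4))
  r2 <- remove_outliers(c(1, 1, 1, 1))
  expect_length(r2$removed, 0)
  # idempotence when nothing is removed
  v <- c(2, 3, 4, 5, 6)
  expect_identical(remove_outliers(remove_outliers(v)$kept)$kept,
                   remove_outliers(v)$kept)
  expect_error(remove_outliers(c(1, 2, 3)), "4 values")
})

test_that("a small campaign aggregates runs and is invariant to group order", {
  case <- shared_case()
  gA <- list(c("I", "II"), c("I", "IV"))
  s1 <- run_campaign(case, gA, algorithms = "nsga2", seeds = 1:2,
                     population = 4, generations = 3)
  expect_s3_class(s1, "campaign_summary")
  expect_equal(nrow(s1$summary), 2)
  expect_equal(unique(s1$summary$n_runs), 2)
  # reordering the groups leaves per-group results unchanged
  s2 <- run_campaign(case, rev(gA), algorithms = "nsga2", seeds = 1:2,
                     population = 4, generations = 3)
  m1 <- s1$summary[order(s1$summary$group), ]
  m2 <- s2$summary[order(s2$summary$group), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("campaign best equals the minimum feasible objective of its runs", {
  case <- shared_case()
  s <- run_campaign(case, list(c("I", "IV")), algorithms = "nsga2",
                    seeds = 1:2, population = 4, generations = 3,
                    keep_histories = TRUE)
  per_seed <- s$best[[1]]$per_seed_best
  mins <- vapply(s$histories, best_feasible, 0.0)
  expect_equal(sort(per_seed[is.finite(per_seed)]),
               sort(unname(mins[is.finite(mins)])))
  expect_equal(s$summary$best_F[1], min(per_seed, na.rm = TRUE))
})
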