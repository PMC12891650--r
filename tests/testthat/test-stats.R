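# Inference stage: plane exclusion, normality checks, one-way ANOVA,
# Bonferroni pairwise comparisons, group summaries.

make_measurements <- function(missing_plane1 = 0L, n = 12L) {
  ids <- sprintf("s%02d", 1:n)
  do.call(rbind, lapply(1:5, function(p) {
    unm <- p == 1L & seq_len(n) <= missing_plane1
    data.frame(subject_id = ids, group = rep(GROUPS <- c("Nulli", "POP"), n / 2),
               plane = p,
               left_ica_deg = ifelse(unm, NA, 45), right_ica_deg = ifelse(unm, NA, 45),
               total_ica_deg = ifelse(unm, NA, 90), measurable = !unm)
  }))
}

test_that("the plane-exclusion rule drops planes with unmeasurable subjects", {
  m <- make_measurements(missing_plane1 = 9L)
  ex <- apply_plane_exclusion(m)
  expect_equal(ex$eligible, 2:5)
  expect_equal(unname(ex$missing_counts["1"]), 9L)
  expect_match(ex$excluded$reason, "9 subject")

  expect_equal(apply_plane_exclusion(make_measurements())$eligible, 1:5)
  expect_equal(apply_plane_exclusion(m, threshold = 10L)$eligible, 1:5)
})

test_that("Shapiro-Wilk per group matches an independent implementation", {
  set.seed(41)
  v <- stats::rnorm(50)
  res <- shapiro_per_group(v, rep("g", 50))
  script <- paste("import scipy.stats, json",
                  sprintf("x = %s", jsonlite::toJSON(v, digits = NA)),
                  "w, p = scipy.stats.shapiro(x)",
                  "print(json.dumps([w, p]))", sep = "\n")
  ref <- jsonlite::fromJSON(system2("python", "-", stdout = TRUE, input = script))
  expect_equal(res$W, ref[1], tolerance = 1e-6)
  expect_equal(res$p, ref[2], tolerance = 1e-6)

  const <- shapiro_per_group(rep(5, 10), rep("g", 10))
  expect_false(const$testable)
})

test_that("heavily skewed samples are rejected as non-normal", {
  set.seed(42)
  rejections <- vapply(1:100, function(i) {
    shapiro_per_group(stats::rexp(50), rep("g", 50))$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("one-way ANOVA matches the hand-computed 9-observation fixture", {
  # groups (1,2,3), (2,3,4), (6,7,8): SSB = 42 (df 2), SSW = 6 (df 6) -> F = 21
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_per_plane(v, g)
  expect_equal(res$F, 21)
  expect_equal(res$p, stats::pf(21, 2, 6, lower.tail = FALSE))

  ident <- anova_per_plane(rep(3, 8), rep(c("a", "b"), 4))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)
})

test_that("ANOVA F equals the lm() decomposition on random fixtures", {
  set.seed(43)
  for (i in 1:10) {
    g <- sample(c("a", "b", "c", "d"), 40, replace = TRUE)
    v <- stats::rnorm(40, mean = as.integer(factor(g)))
    res <- anova_per_plane(v, g)
    ref <- stats::anova(stats::lm(v ~ g))
    expect_equal(res$F, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment is exactly 6x raw, monotone and capped", {
  set.seed(44)
  g <- rep(c("Nulli", "Par-pre", "Par-post", "POP"), each = 10)
  v <- stats::rnorm(40) + ifelse(g == "POP", 2, 0)
  pw <- bonferroni_pairwise(v, g)
  expect_equal(nrow(pw), 6L)
  expect_equal(pw$p_adj, pmin(1, 6 * pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw & pw$p_adj <= 1))

  # raw p via the pooled-variance closed form, one pair checked by hand
  v1 <- v[g == "Nulli"]; v2 <- v[g == "POP"]
  sp2 <- ((length(v1) - 1) * stats::var(v1) + (length(v2) - 1) * stats::var(v2)) /
    (length(v1) + length(v2) - 2)
  tstat <- (mean(v1) - mean(v2)) / sqrt(sp2 * (1 / length(v1) + 1 / length(v2)))
  praw <- 2 * stats::pt(-abs(tstat), length(v1) + length(v2) - 2)
  row <- pw[pw$group1 == "Nulli" & pw$group2 == "POP", ]
  expect_equal(row$p_raw, praw, tolerance = 1e-12)

  same <- bonferroni_pairwise(rep(1:5, 4), rep(c("a", "b"), each = 10))
  expect_equal(same$p_adj, 1)

  tiny <- bonferroni_pairwise(c(1, 2, 3, 5), c("a", "a", "a", "b"))
  expect_false(tiny$testable[1])
})

test_that("permuting group labels yields uniform ANOVA p-values", {
  set.seed(45)
  v <- stats::rnorm(55, 80, 15)
  g <- rep(c("Nulli", "Par-pre", "Par-post", "POP"), c(14, 13, 12, 16))
  ps <- vapply(1:500, function(i) anova_per_plane(v, sample(g))$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("group summaries flag single-subject groups and skip empty ones", {
  m <- data.frame(subject_id = c("a", "b", "c"),
                  group = c("Nulli", "Nulli", "POP"), plane = 2,
                  left_ica_deg = c(50, 52, 60), right_ica_deg = c(48, 50, 62),
                  total_ica_deg = c(82, 78, 58), measurable = TRUE)
  s <- summarize_groups(m)$summary
  expect_equal(s$mean_total[s$group == "Nulli"], 80)
  pop <- s[s$group == "POP", ]
  expect_true(pop$single_subject)
  expect_equal(pop$sd_total, 0)
  empty <- s[s$group == "Par-pre", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean_total))
})

test_that("simulated cohorts at printed group parameters recover their means", {
  pars <- default_cohort_parameters()
  for (g in names(pars)) pars[[g]]$n <- 10000L
  sim <- simulate_cohort(cohort_sim_spec(groups = pars, seed = 46))
  for (g in names(pars)) {
    for (k in 2:5) {
      sub <- sim$measurements[sim$measurements$group == g &
                              sim$measurements$plane == k, ]
      se <- pars[[g]]$plane_sd[k] / sqrt(10000)
      expect_lt(abs(mean(sub$total_ica_deg) - pars[[g]]$plane_mean[k]), 2.5 * se)
    }
  }
})

test_that("ica_group_test composes exclusion, ANOVA and post hoc", {
  sim <- simulate_cohort(cohort_sim_spec(seed = 47))
  res <- ica_group_test(sim$measurements)
  expect_equal(res$exclusion$eligible, 2:5)   # 9 avulsion subjects at plane 1
  expect_lt(res$per_plane[["4"]]$anova$p, 0.001)
  pw4 <- res$per_plane[["4"]]$pairwise
  expect_true(pw4$significant[pw4$group1 == "Nulli" & pw4$group2 == "POP"])
})
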