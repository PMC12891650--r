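# Cohort inference on per-plane total ICA: the plane-exclusion rule
# (a plane with unmeasurable subjects is dropped from statistics),
# Shapiro-Wilk normality checks per group, classical one-way fixed-effects
# ANOVA per plane and Bonferroni-adjusted pairwise comparisons.

#' Plane-exclusion rule for statistical analysis
#'
#' A plane is omitted from inference when the number of subjects for whom
#' the angle could not be measured there exceeds `threshold`. The default
#' threshold of 0 is the strict reading: any subject with an unmeasurable
#' angle (e.g. an avulsion gap in the most anterior plane) excludes that
#' plane.
#'
#' @param measurements data.frame in the layout of [read_measurements()]
#'   (columns `subject_id`, `plane`, `measurable`).
#' @param threshold maximum tolerated number of unmeasurable subjects.
#' @return List with `eligible` (integer plane indices), `missing_counts`
#'   (named integer vector per plane) and `excluded` (data.frame `plane`,
#'   `n_missing`, `reason`).
#' @export
apply_plane_exclusion <- function(measurements, threshold = 0L) {
  planes <- sort(unique(measurements$plane))
  miss <- vapply(planes, function(p)
    sum(!measurements$measurable[measurements$plane == p]), integer(1))
  names(miss) <- planes
  drop <- miss > threshold
  excluded <- data.frame(
    plane = planes[drop], n_missing = miss[drop],
    reason = sprintf("%d subject(s) unmeasurable (threshold %d)",
                     miss[drop], threshold),
    row.names = NULL, stringsAsFactors = FALSE)
  list(eligible = planes[!drop], missing_counts = miss, excluded = excluded)
}

#' Shapiro-Wilk normality check per group
#'
#' Reported per group, never used to gate the ANOVA.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return data.frame `group`, `n`, `W`, `p`, `testable` (FALSE for n < 3
#'   or constant samples).
#' @export
shapiro_per_group <- function(values, groups) {
  rows <- lapply(unique(as.character(groups)), function(g) {
    v <- values[groups == g & !is.na(values)]
    if (length(v) < 3L || length(unique(v)) == 1L)
      return(data.frame(group = g, n = length(v), W = NA_real_, p = NA_real_,
                        testable = FALSE))
    sw <- stats::shapiro.test(v)
    data.frame(group = g, n = length(v), W = unname(sw$statistic),
               p = sw$p.value, testable = TRUE)
  })
  do.call(rbind, rows)
}

#' Classical one-way fixed-effects ANOVA
#'
#' @param values numeric response.
#' @param groups grouping vector.
#' @return List `F`, `p`, `df_between`, `df_within`. Degenerate input with
#'   all values identical yields `F = 0`, `p = 1`.
#' @export
anova_per_plane <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  tab <- table(groups)
  if (sum(tab >= 2L) < 2L || length(tab) < 2L)
    stop("ANOVA needs at least 2 groups with n >= 2")
  k <- length(tab); N <- length(values)
  grand <- mean(values)
  mg <- tapply(values, groups, mean)
  ssb <- sum(tab * (mg[names(tab)] - grand)^2)
  ssw <- sum((values - mg[groups])^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df_between = df1, df_within = df2))
    return(list(F = Inf, p = 0, df_between = df1, df_within = df2))
  }
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Pairwise two-sample t tests between all group pairs, with the raw
#' p-values multiplied by the number of pairs (6 for four groups) and
#' capped at 1 — the textbook Bonferroni post hoc after a one-way ANOVA.
#' Pooled-variance t by default; Welch optional.
#'
#' @param values numeric response.
#' @param groups grouping vector.
#' @param alpha significance level for the `significant` flag.
#' @param welch use Welch's t instead of pooled-variance t.
#' @return data.frame `group1`, `group2`, `t`, `p_raw`, `p_adj`,
#'   `significant`, `testable` (FALSE when a group has n < 2).
#' @export
bonferroni_pairwise <- function(values, groups, alpha = 0.05, welch = FALSE) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  gl <- unique(groups)
  pairs <- utils::combn(gl, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    if (length(v1) < 2L || length(v2) < 2L)
      return(data.frame(group1 = g1, group2 = g2, t = NA_real_,
                        p_raw = NA_real_, p_adj = NA_real_,
                        significant = NA, testable = FALSE))
    if (stats::var(v1) == 0 && stats::var(v2) == 0 && mean(v1) == mean(v2)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(v1, v2, var.equal = !welch)
    }
    p_adj <- min(1, m * tt$p.value)
    data.frame(group1 = g1, group2 = g2, t = unname(tt$statistic),
               p_raw = tt$p.value, p_adj = p_adj,
               significant = p_adj < alpha, testable = TRUE)
  })
  do.call(rbind, rows)
}

#' Per-plane per-group summary of ICA measurements
#'
#' Means and SDs over measurable values only, at full precision; the
#' `rounded` component holds the integer-degree presentation layer
#' (mean total (SD) and left/right side angles) typically used in reports.
#'
#' @param measurements data.frame in [read_measurements()] layout with a
#'   `group` column.
#' @return List with `summary` (data.frame: `plane`, `group`, `n`,
#'   `mean_total`, `sd_total`, `mean_left`, `mean_right`, `single_subject`
#'   flag) and `rounded` (same rows, integer degrees as character).
#' @export
summarize_groups <- function(measurements) {
  planes <- sort(unique(measurements$plane))
  rows <- list()
  for (p in planes) {
    for (g in GROUP_LEVELS) {
      sub <- measurements[measurements$plane == p & measurements$group == g &
                          measurements$measurable %in% TRUE, , drop = FALSE]
      n <- nrow(sub)
      rows[[length(rows) + 1L]] <- data.frame(
        plane = p, group = g, n = n,
        mean_total = if (n) mean(sub$total_ica_deg) else NA_real_,
        sd_total = if (n >= 2L) stats::sd(sub$total_ica_deg) else
          if (n == 1L) 0 else NA_real_,
        mean_left = if (n) mean(sub$left_ica_deg) else NA_real_,
        mean_right = if (n) mean(sub$right_ica_deg) else NA_real_,
        single_subject = n == 1L,
        stringsAsFactors = FALSE)
    }
  }
  s <- do.call(rbind, rows)
  rounded <- data.frame(
    plane = s$plane, group = s$group,
    cell = ifelse(is.na(s$mean_total), "",
                  sprintf("%d (+/- %d) [%d | %d]",
                          round_half_away(s$mean_total, 0),
                          round_half_away(s$sd_total, 0),
                          round_half_away(s$mean_left, 0),
                          round_half_away(s$mean_right, 0))),
    stringsAsFactors = FALSE)
  list(summary = s, rounded = rounded)
}

#' Full inference stage on a cohort measurement table
#'
#' Applies the plane-exclusion rule, then per eligible plane runs the
#' Shapiro-Wilk check per group, the one-way ANOVA and the Bonferroni
#' post hoc comparisons.
#'
#' @param measurements measurement table with `group` column (see
#'   [read_measurements()]).
#' @param alpha significance level.
#' @param threshold plane-exclusion threshold, see [apply_plane_exclusion()].
#' @param welch use Welch pairwise t tests.
#' @return Object of class `"ica_group_test"`: list with `exclusion`,
#'   `summary` (from [summarize_groups()]), and per-plane `anova`,
#'   `shapiro`, `pairwise`.
#' @export
ica_group_test <- function(measurements, alpha = 0.05, threshold = 0L,
                           welch = FALSE) {
  excl <- apply_plane_exclusion(measurements, threshold)
  planes <- excl$eligible
  res <- list()
  for (p in planes) {
    sub <- measurements[measurements$plane == p &
                        measurements$measurable %in% TRUE, , drop = FALSE]
    res[[as.character(p)]] <- list(
      plane = p,
      shapiro = shapiro_per_group(sub$total_ica_deg, sub$group),
      anova = anova_per_plane(sub$total_ica_deg, sub$group),
      pairwise = bonferroni_pairwise(sub$total_ica_deg, sub$group,
                                     alpha = alpha, welch = welch))
  }
  structure(list(exclusion = excl, summary = summarize_groups(measurements),
                 per_plane = res, alpha = alpha),
            class = "ica_group_test")
}

#' @export
print.ica_group_test <- function(x, ...) {
  cat("Cohort inference on total ICA\n")
  if (nrow(x$exclusion$excluded))
    cat("  planes excluded:",
        paste(x$exclusion$excluded$plane, collapse = ", "), "\n")
  for (r in x$per_plane) {
    cat(sprintf("  plane %d: F(%d,%d) = %.2f, p = %s\n", r$plane,
                r$anova$df_between, r$anova$df_within, r$anova$F,
                format.pval(r$anova$p, digits = 3, eps = 1e-3)))
    sig <- r$pairwise[r$pairwise$significant %in% TRUE, , drop = FALSE]
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s vs %s: adj p = %s\n", sig$group1[i], sig$group2[i],
                  format.pval(sig$p_adj[i], digits = 3, eps = 1e-3)))
  }
  invisible(x)
}
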