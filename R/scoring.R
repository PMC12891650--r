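# Expert defect-score aggregation for the pubococcygeus (PCM) and
# iliococcygeus (ICM) muscles. Each side is scored 0-3 by an expert
# protocol (PCM on supine images, ICM upright); the package only
# aggregates: total = left + right, categorized as none (0), minor (1-3)
# or major (4-6), with any single side score of 3 forcing major. For the
# ICM a side score of 3 denotes a hernia.

# rounding half away from zero, one decimal: base round() halves-to-even
# would print 16.2 for 16.25
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate per-side defect scores into a category
#'
#' @param muscle `"PCM"` or `"ICM"`.
#' @param left,right integer side scores in 0..3.
#' @return List of class `"defect_category"`: `muscle`, `left`, `right`,
#'   `total` (0-6), `category` (`"none"`, `"minor"`, `"major"`) and
#'   `hernia` (`TRUE` iff ICM and either side scored 3).
#' @examples
#' categorize_defect("PCM", 1, 2)$category   # "minor"
#' categorize_defect("PCM", 3, 0)$category   # "major" (side-3 override)
#' @export
categorize_defect <- function(muscle, left, right) {
  muscle <- match.arg(muscle, c("PCM", "ICM"))
  for (s in c(left, right))
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s != as.integer(s) ||
        s < 0 || s > 3)
      stop("side scores must be single integers in 0..3")
  total <- as.integer(left + right)
  category <- if (total == 0L) "none"
              else if (total <= 3L && left < 3L && right < 3L) "minor"
              else "major"
  structure(list(muscle = muscle, left = as.integer(left),
                 right = as.integer(right), total = total,
                 category = category,
                 hernia = muscle == "ICM" && (left == 3L || right == 3L)),
            class = "defect_category")
}

#' @export
print.defect_category <- function(x, ...) {
  cat(sprintf("%s defect: left %d + right %d = %d -> %s%s\n", x$muscle,
              x$left, x$right, x$total, x$category,
              if (x$hernia) " (hernia)" else ""))
  invisible(x)
}

#' Categorize a table of per-side scores
#'
#' @param scores data.frame with columns `subject_id`, `muscle`, `left`,
#'   `right` (see [read_scores()]).
#' @return data.frame with one row per input row plus `total`, `category`,
#'   `hernia`.
#' @export
categorize_scores <- function(scores) {
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    d <- categorize_defect(scores$muscle[i], scores$left[i], scores$right[i])
    data.frame(subject_id = scores$subject_id[i], muscle = d$muscle,
               left = d$left, right = d$right, total = d$total,
               category = d$category, hernia = d$hernia,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-group prevalence of defect categories
#'
#' Tabulates, per study group and muscle, the count and percentage of
#' subjects with none / minor / major defects. Percentages are
#' `100 * count / n_scored`, rounded half away from zero to one decimal.
#' Included subjects without a score for a muscle are tallied as
#' `unscored` and excluded from that muscle's denominator.
#'
#' @param manifest a [cohort_manifest()] (only non-excluded rows are used).
#' @param categories output of [categorize_scores()].
#' @return List with `table` (data.frame: `group`, `muscle`, `n`,
#'   `category`, `count`, `percent`) and `unscored` (data.frame of
#'   subject/muscle pairs without a score).
#' @export
prevalence_table <- function(manifest, categories) {
  inc <- if (inherits(manifest, "cohort_manifest"))
    manifest[!manifest$excluded, , drop = FALSE] else manifest
  cats <- c("none", "minor", "major")
  rows <- list(); unscored <- list()
  for (g in GROUP_LEVELS) {
    ids <- inc$subject_id[inc$group == g]
    if (!length(ids)) next
    for (mus in c("PCM", "ICM")) {
      sub <- categories[categories$subject_id %in% ids &
                        categories$muscle == mus, , drop = FALSE]
      missing <- setdiff(ids, sub$subject_id)
      if (length(missing))
        unscored[[length(unscored) + 1L]] <-
          data.frame(subject_id = missing, group = g, muscle = mus,
                     stringsAsFactors = FALSE)
      n <- nrow(sub)
      for (cat in cats) {
        cnt <- sum(sub$category == cat)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, muscle = mus, n = n, category = cat, count = cnt,
          percent = if (n > 0) round_half_away(100 * cnt / n, 1) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, rows),
       unscored = if (length(unscored)) do.call(rbind, unscored) else
         data.frame(subject_id = character(0), group = character(0),
                    muscle = character(0)))
}
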