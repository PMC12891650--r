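# Tabular I/O: landmark files (3D Slicer FCSV and plain CSV), expert defect
# score files, cohort manifests (JSON or CSV) and measurement output tables.

#' Default landmark label alias map
#'
#' Maps the canonical labels `PS`, `SCJ`, `IS_L`, `IS_R` to the spellings
#' accepted in landmark files (case-insensitive).
#'
#' @return Named list of character vectors.
#' @export
default_landmark_aliases <- function() {
  list(PS   = c("PS", "pubic_symphysis", "symphysis"),
       SCJ  = c("SCJ", "sacrococcygeal_joint", "SJ"),
       IS_L = c("IS_L", "ISL", "iL", "ischial_spine_left", "left_ischial_spine"),
       IS_R = c("IS_R", "ISR", "iR", "ischial_spine_right", "right_ischial_spine"))
}

canonical_label <- function(labels, aliases) {
  out <- rep(NA_character_, length(labels))
  for (canon in names(aliases)) {
    hit <- tolower(labels) %in% tolower(aliases[[canon]])
    out[hit] <- canon
  }
  out
}

landmarks_from_table <- function(label, xyz, convention, path) {
  if (identical(convention, "LPS")) {
    # Slicer stores LPS in recent versions; NIfTI world (our contract) is RAS
    xyz[, 1] <- -xyz[, 1]
    xyz[, 2] <- -xyz[, 2]
  }
  for (req in c("PS", "SCJ", "IS_L", "IS_R")) {
    n <- sum(label == req, na.rm = TRUE)
    if (n == 0L) stop("landmark missing: ", req, " (", path, ")")
    if (n > 1L) stop("duplicate landmark: ", req, " (", path, ")")
  }
  row_of <- function(l) as.numeric(xyz[which(label == l), ])
  landmark_set(row_of("PS"), row_of("SCJ"), row_of("IS_L"), row_of("IS_R"))
}

#' Read pelvic landmarks from an FCSV or CSV file
#'
#' Two dialects are supported. `"fcsv"` is the 3D Slicer markups fiducial
#' table: comment header lines starting with `#`, data columns including
#' `x`, `y`, `z` and `label` (column positions are taken from the
#' `# columns = ...` header when present, else Slicer's standard layout).
#' `"csv"` is a plain table with header `subject_id,label,x_mm,y_mm,z_mm`.
#' Rows whose label is not one of the four landmarks (after alias mapping)
#' are ignored.
#'
#' Slicer writes world coordinates in RAS or LPS depending on version; the
#' `# CoordinateSystem` header line declares which. Since mask affines
#' follow the NIfTI RAS convention, LPS input is sign-flipped in x and y.
#' `convention` overrides the file's declaration when the metadata is known
#' to be wrong.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"fcsv"` or `"csv"`.
#' @param aliases label alias map, see [default_landmark_aliases()].
#' @param convention `"auto"` (trust the file header, default RAS), `"RAS"`
#'   or `"LPS"` — the world convention the file's numbers are in.
#' @return A [landmark_set()] in RAS world millimetres.
#' @export
read_landmarks <- function(path, dialect = c("auto", "fcsv", "csv"),
                           aliases = default_landmark_aliases(),
                           convention = c("auto", "RAS", "LPS")) {
  dialect <- match.arg(dialect)
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.fcsv$", path, ignore.case = TRUE)) "fcsv" else "csv"

  if (dialect == "fcsv") {
    lines <- readLines(path, warn = FALSE)
    header <- grep("^#", lines, value = TRUE)
    data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(data_lines)) stop("no fiducial rows in ", path)
    file_conv <- "RAS"
    cs <- grep("CoordinateSystem", header, value = TRUE)
    if (length(cs)) {
      val <- trimws(sub(".*=", "", cs[1]))
      if (toupper(val) == "LPS" || val == "1") file_conv <- "LPS"
    }
    cols <- c(x = 2L, y = 3L, z = 4L, label = 12L)  # Slicer standard layout
    cl <- grep("columns *=", header, value = TRUE)
    if (length(cl)) {
      nm <- trimws(strsplit(sub(".*= *", "", cl[1]), ",")[[1]])
      for (f in c("x", "y", "z", "label"))
        if (f %in% nm) cols[f] <- match(f, nm)
    }
    parts <- strsplit(data_lines, ",")
    need <- max(cols)
    parts <- parts[vapply(parts, length, integer(1)) >= need]
    if (!length(parts)) stop("no parseable fiducial rows in ", path)
    label <- canonical_label(vapply(parts, `[`, "", cols["label"]), aliases)
    xyz <- cbind(as.numeric(vapply(parts, `[`, "", cols["x"])),
                 as.numeric(vapply(parts, `[`, "", cols["y"])),
                 as.numeric(vapply(parts, `[`, "", cols["z"])))
    conv <- if (convention == "auto") file_conv else convention
    landmarks_from_table(label, xyz, conv, path)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(tab)))
      stop("CSV landmark file must have columns ", paste(need, collapse = ", "))
    label <- canonical_label(tab$label, aliases)
    xyz <- cbind(tab$x_mm, tab$y_mm, tab$z_mm)
    conv <- if (convention == "auto") "RAS" else convention
    landmarks_from_table(label, xyz, conv, path)
  }
}

#' Write landmarks as a 3D Slicer fiducial (FCSV) file
#'
#' Emits the Slicer markups table with an explicit `# CoordinateSystem`
#' header so [read_landmarks()] round-trips exactly.
#'
#' @param ls a [landmark_set()] (RAS world mm).
#' @param path output path.
#' @param convention `"RAS"` (write as-is) or `"LPS"` (sign-flip x, y on
#'   output, as recent Slicer versions store).
#' @return `path`, invisibly.
#' @export
write_fcsv <- function(ls, path, convention = c("RAS", "LPS")) {
  convention <- match.arg(convention)
  stopifnot(inherits(ls, "landmark_set"))
  labs <- c(PS = "pubic_symphysis", SCJ = "sacrococcygeal_joint",
            IS_L = "ischial_spine_left", IS_R = "ischial_spine_right")
  lines <- c("# Markups fiducial file version = 5.0",
             paste0("# CoordinateSystem = ", convention),
             "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  i <- 0L
  for (canon in names(labs)) {
    p <- ls[[labs[[canon]]]]
    if (convention == "LPS") p <- c(-p[1], -p[2], p[3])
    i <- i + 1L
    lines <- c(lines, sprintf("%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,,",
                              i, p[1], p[2], p[3], canon))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-side expert defect scores
#'
#' Expects a CSV with header `subject_id,muscle,left,right`; `muscle` is
#' `PCM` or `ICM`, scores are integers 0-3 as assigned by the expert
#' protocols (PCM scored on supine images, ICM on upright).
#'
#' @param path file path.
#' @return data.frame with those four columns, validated.
#' @export
read_scores <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "muscle", "left", "right")
  if (!all(need %in% names(tab)))
    stop("score file must have columns ", paste(need, collapse = ", "))
  if (!all(tab$muscle %in% c("PCM", "ICM")))
    stop("muscle must be PCM or ICM")
  for (cc in c("left", "right"))
    if (!all(tab[[cc]] %in% 0:3))
      stop("side scores must be integers 0-3")
  tab[need]
}

GROUP_LEVELS <- c("Nulli", "Par-pre", "Par-post", "POP")

#' Construct / validate a cohort manifest
#'
#' One row per subject: identifier, study group, exclusion flag and reason,
#' and optional paths to the subject's mask, landmark and score files.
#'
#' @param subject_id character vector, unique.
#' @param group factor/character in `Nulli`, `Par-pre`, `Par-post`, `POP`.
#' @param excluded logical, default all `FALSE`.
#' @param exclusion_reason character, must be non-empty where `excluded`.
#' @param mask_path,landmark_path,score_path optional file paths.
#' @return data.frame of class `"cohort_manifest"`.
#' @export
cohort_manifest <- function(subject_id, group, excluded = FALSE,
                            exclusion_reason = "", mask_path = NA_character_,
                            landmark_path = NA_character_,
                            score_path = NA_character_) {
  n <- length(subject_id)
  m <- data.frame(subject_id = as.character(subject_id),
                  group = as.character(group),
                  excluded = rep_len(as.logical(excluded), n),
                  exclusion_reason = rep_len(as.character(exclusion_reason), n),
                  mask_path = rep_len(as.character(mask_path), n),
                  landmark_path = rep_len(as.character(landmark_path), n),
                  score_path = rep_len(as.character(score_path), n),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$subject_id)) stop("subject_ids must be unique")
  if (!all(m$group %in% GROUP_LEVELS))
    stop("group must be one of: ", paste(GROUP_LEVELS, collapse = ", "))
  if (any(m$excluded & !nzchar(m$exclusion_reason)))
    stop("excluded subjects must carry an exclusion_reason")
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

#' Read a cohort manifest from JSON or CSV
#'
#' JSON manifests are an array of subject records (fields as in
#' [cohort_manifest()]); CSV manifests a table with the same columns.
#' Relative file paths are resolved against the manifest's directory.
#'
#' @param path file path (`.json` or `.csv`).
#' @return A [cohort_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  get0c <- function(nm, default) if (nm %in% names(tab)) tab[[nm]] else default
  m <- cohort_manifest(tab$subject_id, tab$group,
                       excluded = get0c("excluded", FALSE),
                       exclusion_reason = get0c("exclusion_reason", ""),
                       mask_path = get0c("mask_path", NA_character_),
                       landmark_path = get0c("landmark_path", NA_character_),
                       score_path = get0c("score_path", NA_character_))
  base <- dirname(normalizePath(path))
  for (cc in c("mask_path", "landmark_path", "score_path")) {
    rel <- !is.na(m[[cc]]) & nzchar(m[[cc]]) & !grepl("^(/|[A-Za-z]:)", m[[cc]])
    m[[cc]][rel] <- file.path(base, m[[cc]][rel])
  }
  m
}

#' Apply the study's subject-exclusion filter
#'
#' Splits a cohort manifest into the subjects retained for analysis and a
#' tally of exclusions by reason, mirroring the per-subject exclusion
#' accounting of an imaging study (insufficient image quality, landmarks not
#' identifiable, post-scan symptom reports, ...).
#'
#' @param manifest a [cohort_manifest()].
#' @return List with `included` (manifest rows with `excluded = FALSE`),
#'   `tally` (named integer vector of exclusion counts by reason) and
#'   `group_counts` (included subjects per group).
#' @export
filter_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  inc <- manifest[!manifest$excluded, , drop = FALSE]
  exc <- manifest[manifest$excluded, , drop = FALSE]
  tally <- if (nrow(exc)) table(exc$exclusion_reason) else table(character(0))
  tally <- stats::setNames(as.integer(tally), names(tally))
  gc <- vapply(GROUP_LEVELS, function(g) sum(inc$group == g), integer(1))
  list(included = inc, tally = tally, group_counts = gc)
}

#' Write per-plane measurements (and optionally defect categories) to CSV
#'
#' The measurement table has one row per subject per plane with columns
#' `subject_id, group, plane, left_ica_deg, right_ica_deg, total_ica_deg,
#' measurable`; unmeasurable planes keep their row with empty angle fields.
#' When `categories` is supplied a companion file `<stem>_scores.csv` is
#' written with one row per subject per muscle
#' (`subject_id, group, muscle, left, right, total, category, hernia`).
#'
#' @param profiles a list of `"ica"` objects (see [measure_ica()]), or a
#'   data.frame already in the measurement layout.
#' @param path output CSV path.
#' @param groups optional named character vector subject_id -> group.
#' @param categories optional data.frame of defect categories (see
#'   [categorize_defect()]) with a `subject_id` column.
#' @return Path of the measurement CSV, invisibly.
#' @export
write_measurements <- function(profiles, path, groups = NULL, categories = NULL) {
  tab <- if (is.data.frame(profiles)) profiles else {
    do.call(rbind, lapply(profiles, as.data.frame))
  }
  if (!is.null(groups) && !"group" %in% names(tab))
    tab$group <- unname(groups[tab$subject_id])
  if (!"group" %in% names(tab)) tab$group <- NA_character_
  out <- data.frame(subject_id = tab$subject_id, group = tab$group,
                    plane = tab$plane,
                    left_ica_deg = tab$left_ica_deg,
                    right_ica_deg = tab$right_ica_deg,
                    total_ica_deg = tab$total_ica_deg,
                    measurable = tab$measurable)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(categories)) {
    spath <- sub("\\.csv$", "_scores.csv", path)
    if (!is.null(groups) && !"group" %in% names(categories))
      categories$group <- unname(groups[categories$subject_id])
    utils::write.csv(categories, spath, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#'
#' @param path CSV path.
#' @return data.frame with typed columns (`measurable` logical, angles
#'   numeric with `NA` for unmeasurable planes).
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("left_ica_deg", "right_ica_deg", "total_ica_deg"))
    tab[[cc]] <- as.numeric(tab[[cc]])
  tab$measurable <- as.logical(tab$measurable)
  tab
}
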