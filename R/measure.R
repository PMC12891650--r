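# Core geometry: five measurement planes perpendicular to the PICS line,
# slab extraction from the voxel mask, left/right split, first-degree
# polynomial fit per side, and the triangle identity
#   total ICA = 180 - left ICA - right ICA.

#' Measurement settings for [measure_ica()]
#'
#' @param slab_halfwidth_mm half-thickness of the slab of voxels gathered
#'   around each measurement plane, mm. Default `NULL` means 1.5 x the
#'   in-plane voxel size (0.735 mm at the native 0.49 mm isotropic
#'   resolution): thick enough for a stable line fit, thin enough not to mix
#'   adjacent planes.
#' @param min_points minimum foreground voxels per side for a fit; fewer
#'   renders that side (and hence the plane) unmeasurable. Default 10.
#' @param plane_scheme placement of the five planes along the PICS axis
#'   between pubic symphysis and the right ischial spine's axial level `D`:
#'   `"fifths"` puts plane k at `k*D/5` (plane 5 at the spine, plane 1 the
#'   most anterior), `"inclusive"` at `(k-1)*D/4` (plane 1 at the pubis).
#' @param fit_estimator `"ols"` (default) fits vertical on lateral by
#'   ordinary least squares — the literal first-degree polynomial fit;
#'   `"principal_axis"` uses the orthogonal (major principal axis) fit.
#' @return List of class `"ica_control"`.
#' @export
ica_control <- function(slab_halfwidth_mm = NULL, min_points = 10L,
                        plane_scheme = c("fifths", "inclusive"),
                        fit_estimator = c("ols", "principal_axis")) {
  plane_scheme <- match.arg(plane_scheme)
  fit_estimator <- match.arg(fit_estimator)
  if (!is.null(slab_halfwidth_mm) && slab_halfwidth_mm <= 0)
    stop("slab_halfwidth_mm must be positive")
  if (min_points < 2L) stop("min_points must be at least 2")
  structure(list(slab_halfwidth_mm = slab_halfwidth_mm,
                 min_points = as.integer(min_points),
                 plane_scheme = plane_scheme,
                 fit_estimator = fit_estimator),
            class = "ica_control")
}

#' Define the five measurement planes
#'
#' The segmentation is divided by five equidistant planes from the pubic
#' symphysis to the right ischial spine, each perpendicular to the PICS
#' line. With `D` the axial projection of the right ischial spine onto the
#' PICS axis, the default scheme places plane k at `k*D/5` (k = 1..5).
#'
#' @param ls a [landmark_set()].
#' @param frame the matching [pics_frame()].
#' @param slab_halfwidth half-thickness of each measurement slab, mm.
#' @param scheme `"fifths"` (default) or `"inclusive"`, see [ica_control()].
#' @return data.frame with columns `plane` (1..5), `axial_mm`,
#'   `slab_halfwidth_mm`.
#' @export
define_planes <- function(ls, frame, slab_halfwidth, scheme = "fifths") {
  stopifnot(inherits(frame, "pics_frame"), slab_halfwidth > 0)
  D <- project_onto_pics_axis(ls$ischial_spine_right, frame)
  if (D <= 0)
    stop("ischial spine not posterior to pubic symphysis along the PICS axis (D = ",
         signif(D, 4), " mm)")
  pos <- switch(scheme,
                fifths    = (1:5) * D / 5,
                inclusive = (0:4) * D / 4,
                stop("unknown plane scheme: ", scheme))
  data.frame(plane = 1:5, axial_mm = pos, slab_halfwidth_mm = slab_halfwidth)
}

#' Extract the slab of mask voxels around a measurement plane
#'
#' Returns the PICS coordinates of every foreground voxel center whose
#' pics-axial coordinate lies in `[axial - halfwidth, axial + halfwidth)`.
#'
#' @param mask a [volume_mask()].
#' @param frame a [pics_frame()].
#' @param axial_mm plane position along the PICS axis, mm.
#' @param slab_halfwidth_mm slab half-thickness, mm.
#' @param pics_points optional precomputed PICS coordinates of all
#'   foreground voxel centers (n x 3), to avoid retransforming per plane.
#' @return Matrix (possibly 0-row) with columns `lateral`, `axial`,
#'   `vertical`, mm.
#' @export
extract_slab <- function(mask, frame, axial_mm, slab_halfwidth_mm,
                         pics_points = NULL) {
  if (is.null(pics_points))
    pics_points <- to_pics_coords(voxel_centers_world(mask), frame)
  keep <- pics_points[, "axial"] >= axial_mm - slab_halfwidth_mm &
          pics_points[, "axial"] <  axial_mm + slab_halfwidth_mm
  pics_points[keep, , drop = FALSE]
}

#' Split slab points into left and right sides
#'
#' Positive lateral coordinate is the subject's left by the frame
#' convention. Points exactly on the midline (lateral == 0) belong to
#' neither side and are discarded.
#'
#' @param slab matrix with a `lateral` column (PICS coordinates).
#' @return List with elements `left` and `right`, each a matrix.
#' @export
split_sides <- function(slab) {
  lat <- slab[, "lateral"]
  list(left  = slab[lat > 0, , drop = FALSE],
       right = slab[lat < 0, , drop = FALSE])
}

#' Fit a first-degree polynomial through one hemi-slice
#'
#' Ordinary least squares of the vertical on the lateral coordinate (the
#' first-degree polynomial fit through the slice); the side angle is
#' `atan(|slope|)` in degrees, i.e. the inclination of the muscle sheet
#' relative to the transverse (lateral-axial) plane, in `[0, 90)`.
#' Returns `NA` — unmeasurable — when fewer than `min_points` points are
#' available or the lateral spread is zero (a vertical cloud admits no
#' first-degree polynomial in the lateral coordinate).
#'
#' @param lateral,vertical numeric vectors, mm (PICS in-plane coordinates).
#' @param min_points minimum number of points for a fit.
#' @param estimator `"ols"` or `"principal_axis"` (orthogonal fit).
#' @return Side angle in degrees, or `NA_real_`.
#' @export
fit_side_line <- function(lateral, vertical, min_points = 10L,
                          estimator = c("ols", "principal_axis")) {
  estimator <- match.arg(estimator)
  n <- length(lateral)
  if (n != length(vertical)) stop("lateral and vertical lengths differ")
  if (n < min_points) return(NA_real_)
  dx <- lateral - mean(lateral)
  if (all(dx == 0)) return(NA_real_)
  slope <- if (estimator == "ols") {
    sum(dx * (vertical - mean(vertical))) / sum(dx * dx)
  } else {
    # major principal axis of the 2D scatter
    dy <- vertical - mean(vertical)
    sxx <- sum(dx * dx); syy <- sum(dy * dy); sxy <- sum(dx * dy)
    if (sxy == 0) {
      if (syy > sxx) return(NA_real_)  # vertical principal axis
      0
    } else {
      (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    }
  }
  ang <- atan(abs(slope)) * 180 / pi
  min(ang, 90 - .Machine$double.eps)
}

#' Combine side angles into a plane measurement
#'
#' The levator sheet is treated as a triangle: `total = 180 - left - right`
#' degrees. A plane is measurable only when both side angles are.
#'
#' @param left_angle,right_angle side angles in degrees, or `NA`.
#' @return List with `left_angle`, `right_angle`, `total_angle`,
#'   `measurable`.
#' @examples
#' compute_plane_ica(55, 55)$total_angle   # 70
#' compute_plane_ica(43, 42)$total_angle   # 95
#' @export
compute_plane_ica <- function(left_angle, right_angle) {
  measurable <- !is.na(left_angle) && !is.na(right_angle)
  list(left_angle = left_angle, right_angle = right_angle,
       total_angle = if (measurable) 180 - left_angle - right_angle else NA_real_,
       measurable = measurable)
}

#' Measure the iliococcygeus angle profile of one subject
#'
#' The estimator at the heart of the package. Builds the PICS frame from the
#' landmarks, defines the five measurement planes perpendicular to the PICS
#' line, slices the segmentation mask into slabs, splits each slab at the
#' midline, fits a first-degree polynomial through each hemi-slice and
#' derives left, right and total ICA per plane. Planes where either side
#' cannot be fit (too few voxels, e.g. at an avulsion gap) are flagged
#' unmeasurable, never fatal.
#'
#' @param mask a [volume_mask()] of the levator ani segmentation.
#' @param landmarks a [landmark_set()] in the same world space as the mask
#'   affine.
#' @param control an [ica_control()].
#' @param subject_id identifier carried into outputs.
#' @return Object of class `"ica"`: a list with `subject_id`, `planes`
#'   (data.frame: `plane`, `axial_mm`, `left_ica_deg`, `right_ica_deg`,
#'   `total_ica_deg`, `measurable`, `left_n`, `right_n`), `frame`,
#'   `control`. Methods: `print`, `summary`, `coef` (matrix of angles),
#'   `as.data.frame`, `plot`.
#' @examples
#' ph <- generate_phantom(phantom_spec(left_angles = 45, right_angles = 45))
#' fit <- measure_ica(ph$mask, ph$landmarks)
#' coef(fit)
#' @export
measure_ica <- function(mask, landmarks, control = ica_control(),
                        subject_id = "subject") {
  stopifnot(inherits(mask, "volume_mask"), inherits(landmarks, "landmark_set"),
            inherits(control, "ica_control"))
  if (!mask$usable) stop("mask has no foreground voxels (subject ", subject_id, ")")
  bad <- validate_landmarks(landmarks)
  if (length(bad))
    stop("invalid landmarks for subject ", subject_id, ": ",
         paste(bad, collapse = "; "))
  frame <- pics_frame(landmarks)
  halfwidth <- control$slab_halfwidth_mm
  if (is.null(halfwidth)) halfwidth <- 1.5 * max(mask$spacing[1:2])
  planes <- tryCatch(
    define_planes(landmarks, frame, halfwidth, control$plane_scheme),
    error = function(e) stop("subject ", subject_id, ": ", conditionMessage(e)))
  pics_pts <- to_pics_coords(voxel_centers_world(mask), frame)

  rows <- lapply(seq_len(nrow(planes)), function(i) {
    slab <- extract_slab(mask, frame, planes$axial_mm[i], halfwidth,
                         pics_points = pics_pts)
    sides <- split_sides(slab)
    la <- fit_side_line(sides$left[, "lateral"], sides$left[, "vertical"],
                        control$min_points, control$fit_estimator)
    ra <- fit_side_line(sides$right[, "lateral"], sides$right[, "vertical"],
                        control$min_points, control$fit_estimator)
    m <- compute_plane_ica(la, ra)
    data.frame(plane = planes$plane[i], axial_mm = planes$axial_mm[i],
               left_ica_deg = m$left_angle, right_ica_deg = m$right_angle,
               total_ica_deg = m$total_angle, measurable = m$measurable,
               left_n = nrow(sides$left), right_n = nrow(sides$right))
  })
  structure(list(subject_id = subject_id, planes = do.call(rbind, rows),
                 frame = frame, control = control),
            class = "ica")
}

#' @export
print.ica <- function(x, digits = 1, ...) {
  cat("Iliococcygeus angle profile - subject:", x$subject_id, "\n")
  p <- x$planes
  cat(sprintf("  %-6s %-10s %-8s %-8s %-8s\n",
              "plane", "axial(mm)", "left", "right", "total"))
  for (i in seq_len(nrow(p))) {
    fmt <- function(v) if (is.na(v)) "   --" else sprintf("%5.*f", digits, v)
    cat(sprintf("  %-6d %-10.1f %-8s %-8s %-8s%s\n", p$plane[i], p$axial_mm[i],
                fmt(p$left_ica_deg[i]), fmt(p$right_ica_deg[i]),
                fmt(p$total_ica_deg[i]),
                if (p$measurable[i]) "" else " [unmeasurable]"))
  }
  invisible(x)
}

#' @export
coef.ica <- function(object, ...) {
  p <- object$planes
  out <- cbind(left = p$left_ica_deg, right = p$right_ica_deg,
               total = p$total_ica_deg)
  rownames(out) <- paste0("plane", p$plane)
  out
}

#' @export
as.data.frame.ica <- function(x, ...) {
  cbind(subject_id = x$subject_id, x$planes, stringsAsFactors = FALSE)
}

#' @export
summary.ica <- function(object, ...) {
  p <- object$planes
  structure(list(subject_id = object$subject_id,
                 n_measurable = sum(p$measurable),
                 mean_total = mean(p$total_ica_deg, na.rm = TRUE),
                 planes = p),
            class = "summary.ica")
}

#' @export
print.summary.ica <- function(x, ...) {
  cat(sprintf("Subject %s: %d of 5 planes measurable; mean total ICA %.1f deg\n",
              x$subject_id, x$n_measurable, x$mean_total))
  invisible(x)
}

#' @export
plot.ica <- function(x, ...) {
  p <- x$planes
  graphics::plot(p$plane, p$total_ica_deg, type = "b", pch = 19,
                 xlab = "plane (anterior -> posterior)",
                 ylab = "total ICA (degrees)",
                 main = paste("Total ICA -", x$subject_id),
                 ylim = range(c(p$total_ica_deg, 0, 180), na.rm = TRUE), ...)
  graphics::points(p$plane[!p$measurable], rep(0, sum(!p$measurable)), pch = 4)
  invisible(x)
}
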