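#' Construct a set of pelvic bony landmarks
#'
#' Bundles the four anatomical reference points used to standardize levator
#' ani segmentations: pubic symphysis (PS), sacrococcygeal joint (SCJ) and
#' the left and right ischial spines (IS_L, IS_R). All coordinates are world
#' (scanner) millimetres; voxel-index inputs must be converted through the
#' mask affine before they reach this constructor.
#'
#' @param pubic_symphysis,sacrococcygeal_joint,ischial_spine_left,ischial_spine_right
#'   numeric length-3 vectors, world coordinates in mm.
#' @return An object of class `"landmark_set"`: a named list of the four
#'   points.
#' @seealso [validate_landmarks()], [pics_frame()]
#' @export
landmark_set <- function(pubic_symphysis, sacrococcygeal_joint,
                         ischial_spine_left, ischial_spine_right) {
  as_pt <- function(p, what) {
    p <- as.numeric(p)
    if (length(p) != 3L)
      stop(sprintf("landmark '%s' must have 3 coordinates", what))
    p
  }
  structure(list(
    pubic_symphysis      = as_pt(pubic_symphysis, "pubic_symphysis"),
    sacrococcygeal_joint = as_pt(sacrococcygeal_joint, "sacrococcygeal_joint"),
    ischial_spine_left   = as_pt(ischial_spine_left, "ischial_spine_left"),
    ischial_spine_right  = as_pt(ischial_spine_right, "ischial_spine_right")
  ), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Pelvic landmark set (world mm):\n")
  for (nm in names(x))
    cat(sprintf("  %-22s % .2f % .2f % .2f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Validate a landmark set
#'
#' Diagnostic check of the geometric invariants a usable landmark set must
#' satisfy: all coordinates finite, a non-degenerate PICS line (PS distinct
#' from SCJ), distinct ischial spines, and an inter-spine vector that is not
#' parallel (within 1 degree) to the PICS line.
#'
#' @param ls a [landmark_set()].
#' @return Character vector of violations; empty when the set is valid.
#' @export
validate_landmarks <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  bad <- character(0)
  if (!all(vapply(ls, function(p) all(is.finite(p)), logical(1))))
    bad <- c(bad, "non-finite coordinates")
  pics <- ls$sacrococcygeal_joint - ls$pubic_symphysis
  lat  <- ls$ischial_spine_left - ls$ischial_spine_right
  if (sqrt(sum(pics^2)) < 1e-9)
    bad <- c(bad, "degenerate PICS line (pubic symphysis coincides with sacrococcygeal joint)")
  if (sqrt(sum(lat^2)) < 1e-9)
    bad <- c(bad, "degenerate lateral axis (ischial spines coincide)")
  if (sqrt(sum(pics^2)) >= 1e-9 && sqrt(sum(lat^2)) >= 1e-9) {
    cosang <- abs(sum(pics * lat)) / (sqrt(sum(pics^2)) * sqrt(sum(lat^2)))
    # parallel within 1 degree of the PICS line makes the lateral axis unstable
    if (cosang > cos(pi / 180))
      bad <- c(bad, "inter-spine vector parallel to PICS line (within 1 degree)")
  }
  bad
}

#' Build the PICS anatomical coordinate frame
#'
#' Constructs the 3D Pelvic Inclination Correction System frame from the four
#' bony landmarks. The origin sits at the pubic symphysis; the PICS axis is
#' the unit vector from the pubic symphysis toward the sacrococcygeal joint
#' (the PICS line); the lateral axis is the inter-spine vector (left minus
#' right, so positive lateral = subject's left) Gram-Schmidt-orthogonalized
#' against the PICS axis; the vertical axis completes a right-handed frame.
#'
#' @param ls a valid [landmark_set()].
#' @return Object of class `"pics_frame"` with fields `origin` (mm),
#'   `axis_pics`, `axis_lateral`, `axis_vertical` (unit vectors) and `axes`
#'   (3x3 matrix with columns lateral, pics, vertical; determinant +1).
#' @examples
#' ls <- landmark_set(c(0, 0, 0), c(0, 100, 0), c(50, 60, -10), c(-50, 60, -10))
#' fr <- pics_frame(ls)
#' fr$axis_pics      # (0, 1, 0)
#' @export
pics_frame <- function(ls) {
  bad <- validate_landmarks(ls)
  if (length(bad))
    stop("cannot build PICS frame: ", paste(bad, collapse = "; "))
  origin <- ls$pubic_symphysis
  a <- ls$sacrococcygeal_joint - origin
  a <- a / sqrt(sum(a * a))
  u <- ls$ischial_spine_left - ls$ischial_spine_right
  u <- u - sum(u * a) * a
  u <- u / sqrt(sum(u * u))
  # vertical = lateral x pics: the triple (lateral, pics, vertical) -- the
  # ordering of PICS coordinates -- is then always right-handed (det +1)
  v <- c(u[2] * a[3] - u[3] * a[2],
         u[3] * a[1] - u[1] * a[3],
         u[1] * a[2] - u[2] * a[1])
  structure(list(origin = origin, axis_pics = a, axis_lateral = u,
                 axis_vertical = v, axes = cbind(u, a, v, deparse.level = 0)),
            class = "pics_frame")
}

#' @export
print.pics_frame <- function(x, ...) {
  cat("PICS coordinate frame\n")
  cat(sprintf("  origin (pubic symphysis): % .2f % .2f % .2f mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  lab <- c("PICS axis (PS -> SCJ)", "lateral axis (to left)", "vertical axis")
  ax <- list(x$axis_pics, x$axis_lateral, x$axis_vertical)
  for (i in 1:3)
    cat(sprintf("  %-24s % .4f % .4f % .4f\n", lab[i], ax[[i]][1], ax[[i]][2], ax[[i]][3]))
  invisible(x)
}

#' Transform world points into PICS coordinates
#'
#' Rigid change of basis: each point is expressed as (lateral, pics-axial,
#' vertical) millimetres relative to the frame origin. The map is an
#' isometry; pairwise distances are preserved.
#'
#' @param points numeric matrix n x 3 (or length-3 vector) of world mm.
#' @param frame a [pics_frame()].
#' @return n x 3 matrix with columns `lateral`, `axial`, `vertical`.
#' @export
to_pics_coords <- function(points, frame) {
  stopifnot(inherits(frame, "pics_frame"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  centered <- sweep(points, 2, frame$origin)
  out <- centered %*% cbind(frame$axis_lateral, frame$axis_pics, frame$axis_vertical)
  colnames(out) <- c("lateral", "axial", "vertical")
  out
}

#' Axial coordinate of a point along the PICS line
#'
#' @param point length-3 world point (mm) or n x 3 matrix.
#' @param frame a [pics_frame()].
#' @return Scalar (or vector) signed distance along the PICS axis from the
#'   pubic symphysis, mm.
#' @export
project_onto_pics_axis <- function(point, frame) {
  stopifnot(inherits(frame, "pics_frame"))
  if (is.null(dim(point))) point <- matrix(point, ncol = 3)
  as.numeric(sweep(point, 2, frame$origin) %*% frame$axis_pics)
}
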