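# Synthetic voxel phantoms of the levator ani with analytic ground truth,
# and cohort simulation from printed group-level summary statistics. These
# stand in for the study's MRI data, which has no public accession: the
# phantom validates the geometry estimator end-to-end, the cohort simulator
# the inference stage.

# run code under a temporary RNG state; NULL seed = use the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic levator ani phantom
#'
#' The phantom is two planar muscle sheets attached laterally and descending
#' toward the midline where they meet, forming the triangle whose apex angle
#' is the total ICA. Per measurement plane a left and right inclination is
#' prescribed (angles between the sheet and the transverse plane, measured
#' at the midline); between plane positions the inclination is linearly
#' interpolated. The sheet is voxelized at the stated isotropic resolution
#' (0.49 mm, matching the bSSFP acquisition the method was developed on).
#'
#' @param left_angles,right_angles prescribed side angles in degrees,
#'   length 1 or 5, each in `[0, 85]`.
#' @param lateral_halfwidth_mm lateral extent of each sheet from the
#'   midline, mm (default 40, a realistic hemipelvis width).
#' @param thickness_mm sheet thickness, mm (default 3, a typical
#'   iliococcygeus thickness; must be at least one voxel).
#' @param spine_distance_mm axial distance `D` from pubic symphysis to the
#'   ischial-spine level along the PICS line, mm (default 60).
#' @param voxel_mm isotropic voxel size, mm (default 0.49).
#' @param avulsion `NULL`, or `list(side = "left"|"right", extent_mm = e)`:
#'   the sheet on that side is removed for axial positions `< e`,
#'   emulating an anterior avulsion gap.
#' @param noise_flip_prob probability of flipping each boundary voxel (see
#'   [add_boundary_noise()]); applied by [generate_phantom()] when > 0.
#' @param seed integer seed for the noise.
#' @return List of class `"phantom_spec"`.
#' @export
phantom_spec <- function(left_angles = 45, right_angles = 45,
                         lateral_halfwidth_mm = 40, thickness_mm = 3,
                         spine_distance_mm = 60, voxel_mm = 0.49,
                         avulsion = NULL, noise_flip_prob = 0, seed = NULL) {
  rec <- function(a) if (length(a) == 1L) rep(a, 5L) else a
  left_angles <- rec(left_angles); right_angles <- rec(right_angles)
  if (length(left_angles) != 5L || length(right_angles) != 5L)
    stop("angles must have length 1 or 5 (one per plane)")
  if (any(c(left_angles, right_angles) < 0 | c(left_angles, right_angles) > 85))
    stop("prescribed angles must lie in [0, 85] degrees")
  if (thickness_mm < voxel_mm) stop("thickness must be at least one voxel")
  if (noise_flip_prob < 0 || noise_flip_prob > 1)
    stop("noise_flip_prob must be a probability")
  if (!is.null(avulsion)) {
    if (!all(c("side", "extent_mm") %in% names(avulsion)) ||
        !avulsion$side %in% c("left", "right") || avulsion$extent_mm <= 0)
      stop("avulsion must be list(side = 'left'|'right', extent_mm > 0)")
  }
  structure(list(left_angles = left_angles, right_angles = right_angles,
                 lateral_halfwidth_mm = lateral_halfwidth_mm,
                 thickness_mm = thickness_mm,
                 spine_distance_mm = spine_distance_mm, voxel_mm = voxel_mm,
                 avulsion = avulsion, noise_flip_prob = noise_flip_prob,
                 seed = seed),
            class = "phantom_spec")
}

#' Generate a voxelized levator ani phantom
#'
#' Builds the two inclined sheets of [phantom_spec()] on a voxel grid,
#' places the four bony landmarks analytically consistent with the
#' construction (so the derived PICS frame is the canonical frame of the
#' phantom), and returns the ground-truth angle profile. With the sheets
#' meeting at the midline, ground truth per plane is
#' `total = 180 - left - right` of the prescribed angles.
#'
#' @param spec a [phantom_spec()].
#' @return List with `mask` ([volume_mask()]), `landmarks`
#'   ([landmark_set()]), `truth` (data.frame `plane`, `left`, `right`,
#'   `total` in degrees) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- spec$lateral_halfwidth_mm; t2 <- spec$thickness_mm / 2
  D <- spec$spine_distance_mm; s <- spec$voxel_mm
  plane_y <- (1:5) * D / 5

  centers <- function(lo, hi) {
    n <- ceiling((hi - lo) / s)
    lo + (seq_len(n) - 0.5) * s
  }
  zmax <- tan(max(c(spec$left_angles, spec$right_angles)) * pi / 180) * W
  cx <- centers(-(W + 2), W + 2)
  cy <- centers(-1, D + 2)
  cz <- centers(-spec$thickness_mm, zmax + spec$thickness_mm)

  # per-voxel-column sheet height: angle interpolated along the axial axis
  aL <- stats::approx(plane_y, spec$left_angles, xout = cy, rule = 2)$y
  aR <- stats::approx(plane_y, spec$right_angles, xout = cy, rule = 2)$y
  slopeL <- tan(aL * pi / 180); slopeR <- tan(aR * pi / 180)
  inL <- cx > 0 & cx <= W; inR <- cx < 0 & cx >= -W
  zsheet <- outer(abs(cx), slopeL) # nx x ny, left slopes
  zsheet[inR, ] <- outer(abs(cx[inR]), slopeR)
  occup <- matrix(FALSE, length(cx), length(cy))
  occup[inL | inR, ] <- TRUE
  occup[, cy < 0 | cy > D] <- FALSE
  if (!is.null(spec$avulsion)) {
    side_in <- if (spec$avulsion$side == "left") inL else inR
    occup[side_in, cy < spec$avulsion$extent_mm] <- FALSE
  }
  vox <- array(FALSE, c(length(cx), length(cy), length(cz)))
  for (k in seq_along(cz))
    vox[, , k] <- occup & abs(cz[k] - zsheet) <= t2
  if (!any(vox)) stop("phantom spec produced an empty mask")

  affine <- diag(c(s, s, s, 1))
  affine[1:3, 4] <- c(cx[1], cy[1], cz[1])
  mask <- volume_mask(array(as.integer(vox), dim = dim(vox)), affine = affine)
  if (spec$noise_flip_prob > 0)
    mask <- add_boundary_noise(mask, spec$noise_flip_prob, spec$seed)

  lm <- landmark_set(c(0, 0, 0), c(0, D + 30, 0),
                     c(W + 15, D, 0), c(-(W + 15), D, 0))
  truth <- data.frame(plane = 1:5, left = spec$left_angles,
                      right = spec$right_angles,
                      total = 180 - spec$left_angles - spec$right_angles)
  list(mask = mask, landmarks = lm, truth = truth, spec = spec)
}

#' Flip boundary voxels of a mask at random
#'
#' Boundary voxels are foreground voxels with at least one background
#' 6-neighbor and background voxels with at least one foreground
#' 6-neighbor; each is flipped independently with probability `flip_prob`.
#' Deterministic given `seed`.
#'
#' @param mask a [volume_mask()].
#' @param flip_prob flip probability in `[0, 1]`.
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return A new [volume_mask()].
#' @export
add_boundary_noise <- function(mask, flip_prob, seed = NULL) {
  stopifnot(inherits(mask, "volume_mask"), flip_prob >= 0, flip_prob <= 1)
  if (flip_prob == 0) return(mask)
  v <- mask$voxels
  d <- dim(v)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  inner <- function(di, dj, dk)
    pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk]
  nfg <- inner(1, 0, 0) + inner(-1, 0, 0) + inner(0, 1, 0) +
         inner(0, -1, 0) + inner(0, 0, 1) + inner(0, 0, -1)
  boundary <- (v == 1L & nfg < 6L) | (v == 0L & nfg > 0L)
  idx <- which(boundary)
  flip <- with_seed(seed, stats::runif(length(idx)) < flip_prob)
  v[idx[flip]] <- 1L - v[idx[flip]]
  volume_mask(v, spacing = mask$spacing, affine = mask$affine)
}

#' Printed cohort parameters of the reference study population
#'
#' Group sizes, per-plane total-ICA means and SDs, plane-1 avulsion counts
#' and defect-category probabilities for the four groups (nulliparous,
#' parous premenopausal, parous postmenopausal, prolapse), as printed in
#' the study this pipeline reproduces. Plane 1 was excluded from that
#' study's statistics (avulsion subjects made it unmeasurable), so no
#' plane-1 summary exists; the simulator reuses the plane-2 parameters
#' there as a synthetic stand-in.
#'
#' @return Named list per group with `n`, `plane_mean`, `plane_sd` (length
#'   5, planes 1..5), `n_avulsion` (subjects unmeasurable at plane 1) and
#'   `defect_probs` (list `PCM`/`ICM`, probabilities of none/minor/major).
#' @export
default_cohort_parameters <- function() {
  list(
    "Nulli" = list(
      n = 14L, n_avulsion = 0L,
      plane_mean = c(65.7, 65.7, 77.8, 95.2, 103),
      plane_sd   = c(14.7, 14.7, 12.4, 14.6, 14.6),
      defect_probs = list(PCM = c(none = 14, minor = 0, major = 0) / 14,
                          ICM = c(none = 11, minor = 3, major = 0) / 14)),
    "Par-pre" = list(
      n = 13L, n_avulsion = 1L,
      plane_mean = c(61, 61, 68.5, 78.6, 88),
      plane_sd   = c(16, 16, 14.7, 21.3, 23),
      defect_probs = list(PCM = c(none = 6, minor = 6, major = 1) / 13,
                          ICM = c(none = 5, minor = 8, major = 0) / 13)),
    "Par-post" = list(
      n = 12L, n_avulsion = 5L,
      plane_mean = c(52, 52, 67.2, 79.7, 88),
      plane_sd   = c(16, 16, 7.6, 19.3, 22),
      defect_probs = list(PCM = c(none = 2, minor = 8, major = 2) / 12,
                          ICM = c(none = 4, minor = 8, major = 0) / 12)),
    "POP" = list(
      n = 16L, n_avulsion = 3L,
      plane_mean = c(49, 49, 48.3, 53.4, 70),
      plane_sd   = c(13.7, 13.7, 10.2, 11.9, 16),
      defect_probs = list(PCM = c(none = 2, minor = 3, major = 11) / 16,
                          ICM = c(none = 0, minor = 9, major = 7) / 16))
  )
}

#' Cohort simulation specification
#'
#' @param groups per-group parameter list in the layout of
#'   [default_cohort_parameters()] (the default).
#' @param seed integer seed.
#' @return List of class `"cohort_sim_spec"`.
#' @export
cohort_sim_spec <- function(groups = default_cohort_parameters(), seed = NULL) {
  for (g in names(groups)) {
    p <- groups[[g]]
    if (p$n < 1L) stop("group size must be >= 1")
    if (any(p$plane_sd <= 0)) stop("plane SDs must be positive")
    for (mus in names(p$defect_probs))
      if (abs(sum(p$defect_probs[[mus]]) - 1) > 1e-9)
        stop("defect category probabilities must sum to 1 (", g, "/", mus, ")")
  }
  structure(list(groups = groups, seed = seed), class = "cohort_sim_spec")
}

rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 180) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

# side-score pairs compatible with each category (exhaustive over 0..3 x 0..3)
compatible_pairs <- function(category) {
  grid <- expand.grid(left = 0:3, right = 0:3)
  cat <- mapply(function(l, r) categorize_defect("PCM", l, r)$category,
                grid$left, grid$right)
  grid[cat == category, , drop = FALSE]
}

#' Simulate a cohort of total-ICA measurements and defect scores
#'
#' Per group and plane, total ICA values are drawn from a normal
#' distribution at the printed group mean and SD, truncated to (0, 180);
#' side angles are synthesized to satisfy the triangle identity with a
#' small random left/right asymmetry. Defect categories are drawn from the
#' printed prevalence fractions, and side scores uniformly from the pairs
#' compatible with the drawn category, so the aggregation rules can be
#' round-trip tested. The configured number of subjects per group is
#' marked unmeasurable at plane 1 (avulsion).
#'
#' @param spec a [cohort_sim_spec()].
#' @return List with `manifest` ([cohort_manifest()]), `measurements`
#'   (measurement-table data.frame) and `scores` (per-side score
#'   data.frame).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    meas <- list(); sco <- list(); man <- list()
    for (g in names(spec$groups)) {
      p <- spec$groups[[g]]
      ids <- sprintf("%s_%02d", gsub("[^A-Za-z]", "", g), seq_len(p$n))
      man[[g]] <- data.frame(subject_id = ids, group = g,
                             stringsAsFactors = FALSE)
      avulsed <- ids[seq_len(p$n_avulsion)]
      for (k in 1:5) {
        tot <- rtruncnorm01(p$n, p$plane_mean[k], p$plane_sd[k])
        asym <- stats::rnorm(p$n, 0, 2)
        left <- pmin(pmax((180 - tot) / 2 + asym, 0), 89.9)
        right <- (180 - tot) - left
        unm <- k == 1L & ids %in% avulsed
        meas[[length(meas) + 1L]] <- data.frame(
          subject_id = ids, group = g, plane = k,
          left_ica_deg = ifelse(unm, NA_real_, left),
          right_ica_deg = ifelse(unm, NA_real_, right),
          total_ica_deg = ifelse(unm, NA_real_, tot),
          measurable = !unm, stringsAsFactors = FALSE)
      }
      for (mus in c("PCM", "ICM")) {
        cat_draw <- sample(names(p$defect_probs[[mus]]), p$n, replace = TRUE,
                           prob = p$defect_probs[[mus]])
        pair_rows <- lapply(cat_draw, function(cc) {
          pairs <- compatible_pairs(cc)
          pairs[sample.int(nrow(pairs), 1L), ]
        })
        pairs <- do.call(rbind, pair_rows)
        sco[[length(sco) + 1L]] <- data.frame(
          subject_id = ids, muscle = mus, left = pairs$left,
          right = pairs$right, stringsAsFactors = FALSE)
      }
    }
    man <- do.call(rbind, man)
    list(manifest = cohort_manifest(man$subject_id, man$group),
         measurements = do.call(rbind, meas),
         scores = do.call(rbind, sco))
  })
}
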