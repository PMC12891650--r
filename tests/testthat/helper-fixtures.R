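# Shared fixtures: canonical landmark configurations, random rigid motions
# and a downsized phantom spec that keeps the native 0.49 mm voxels but a
# smaller field of view so geometry tests stay fast.

axis_aligned_landmarks <- function() {
  landmark_set(c(0, 0, 0), c(0, 100, 0), c(50, 60, -10), c(-50, 60, -10))
}

random_landmarks <- function() {
  repeat {
    ps <- stats::runif(3, -20, 20)
    scj <- ps + stats::runif(3, -60, 60)
    isl <- ps + c(stats::runif(1, 20, 60), stats::runif(1, 20, 80), stats::runif(1, -30, 10))
    isr <- ps + c(stats::runif(1, -60, -20), stats::runif(1, 20, 80), stats::runif(1, -30, 10))
    ls <- landmark_set(ps, scj, isl, isr)
    if (length(validate_landmarks(ls)) == 0L) return(ls)
  }
}

# uniform-ish random rotation: QR of a Gaussian matrix, det forced to +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_landmarks <- function(ls, R, t = c(0, 0, 0)) {
  landmark_set(R %*% ls$pubic_symphysis + t,
               R %*% ls$sacrococcygeal_joint + t,
               R %*% ls$ischial_spine_left + t,
               R %*% ls$ischial_spine_right + t)
}

transform_mask <- function(mask, R, t = c(0, 0, 0)) {
  T4 <- rbind(cbind(R, t), c(0, 0, 0, 1))
  volume_mask(mask$voxels, affine = T4 %*% mask$affine)
}

# mirror across the midsagittal plane: reflect world x, swap spine labels
mirror_scene <- function(mask, ls) {
  M <- diag(c(-1, 1, 1, 1))
  list(mask = volume_mask(mask$voxels, affine = M %*% mask$affine),
       landmarks = landmark_set(c(-1, 1, 1) * ls$pubic_symphysis,
                                c(-1, 1, 1) * ls$sacrococcygeal_joint,
                                c(-1, 1, 1) * ls$ischial_spine_right,
                                c(-1, 1, 1) * ls$ischial_spine_left))
}

small_phantom_spec <- function(left = 45, right = 45, ...) {
  phantom_spec(left_angles = left, right_angles = right,
               lateral_halfwidth_mm = 25, spine_distance_mm = 50, ...)
}

# tiny random mask for slab-extraction oracle tests
random_small_mask <- function(dims = c(12, 14, 10), p = 0.3) {
  volume_mask(array(stats::rbinom(prod(dims), 1, p), dim = dims),
              affine = rbind(cbind(random_rotation() * 0.8,
                                   stats::runif(3, -5, 5)),
                             c(0, 0, 0, 1)))
}

# the 63-subject manifest replicating the study's exclusion accounting:
# 15/15/15/18 recruited; 1 Nulli image-quality, 2 Par-pre + 1 Par-post +
# 2 POP missing ischial spines, 2 Par-post de novo symptoms
study_manifest <- function() {
  groups <- rep(c("Nulli", "Par-pre", "Par-post", "POP"), c(15, 15, 15, 18))
  ids <- sprintf("S%02d", seq_along(groups))
  excluded <- rep(FALSE, 63)
  reason <- rep("", 63)
  set_excl <- function(group, k, why) {
    idx <- which(groups == group & !excluded)[seq_len(k)]
    excluded[idx] <<- TRUE
    reason[idx] <<- why
  }
  set_excl("Nulli", 1, "insufficient image quality")
  set_excl("Par-pre", 2, "ischial spine not identifiable")
  set_excl("Par-post", 1, "ischial spine not identifiable")
  set_excl("POP", 2, "ischial spine not identifiable")
  set_excl("Par-post", 2, "de novo POP symptoms")
  cohort_manifest(ids, groups, excluded, reason)
}
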