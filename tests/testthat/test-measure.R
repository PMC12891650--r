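# Core ICA geometry: plane placement, slab extraction, side split, line
# fits and the end-to-end estimator on phantoms.

test_that("planes sit at k*D/5 along the PICS axis", {
  ls <- landmark_set(c(0, 0, 0), c(0, 120, 0), c(50, 80, -10), c(-50, 80, -10))
  fr <- pics_frame(ls)
  pl <- define_planes(ls, fr, slab_halfwidth = 0.75)  # D = 80
  expect_equal(pl$axial_mm, c(16, 32, 48, 64, 80))

  ls2 <- landmark_set(c(0, 0, 0), c(0, 150, 0), c(50, 100, 0), c(-50, 100, 0))
  pl2 <- define_planes(ls2, pics_frame(ls2), 0.75)    # D = 100
  expect_equal(unique(diff(pl2$axial_mm)), 20)

  ls3 <- axis_aligned_landmarks()                      # IS_R = (-50, 60, -10)
  pl3 <- define_planes(ls3, pics_frame(ls3), 0.75)    # D = 60
  expect_equal(pl3$axial_mm[3], 36)

  backwards <- landmark_set(c(0, 0, 0), c(0, 100, 0), c(50, -60, 0), c(-50, -60, 0))
  expect_error(define_planes(backwards, pics_frame(backwards), 0.75),
               "not posterior")
})

test_that("extract_slab equals a brute-force per-voxel filter", {
  set.seed(31)
  for (i in 1:5) {
    mask <- random_small_mask()
    ls <- random_landmarks()
    fr <- pics_frame(ls)
    pos <- stats::runif(1, -10, 10); half <- stats::runif(1, 0.5, 3)
    got <- extract_slab(mask, fr, pos, half)
    # oracle: loop over every voxel of the array
    d <- dim(mask$voxels)
    keep <- list()
    for (ii in 1:d[1]) for (jj in 1:d[2]) for (kk in 1:d[3]) {
      if (mask$voxels[ii, jj, kk] == 0L) next
      w <- (mask$affine %*% c(ii - 1, jj - 1, kk - 1, 1))[1:3]
      ax <- sum((w - fr$origin) * fr$axis_pics)
      if (ax >= pos - half && ax < pos + half)
        keep[[length(keep) + 1L]] <- as.numeric(to_pics_coords(w, fr))
    }
    oracle <- if (length(keep)) do.call(rbind, keep) else
      matrix(numeric(0), ncol = 3)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got))
      expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                   oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ,
                          drop = FALSE],
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("slab far outside the mask is empty", {
  mask <- random_small_mask()
  fr <- pics_frame(axis_aligned_landmarks())
  expect_equal(nrow(extract_slab(mask, fr, 1e5, 1)), 0L)
})

test_that("split_sides partitions by the sign of the lateral coordinate", {
  slab <- cbind(lateral = c(-3, -1, 2, 4), axial = 0, vertical = 1:4)
  s <- split_sides(slab)
  expect_equal(nrow(s$left), 2L)
  expect_equal(nrow(s$right), 2L)

  mid <- cbind(lateral = c(0, 0), axial = 0, vertical = 0)
  s0 <- split_sides(mid)
  expect_equal(nrow(s0$left) + nrow(s0$right), 0L)

  mirrored <- slab; mirrored[, "lateral"] <- -mirrored[, "lateral"]
  sm <- split_sides(mirrored)
  expect_equal(sm$left[, "vertical"], s$right[, "vertical"])
  expect_equal(sm$right[, "vertical"], s$left[, "vertical"])
})

test_that("fit_side_line reproduces closed-form least-squares angles", {
  x <- seq(1, 10, by = 0.5)
  expect_equal(fit_side_line(x, x, min_points = 5), 45)
  expect_equal(fit_side_line(x, rep(2, length(x)), min_points = 5), 0)
  expect_equal(fit_side_line(c(1, 2, 3), c(0.5, 1.0, 1.5), min_points = 3),
               atan(0.5) * 180 / pi)  # 26.565 degrees

  expect_true(is.na(fit_side_line(1:5, 1:5, min_points = 10)))
  expect_true(is.na(fit_side_line(rep(2, 12), stats::rnorm(12), min_points = 10)))

  # noisy-but-linear points: OLS equals lm()
  set.seed(32)
  y <- 0.7 * x + stats::rnorm(length(x), 0, 0.1)
  expect_equal(fit_side_line(x, y, min_points = 5),
               atan(abs(unname(stats::coef(stats::lm(y ~ x))[2]))) * 180 / pi)
})

test_that("the triangle identity drives compute_plane_ica", {
  expect_equal(compute_plane_ica(55, 55)$total_angle, 70)
  expect_equal(compute_plane_ica(43, 42)$total_angle, 95)
  expect_equal(compute_plane_ica(0, 0)$total_angle, 180)
  m <- compute_plane_ica(NA_real_, 40)
  expect_false(m$measurable)
  expect_true(is.na(m$total_angle))
})

test_that("measure_ica recovers prescribed phantom angles within 2 degrees", {
  ph <- generate_phantom(small_phantom_spec(45, 45))
  fit <- measure_ica(ph$mask, ph$landmarks)
  expect_true(all(fit$planes$measurable))
  expect_true(all(abs(fit$planes$total_ica_deg - 90) < 2))

  # per-plane varying prescription
  ph2 <- generate_phantom(small_phantom_spec(left = c(60, 55, 50, 45, 40),
                                             right = c(58, 53, 48, 43, 38)))
  fit2 <- measure_ica(ph2$mask, ph2$landmarks)
  expect_true(all(abs(fit2$planes$left_ica_deg - ph2$truth$left) < 2))
  expect_true(all(abs(fit2$planes$right_ica_deg - ph2$truth$right) < 2))
})

test_that("total = 180 - left - right holds exactly wherever measurable", {
  set.seed(33)
  ph <- generate_phantom(small_phantom_spec(50, 35, noise_flip_prob = 0.1,
                                            seed = 5))
  fit <- measure_ica(ph$mask, ph$landmarks)
  ok <- fit$planes$measurable
  expect_identical(fit$planes$total_ica_deg[ok],
                   180 - fit$planes$left_ica_deg[ok] - fit$planes$right_ica_deg[ok])
})

test_that("an anterior avulsion gap makes plane 1 unmeasurable, not fatal", {
  ph <- generate_phantom(small_phantom_spec(
    45, 45, avulsion = list(side = "left", extent_mm = 12)))  # plane 1 at 10 mm
  fit <- measure_ica(ph$mask, ph$landmarks)
  expect_false(fit$planes$measurable[1])
  expect_true(is.na(fit$planes$total_ica_deg[1]))
  expect_true(all(fit$planes$measurable[2:5]))
})

test_that("measurements are invariant under rigid motion of the whole scene", {
  ph <- generate_phantom(small_phantom_spec(55, 40))
  fit <- measure_ica(ph$mask, ph$landmarks)
  set.seed(34)
  for (i in 1:3) {
    R <- random_rotation(); t <- stats::runif(3, -30, 30)
    fit2 <- measure_ica(transform_mask(ph$mask, R, t),
                        transform_landmarks(ph$landmarks, R, t))
    expect_true(max(abs(fit2$planes$left_ica_deg - fit$planes$left_ica_deg)) < 0.5)
    expect_true(max(abs(fit2$planes$right_ica_deg - fit$planes$right_ica_deg)) < 0.5)
  }
})

test_that("mirroring the scene across the midline swaps left and right exactly", {
  ph <- generate_phantom(small_phantom_spec(50, 30))
  fit <- measure_ica(ph$mask, ph$landmarks)
  mir <- mirror_scene(ph$mask, ph$landmarks)
  fitm <- measure_ica(mir$mask, mir$landmarks)
  expect_identical(fitm$planes$left_ica_deg, fit$planes$right_ica_deg)
  expect_identical(fitm$planes$right_ica_deg, fit$planes$left_ica_deg)
})

test_that("steeper phantoms yield strictly smaller total ICA", {
  angles <- c(20, 35, 50, 65)
  totals <- vapply(angles, function(a) {
    ph <- generate_phantom(small_phantom_spec(a, a))
    mean(measure_ica(ph$mask, ph$landmarks)$planes$total_ica_deg)
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})
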