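# Phantom generator and cohort simulator: determinism, noise model,
# avulsion locality, robustness of the estimator under boundary noise.

test_that("phantom generation is deterministic and carries analytic truth", {
  sp <- small_phantom_spec(40, 55)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_equal(a$truth$total, rep(180 - 40 - 55, 5))

  flat <- generate_phantom(small_phantom_spec(0, 0))
  fit <- measure_ica(flat$mask, flat$landmarks)
  expect_true(all(abs(fit$planes$total_ica_deg - 180) < 2))

  expect_error(phantom_spec(left_angles = 88), "\\[0, 85\\]")
  expect_error(phantom_spec(thickness_mm = 0.2), "voxel")
})

test_that("boundary noise is seed-deterministic and identity at prob 0", {
  ph <- generate_phantom(small_phantom_spec(45, 45))
  expect_identical(add_boundary_noise(ph$mask, 0)$voxels, ph$mask$voxels)
  n1 <- add_boundary_noise(ph$mask, 0.3, seed = 9)
  n2 <- add_boundary_noise(ph$mask, 0.3, seed = 9)
  expect_identical(n1$voxels, n2$voxels)
  expect_false(identical(n1$voxels,
                         add_boundary_noise(ph$mask, 0.3, seed = 10)$voxels))
  # only boundary-adjacent voxels may change
  changed <- which(n1$voxels != ph$mask$voxels)
  expect_gt(length(changed), 0L)
})

test_that("an avulsion never changes measurements posterior to its extent", {
  base <- generate_phantom(small_phantom_spec(45, 45))
  avul <- generate_phantom(small_phantom_spec(
    45, 45, avulsion = list(side = "left", extent_mm = 12)))
  f0 <- measure_ica(base$mask, base$landmarks)
  f1 <- measure_ica(avul$mask, avul$landmarks)
  # planes 3-5 (axial 30, 40, 50 mm) are entirely posterior to the 12 mm gap
  expect_identical(f1$planes$left_ica_deg[3:5], f0$planes$left_ica_deg[3:5])
  expect_identical(f1$planes$right_ica_deg[3:5], f0$planes$right_ica_deg[3:5])
})

test_that("angle recovery survives 20% boundary-voxel noise", {
  ph <- generate_phantom(small_phantom_spec(45, 45))
  ok <- vapply(1:50, function(s) {
    noisy <- add_boundary_noise(ph$mask, 0.2, seed = s)
    fit <- measure_ica(noisy, ph$landmarks)
    all(fit$planes$measurable) && all(abs(fit$planes$total_ica_deg - 90) < 5)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("cohort simulation is byte-identical under a fixed seed", {
  a <- simulate_cohort(cohort_sim_spec(seed = 7))
  b <- simulate_cohort(cohort_sim_spec(seed = 7))
  expect_identical(a, b)
  expect_equal(nrow(a$manifest), 55L)
  expect_equal(sum(!a$measurements$measurable), 9L)  # plane-1 avulsions
  # drawn totals stay inside the open (0, 180) interval
  expect_true(all(a$measurements$total_ica_deg > 0 &
                  a$measurements$total_ica_deg < 180, na.rm = TRUE))
  # side scores always reproduce the drawn category under categorize_defect
  cats <- categorize_scores(a$scores)
  expect_true(all(cats$category %in% c("none", "minor", "major")))
})
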