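# PICS landmark frame: validation, construction, coordinate transform.

test_that("validate_landmarks flags each degenerate configuration by name", {
  expect_length(validate_landmarks(axis_aligned_landmarks()), 0L)

  coincident <- landmark_set(c(0, 0, 0), c(0, 0, 0), c(50, 60, -10), c(-50, 60, -10))
  expect_match(validate_landmarks(coincident), "degenerate PICS line", all = FALSE)

  same_spines <- landmark_set(c(0, 0, 0), c(0, 100, 0), c(10, 60, 0), c(10, 60, 0))
  expect_match(validate_landmarks(same_spines), "degenerate lateral axis", all = FALSE)

  parallel <- landmark_set(c(0, 0, 0), c(0, 100, 0), c(0, 80, 0), c(0, 20, 0))
  expect_match(validate_landmarks(parallel), "parallel", all = FALSE)

  expect_error(pics_frame(coincident), "degenerate PICS line")
})

test_that("frame axes match the hand-computed axis-aligned and Gram-Schmidt cases", {
  fr <- pics_frame(axis_aligned_landmarks())
  expect_equal(fr$axis_pics, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$axis_lateral, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$axis_vertical, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))

  # inter-spine vector (100, 40, 0); removing its projection on (0,1,0)
  # leaves (100, 0, 0) -> lateral axis (1, 0, 0)
  skew <- landmark_set(c(0, 0, 0), c(0, 100, 0), c(50, 80, 0), c(-50, 40, 0))
  fr2 <- pics_frame(skew)
  expect_equal(fr2$axis_lateral, c(1, 0, 0), tolerance = 1e-12)
})

test_that("frames are orthonormal and right-handed for random configurations", {
  set.seed(11)
  for (i in 1:50) {
    fr <- pics_frame(random_landmarks())
    expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  }
})

test_that("frame construction is equivariant under rigid motions", {
  set.seed(12)
  ls <- random_landmarks()
  fr <- pics_frame(ls)
  for (i in 1:20) {
    R <- random_rotation(); t <- stats::runif(3, -50, 50)
    fr2 <- pics_frame(transform_landmarks(ls, R, t))
    expect_equal(fr2$axis_pics, as.numeric(R %*% fr$axis_pics), tolerance = 1e-7)
    expect_equal(fr2$axis_lateral, as.numeric(R %*% fr$axis_lateral), tolerance = 1e-7)
    expect_equal(fr2$axis_vertical, as.numeric(R %*% fr$axis_vertical), tolerance = 1e-7)
  }
})

test_that("to_pics_coords maps landmarks as specified and preserves distances", {
  ls <- axis_aligned_landmarks()
  fr <- pics_frame(ls)
  expect_equal(as.numeric(to_pics_coords(fr$origin, fr)), c(0, 0, 0))
  expect_equal(as.numeric(to_pics_coords(c(0, 100, 0), fr)), c(0, 100, 0))

  set.seed(13)
  pts <- matrix(stats::rnorm(300, sd = 40), ncol = 3)
  out <- to_pics_coords(pts, pics_frame(random_landmarks()))
  for (i in 1:100) {
    jk <- sample(100, 2)
    expect_equal(sqrt(sum((pts[jk[1], ] - pts[jk[2], ])^2)),
                 sqrt(sum((out[jk[1], ] - out[jk[2], ])^2)),
                 tolerance = 1e-9)
  }
})

test_that("projection onto the PICS axis is the axial dot product", {
  ls <- axis_aligned_landmarks()
  fr <- pics_frame(ls)
  expect_equal(project_onto_pics_axis(ls$pubic_symphysis, fr), 0)
  expect_equal(project_onto_pics_axis(c(0, 100, 0), fr), 100)
  expect_equal(project_onto_pics_axis(c(-50, 60, -10), fr), 60)
})
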