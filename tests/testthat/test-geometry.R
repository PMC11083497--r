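test_that("a straight cylinder yields its axis as centerline with orthonormal frames", {
  m <- make_cylinder_mask(c(41, 41, 101), c(1, 1, 1), c(20, 20, 0),
                          c(0, 0, 1), 12)
  cl <- extract_centerline(m, c(20, 20, 0), c(20, 20, 100), step_mm = 2)
  # every sample lies on the axis to within half a voxel
  dev <- sqrt((cl$points[, 1] - 20)^2 + (cl$points[, 2] - 20)^2)
  expect_lt(max(dev), 0.5)
  expect_true(all(diff(cl$s) > 0))
  # orthonormal frames everywhere
  for (i in seq_len(nrow(cl$points))) {
    expect_equal(sum(cl$tangent[i, ]^2), 1, tolerance = 1e-9)
    expect_equal(sum(cl$u[i, ]^2), 1, tolerance = 1e-9)
    expect_equal(sum(cl$v[i, ]^2), 1, tolerance = 1e-9)
    expect_equal(sum(cl$u[i, ] * cl$tangent[i, ]), 0, tolerance = 1e-9)
    expect_equal(sum(cl$v[i, ] * cl$tangent[i, ]), 0, tolerance = 1e-9)
    expect_equal(sum(cl$u[i, ] * cl$v[i, ]), 0, tolerance = 1e-9)
  }
  # centerline stays inside the mask
  expect_true(all(sample_volume(m, cl$points, "nearest") == 1))
})

test_that("candy-cane arc length is recovered within 2%", {
  fx <- fix_seg_bulge()
  L_true <- fx$case$truth$total_length_mm
  expect_lt(abs(max(fx$cl$s) - L_true) / L_true, 0.02)
})

test_that("parallel-transport frames have no flips along the phantom", {
  fx <- fix_seg_bulge()
  u <- fx$cl$u
  ang <- acos(pmin(1, rowSums(u[-1, ] * u[-nrow(u), ]))) * 180 / pi
  expect_lt(max(ang), 15)
})

test_that("section partition matches the analytic ranges", {
  fx <- fix_seg_bulge()
  rng <- attr(fx$cl, "section_ranges")
  tr <- fx$case$truth$section_ranges
  step <- diff(fx$cl$s[1:2])
  # the extracted centerline starts at the snapped root, so allow a couple
  # of sampling steps of slack on each boundary
  expect_lt(abs(rng$ascending[2] - tr$ascending[2]), 2 * step + 1)
  expect_lt(abs(rng$arch[2] - tr$arch[2]), 2 * step + 1)
  expect_identical(unique(fx$cl$section),
                   c("ascending", "arch", "descending"))
  # labels are contiguous: one run per section
  runs <- rle(fx$cl$section)
  expect_identical(runs$values, c("ascending", "arch", "descending"))
})

test_that("partition demands the required landmarks in order", {
  fx <- fix_seg_bulge()
  lm <- fx$case$truth$landmarks
  expect_error(partition_sections(fx$cl, lm["aortic_root"]),
               "missing landmark")
  swapped <- lm
  swapped$brachiocephalic <- lm$left_subclavian
  swapped$left_subclavian <- lm$brachiocephalic
  expect_error(partition_sections(fx$cl, swapped), "order")
})

test_that("centerline extraction is equivariant under 90-degree rotation", {
  fx <- fix_seg_bulge()
  m <- fx$mask2
  rot <- rotate90_z(m)
  tr <- fx$case$truth
  root_r <- rotate90_z_point(tr$landmarks$aortic_root, m)
  cel_r <- rotate90_z_point(tr$landmarks$celiac, m)
  cl_r <- extract_centerline(rot, root_r, cel_r, step_mm = 2)
  # compare rotated original samples against the rotated-mask centerline at
  # matched arc lengths
  cl <- fx$cl
  s_common <- seq(5, min(max(cl$s), max(cl_r$s)) - 5, by = 10)
  p_orig <- vapply(s_common, function(sv) {
    i <- which.min(abs(cl$s - sv))
    rotate90_z_point(cl$points[i, ], m)
  }, numeric(3))
  p_rot <- vapply(s_common, function(sv) {
    i <- which.min(abs(cl_r$s - sv))
    cl_r$points[i, ]
  }, numeric(3))
  dev <- sqrt(colSums((p_orig - p_rot)^2))
  expect_lt(max(dev), 2 * max(m$spacing))
})

test_that("disconnected endpoints and far landmarks raise clear errors", {
  a <- array(FALSE, c(20, 20, 20))
  a[2:5, 2:5, 2:5] <- TRUE
  a[14:18, 14:18, 14:18] <- TRUE
  m <- aq_mask(a)
  expect_error(extract_centerline(m, c(3, 3, 3), c(16, 16, 16)),
               "disconnected")
  expect_error(extract_centerline(m, c(3, 3, 3), c(3, 3, 19)), "celiac")
})

test_that("centerlines round-trip through JSON", {
  fx <- fix_seg_bulge()
  td <- withr::local_tempdir()
  write_centerline(fx$cl, file.path(td, "cl.json"))
  cl2 <- read_centerline(file.path(td, "cl.json"))
  expect_equal(cl2$points, fx$cl$points, ignore_attr = TRUE)
  expect_equal(cl2$s, fx$cl$s)
  expect_identical(cl2$section, fx$cl$section)
})
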