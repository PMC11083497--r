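# straight centerline along z for analytic masks
straight_cl <- function(z_max, centre_xy, step = 2) {
  n <- floor(z_max / step) + 1
  pts <- cbind(centre_xy[1], centre_xy[2], (seq_len(n) - 1) * step)
  cl <- aortaq:::.centerline_from_points(pts, step)
  cl$section <- rep("descending", nrow(cl$points))
  attr(cl, "section_ranges") <- list(ascending = c(0, 0),
                                     arch = c(0, 0),
                                     descending = c(0, max(cl$s)))
  cl
}

test_that("a circular section measures its true diameter on every ray", {
  m <- make_cylinder_mask(c(61, 61, 41), c(1, 1, 1), c(30, 30, 0),
                          c(0, 0, 1), 15)
  cl <- straight_cl(40, c(30, 30))
  cs <- cross_section_diameters(m, cl, 10)
  expect_equal(mean(cs$ray_diameters), 30, tolerance = 0.6)
  expect_lt(diff(range(cs$ray_diameters)), 2)     # all chords alike
  expect_equal(cs$average_diameter, mean(cs$ray_diameters))
  expect_equal(cs$area, pi * 15^2, tolerance = pi * 15^2 * 0.03)
  expect_false(is.null(cs$boundary))
})

test_that("elliptical sections average chords between the two axes", {
  m <- make_elliptic_mask(c(61, 41, 21), c(1, 1, 1), c(30, 20), 20, 10)
  cl <- straight_cl(20, c(30, 20))
  cs <- cross_section_diameters(m, cl, 5)
  expect_gt(cs$average_diameter, 20)
  expect_lt(cs$average_diameter, 40)
  # independent oracle: analytic centre-chord length of the ellipse,
  # 2ab/sqrt(b^2 cos^2 + a^2 sin^2), averaged over the same ray angles
  th <- (seq_len(90) - 1) * pi / 90
  oracle <- mean(2 * 20 * 10 / sqrt((10 * cos(th))^2 + (20 * sin(th))^2))
  expect_equal(cs$average_diameter, oracle, tolerance = 0.8)
})

test_that("diameters are measured perpendicular to a tilted cylinder", {
  # axis at 45 degrees to the grid: an axial (z-plane) cut would read
  # 30*sqrt(2) mm; perpendicular measurement must still read 30 mm
  dir <- c(1, 0, 1) / sqrt(2)
  m <- make_cylinder_mask(c(121, 51, 121), c(1, 1, 1), c(10, 25, 10),
                          dir, 15)
  p0 <- c(10, 25, 10)
  cl <- extract_centerline(m, p0 + 12 * dir, p0 + 130 * dir, step_mm = 2)
  n <- nrow(cl$points)
  mid <- (n %/% 3):(2 * n %/% 3)
  d_mid <- vapply(mid, function(i)
    cross_section_diameters(m, cl, i)$average_diameter, numeric(1))
  expect_lt(abs(median(d_mid) - 30) / 30, 0.03)
})

test_that("per-section maxima recover the analytic bulge", {
  fx <- fix_seg_bulge()     # r0 15, A 5, descending bulge, 1 mm voxels
  rep <- max_section_diameters(fx$mask2, fx$cl)
  tol <- max(max(fx$mask2$spacing), 0.05 * 40)
  expect_equal(rep$descending$max_avg_diameter_mm, 40, tolerance = tol)
  expect_equal(rep$ascending$max_avg_diameter_mm, 30, tolerance = tol)
  spec <- fx$case$truth$spec
  expect_lt(abs(rep$descending$s_mm - spec$bulge_center_s0),
            spec$bulge_width_sigma_s)
  # profile invariant: reported max equals the profile max on that section
  prof <- rep$profile
  expect_equal(rep$descending$max_avg_diameter_mm,
               max(prof$diameter[prof$section == "descending" &
                                   prof$s >= rep$descending$s_mm - 50 &
                                   prof$s <= rep$descending$s_mm + 50],
                   na.rm = TRUE))
})

test_that("reported maxima are invariant to volume rotation within 1%", {
  fx <- fix_seg_bulge()
  rep0 <- max_section_diameters(fx$mask2, fx$cl)
  rot <- rotate90_z(fx$mask2)
  tr <- fx$case$truth
  lm_r <- lapply(tr$landmarks, rotate90_z_point, v = fx$mask2)
  cl_r <- extract_centerline(rot, lm_r$aortic_root, lm_r$celiac, step_mm = 2)
  cl_r <- partition_sections(cl_r, lm_r)
  rep_r <- max_section_diameters(rot, cl_r)
  for (sec in c("ascending", "descending")) {
    rel <- abs(rep_r[[sec]]$max_avg_diameter_mm -
                 rep0[[sec]]$max_avg_diameter_mm) /
      rep0[[sec]]$max_avg_diameter_mm
    expect_lt(rel, 0.01)
  }
})

test_that("increasing bulge amplitude strictly increases the section maximum", {
  maxima <- vapply(c(0, 4, 8), function(A) {
    case <- synth_case(phantom_spec(bulge_amplitude_mm = A,
                                    bulge_section = "descending",
                                    noise_sd_hu = 0, seed = 50))
    m <- resample_isotropic(classical_segment(case$volume, noise_sd_hu = 1), 2)
    cl <- extract_centerline(m, case$truth$landmarks$aortic_root,
                             case$truth$landmarks$celiac)
    cl <- partition_sections(cl, case$truth$landmarks)
    max_section_diameters(m, cl)$descending$max_avg_diameter_mm
  }, numeric(1))
  expect_true(all(diff(maxima) > 0))
})

test_that("empty planes are measurement gaps, not errors", {
  m <- make_cylinder_mask(c(21, 21, 21), c(1, 1, 1), c(10, 10, 0),
                          c(0, 0, 1), 5)
  cl <- straight_cl(20, c(10, 10))
  # a plane far outside the mask
  cl$points[1, ] <- c(200, 200, 200)
  expect_null(cross_section_diameters(m, cl, 1))
})
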