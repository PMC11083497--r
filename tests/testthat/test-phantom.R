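test_that("analytic diameter oracle follows the radius profile", {
  case0 <- fix_case_plain()
  # constant-radius tube: 30 mm everywhere
  s <- seq(0, case0$truth$total_length_mm, by = 5)
  expect_equal(ground_truth_diameter(case0$truth, s), rep(30, length(s)))

  spec <- phantom_spec(base_radius_mm = 15, bulge_amplitude_mm = 5,
                       bulge_section = "descending", noise_sd_hu = 0,
                       seed = 2)
  case <- synth_case(spec)
  expect_equal(ground_truth_diameter(case$truth, spec$bulge_center_s0), 40)
  # far from the bulge the tube is at its base diameter
  expect_equal(ground_truth_diameter(case$truth, 5), 30, tolerance = 1e-6)
  # brute-force scan: the apex sits at s0 and the global max is 2*(r0+A)
  grid <- seq(0, case$truth$total_length_mm, by = 0.1)
  dg <- ground_truth_diameter(case$truth, grid)
  expect_equal(grid[which.max(dg)], spec$bulge_center_s0, tolerance = 0.1)
  expect_equal(max(dg), 40, tolerance = 1e-5)
  expect_error(ground_truth_diameter(case$truth, -1), "out of range")
  expect_error(ground_truth_diameter(case$truth, 1e5), "out of range")
})

test_that("volume synthesis is bit-reproducible under a fixed seed", {
  spec <- phantom_spec(seed = 33, voxel_mm = 2)
  a <- synth_case(spec)
  b <- synth_case(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$mask$voxels, b$truth$mask$voxels)
  c2 <- synth_case(phantom_spec(seed = 34, voxel_mm = 2))
  expect_false(identical(a$volume$voxels, c2$volume$voxels))
})

test_that("phantom materials and geometry are consistent", {
  case <- fix_case_plain()   # noiseless, contrast
  v <- case$volume; tr <- case$truth
  # lumen voxels carry the contrast HU, background the air-ish HU
  centre <- tr$centerline[round(nrow(tr$centerline) / 2), ]
  expect_equal(sample_volume(v, rbind(centre)), 300, tolerance = 1)
  expect_equal(sample_volume(v, rbind(c(2, 2, 2))), -50, tolerance = 1)
  # mask and volume share the raster; landmarks project in anatomical order
  expect_identical(dim(v$voxels), dim(tr$mask$voxels))
  expect_true(all(diff(tr$landmark_s) > 0))
  # section ranges partition [0, L)
  rng <- tr$section_ranges
  expect_equal(rng$ascending[1], 0)
  expect_equal(rng$ascending[2], rng$arch[1])
  expect_equal(rng$arch[2], rng$descending[1])
  expect_equal(rng$descending[2], tr$total_length_mm)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(bulge_center_s0 = 5, bulge_section = "descending"),
               "bulge_center_s0")
  expect_error(phantom_spec(flap_arc_range = c(50, 20)), "flap_arc_range")
  expect_error(phantom_spec(base_radius_mm = -3))
  expect_error(phantom_spec(base_radius_mm = 1, wall_thickness_mm = 2))
})

test_that("cohort label balance and reproducibility hold for any prevalence", {
  sp <- cohort_specs(20, 0.5, seed = 3)
  expect_equal(sum(vapply(sp, `[[`, TRUE, "has_dissection")), 10)
  sp <- cohort_specs(100, 0.42, seed = 3)
  expect_equal(sum(vapply(sp, `[[`, TRUE, "has_dissection")), 42)
  for (pv in c(0, 0.1, 0.73, 1)) {
    n <- 17
    sp <- cohort_specs(n, pv, seed = 8)
    expect_equal(sum(vapply(sp, `[[`, TRUE, "has_dissection")), round(n * pv))
  }
  a <- cohort_specs(10, 0.3, seed = 42)
  b <- cohort_specs(10, 0.3, seed = 42)
  expect_identical(a, b)
  expect_error(cohort_specs(5, 0.5, spec_ranges = list()), "empty")
})

test_that("phantom cases round-trip through NIfTI + JSON sidecars", {
  case <- synth_case(phantom_spec(voxel_mm = 2, seed = 12))
  td <- withr::local_tempdir()
  write_phantom_case(case, file.path(td, "c"))
  v2 <- read_volume(file.path(td, "c.nii.gz"))
  m2 <- read_volume(file.path(td, "c.mask.nii.gz"), as_mask = TRUE)
  expect_equal(v2$voxels, case$volume$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(v2$spacing, case$volume$spacing)
  expect_identical(m2$voxels, case$truth$mask$voxels)
  side <- jsonlite::read_json(file.path(td, "c.truth.json"),
                              simplifyVector = TRUE)
  expect_true(isFALSE(side$dissection_label))
  expect_equal(side$total_length_mm, case$truth$total_length_mm)
})
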