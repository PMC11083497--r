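# Constructed slices: a disc of given HU, optionally crossed by a darker
# horizontal flap band.
make_disc_slice <- function(hu_lumen = 300, flap_hu = NULL, radius = 15,
                            ng = 41, noise = 0) {
  cx <- (ng + 1) / 2
  d <- sqrt(outer((1:ng - cx)^2, (1:ng - cx)^2, "+"))
  comp <- d <= radius
  hu <- matrix(NA_real_, ng, ng)
  hu[comp] <- hu_lumen
  if (!is.null(flap_hu))
    hu[comp & row(hu) >= cx - 1 & row(hu) <= cx + 1] <- flap_hu
  if (noise > 0) hu[comp] <- hu[comp] + rnorm(sum(comp), 0, noise)
  list(hu = hu, comp = comp, s = 0, section = "descending", valid = TRUE)
}

test_that("slice features have the fixed 18-value contract", {
  f <- slice_features(make_disc_slice())
  expect_length(f, 18)
  expect_true(attr(f, "valid"))
  empty <- slice_features(list(hu = NULL, comp = NULL, valid = FALSE))
  expect_length(empty, 18)
  expect_false(attr(empty, "valid"))
  expect_true(all(empty == 0))
})

test_that("a uniform disc has degenerate texture features", {
  f <- slice_features(make_disc_slice())
  expect_equal(unname(f["hu_sd"]), 0)
  expect_equal(unname(f["ridge_response_max"]), 0)
  expect_equal(unname(f["dark_fraction"]), 0)
  # histogram mass concentrates in the single bin holding 300 HU
  expect_equal(max(f[paste0("hist_bin", 1:8)]), 1)
  # area of a 15 px disc at 1 mm
  expect_equal(unname(f["area_mm2"]), pi * 15^2, tolerance = 20)
  expect_equal(unname(f["equiv_diameter_mm"]), 30, tolerance = 1)
})

test_that("a flap strictly raises membrane-sensitive features", {
  plain <- slice_features(make_disc_slice())
  flap <- slice_features(make_disc_slice(flap_hu = 60))
  expect_gt(flap["ridge_response_max"], plain["ridge_response_max"])
  expect_gt(flap["dark_fraction"], plain["dark_fraction"])
  expect_gt(flap["hu_sd"], plain["hu_sd"])
})

test_that("straightened slice count and disc diameters follow the geometry", {
  # straight cylinder, length 300 mm -> floor(300/2)+1 = 151 slices
  m <- make_cylinder_mask(c(41, 41, 301), c(1, 1, 1), c(20, 20, 0),
                          c(0, 0, 1), 15)
  v <- aq_volume(array(ifelse(m$voxels, 300, -50), dim(m$voxels)),
                 m$spacing, m$origin)
  cl <- extract_centerline(m, c(20, 20, 0), c(20, 20, 300), step_mm = 2)
  sv <- straighten(v, m, cl)
  expect_length(sv$slices, floor(max(cl$s) / 2) + 1)
  eqd <- vapply(sv$slices[5:(length(sv$slices) - 5)], function(sl)
    unname(slice_features(sl)["equiv_diameter_mm"]), numeric(1))
  expect_lt(max(abs(eqd - 30)), 1.5)
})

test_that("straightened diameters track the analytic radius profile", {
  fx <- fix_seg_bulge()
  sv <- straighten(fx$case$volume, fx$mask2, fx$cl)
  tr <- fx$case$truth
  ns <- length(sv$slices)
  idx <- 5:(ns - 5)
  err <- vapply(idx, function(i) {
    sl <- sv$slices[[i]]
    if (!sl$valid) return(NA_real_)
    unname(slice_features(sl)["equiv_diameter_mm"]) - 2 * tr$radius_fn(sl$s)
  }, numeric(1))
  expect_lt(max(abs(err), na.rm = TRUE), 2.5)  # about one working voxel
})

test_that("probability pooling matches hand computations and is monotone", {
  expect_equal(pool_probabilities(rep(0, 30))$probability, 0)
  expect_equal(pool_probabilities(rep(1, 30))$probability, 1)
  p <- c(0.9, 0.9, 0.9, rep(0.1, 27))
  expect_equal(pool_probabilities(p, k_min = 3, k_frac = 0.1)$probability, 0.9)
  set.seed(6)
  for (r in 1:20) {
    pv <- runif(25)
    base <- pool_probabilities(pv)$probability
    j <- sample.int(25, 1)
    pv2 <- pv; pv2[j] <- min(1, pv[j] + runif(1))
    expect_gte(pool_probabilities(pv2)$probability, base)
  }
})

test_that("SVM training is seeded and separates separable slices", {
  plain_sv <- structure(list(
    slices = replicate(20, make_disc_slice(noise = 5), simplify = FALSE),
    inplane_mm = 1, spacing_mm = 2), class = "aq_straightened")
  flap_sv <- structure(list(
    slices = replicate(20, make_disc_slice(flap_hu = 60, noise = 5),
                       simplify = FALSE),
    inplane_mm = 1, spacing_mm = 2), class = "aq_straightened")
  cohort <- list(list(sv = plain_sv, labels = rep(FALSE, 20)),
                 list(sv = flap_sv, labels = rep(TRUE, 20)))
  m1 <- train_dissection_classifier(cohort, seed = 2)
  m2 <- train_dissection_classifier(cohort, seed = 2)
  expect_identical(c(m1$cost, m1$gamma), c(m2$cost, m2$gamma))
  # training slices classify perfectly
  r_plain <- predict_dissection(m1, plain_sv)
  r_flap <- predict_dissection(m1, flap_sv)
  expect_lt(r_plain$patient_probability, 0.5)
  expect_gt(r_flap$patient_probability, 0.5)
  expect_true(r_flap$decision)
  expect_false(r_plain$decision)
  # single-class input is rejected
  expect_error(train_dissection_classifier(
    list(list(sv = plain_sv, labels = rep(FALSE, 20)))), "single class")
})

test_that("too few valid slices flag the result indeterminate", {
  sv2 <- structure(list(
    slices = replicate(2, make_disc_slice(), simplify = FALSE),
    inplane_mm = 1, spacing_mm = 2), class = "aq_straightened")
  plain_sv <- structure(list(
    slices = replicate(10, make_disc_slice(noise = 5), simplify = FALSE),
    inplane_mm = 1, spacing_mm = 2), class = "aq_straightened")
  flap_sv <- structure(list(
    slices = replicate(10, make_disc_slice(flap_hu = 60, noise = 5),
                       simplify = FALSE),
    inplane_mm = 1, spacing_mm = 2), class = "aq_straightened")
  model <- train_dissection_classifier(
    list(list(sv = plain_sv, labels = rep(FALSE, 10)),
         list(sv = flap_sv, labels = rep(TRUE, 10))), seed = 1)
  res <- predict_dissection(model, sv2)
  expect_true(res$indeterminate)
})
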