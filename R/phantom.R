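#' Phantom specification for a synthetic thoracic aorta
#'
#' Describes a "candy-cane" tube: an ascending limb, a half-torus arch and a
#' descending limb, with a Gaussian aneurysm bulge in the lumen radius
#' profile, an optional dissection flap (a thin membrane splitting the lumen
#' into two channels) and an optional graft segment in the wall. Intensities
#' follow a simple Hounsfield-unit model for contrast or non-contrast CT.
#'
#' The outer vessel radius along arc length `s` is
#' `r(s) = r0 + A * exp(-(s - s0)^2 / (2 * sigma^2))`;
#' the lumen occupies radii up to `r(s) - wall_thickness_mm` and the wall the
#' remaining shell, so `2 * r(s)` is the external vessel diameter — the
#' quantity recovered when measuring the segmented vessel envelope.
#'
#' @param limb_length_mm length of each straight limb (mm).
#' @param arch_radius_mm radius of the half-torus arch centreline (mm).
#' @param base_radius_mm baseline outer vessel radius `r0` (mm).
#' @param bulge_amplitude_mm aneurysm amplitude `A` (mm, >= 0; 0 = no bulge).
#' @param bulge_section `"ascending"` or `"descending"`; which limb carries
#'   the bulge when `bulge_center_s0` is not given.
#' @param bulge_center_s0 arc-length position of the bulge apex (mm);
#'   default: midpoint of `bulge_section`.
#' @param bulge_width_sigma_s Gaussian width of the bulge (mm).
#' @param wall_thickness_mm thickness of the vessel wall shell (mm).
#' @param has_dissection logical; add an intimal flap.
#' @param flap_thickness_mm flap sheet thickness (mm).
#' @param flap_arc_range length-2 arc-length interval covered by the flap
#'   (mm); default: a 60 mm stretch of the proximal descending aorta.
#' @param has_graft logical; replace a mid-descending stretch of wall with
#'   high-attenuation graft material.
#' @param contrast logical; contrast-enhanced (bright lumen) or non-contrast.
#' @param voxel_mm isotropic voxel size (mm).
#' @param noise_sd_hu Gaussian noise standard deviation (HU).
#' @param hu_model named list of HU values for `lumen`, `wall`, `flap`,
#'   `graft`, `background`; `NULL` uses the defaults (contrast lumen 300,
#'   non-contrast lumen 40, wall 50, flap 60, graft 500, background -50).
#' @param margin_mm padding between the outer vessel wall and volume faces.
#' @param seed integer seed controlling the noise field.
#' @return A validated `aq_phantom_spec` list.
#' @export
phantom_spec <- function(limb_length_mm = 100, arch_radius_mm = 35,
                         base_radius_mm = 15, bulge_amplitude_mm = 0,
                         bulge_section = c("descending", "ascending"),
                         bulge_center_s0 = NULL, bulge_width_sigma_s = 15,
                         wall_thickness_mm = 2,
                         has_dissection = FALSE, flap_thickness_mm = 2,
                         flap_arc_range = NULL,
                         has_graft = FALSE, contrast = TRUE,
                         voxel_mm = 1, noise_sd_hu = 10, hu_model = NULL,
                         margin_mm = 8, seed = 1L) {
  bulge_section <- match.arg(bulge_section)
  stopifnot(limb_length_mm > 0, arch_radius_mm > 0, base_radius_mm > 0,
            bulge_amplitude_mm >= 0, bulge_width_sigma_s > 0,
            wall_thickness_mm > 0, base_radius_mm > wall_thickness_mm,
            flap_thickness_mm > 0, voxel_mm > 0, noise_sd_hu >= 0)
  L <- 2 * limb_length_mm + pi * arch_radius_mm
  arch0 <- limb_length_mm
  arch1 <- limb_length_mm + pi * arch_radius_mm
  sec <- list(ascending = c(0, arch0 + 0.25 * pi * arch_radius_mm),
              arch = c(arch0 + 0.25 * pi * arch_radius_mm,
                       arch0 + 0.75 * pi * arch_radius_mm),
              descending = c(arch0 + 0.75 * pi * arch_radius_mm, L))
  if (is.null(bulge_center_s0))
    bulge_center_s0 <- mean(sec[[bulge_section]])
  rng <- sec[[bulge_section]]
  if (bulge_center_s0 < rng[1] || bulge_center_s0 >= rng[2])
    stop("bulge_center_s0 must lie inside the ", bulge_section, " section")
  if (is.null(flap_arc_range))
    flap_arc_range <- c(arch1 + 10, min(arch1 + 70, L - 5))
  if (flap_arc_range[1] < 0 || flap_arc_range[2] > L ||
      flap_arc_range[1] >= flap_arc_range[2])
    stop("flap_arc_range must be an increasing interval inside [0, total length]")
  hu_default <- list(lumen = if (contrast) 300 else 40, wall = 50, flap = 60,
                     graft = 500, background = -50)
  hu <- if (is.null(hu_model)) hu_default else modifyList(hu_default, hu_model)
  structure(list(
    limb_length_mm = limb_length_mm, arch_radius_mm = arch_radius_mm,
    base_radius_mm = base_radius_mm, bulge_amplitude_mm = bulge_amplitude_mm,
    bulge_section = bulge_section, bulge_center_s0 = bulge_center_s0,
    bulge_width_sigma_s = bulge_width_sigma_s,
    wall_thickness_mm = wall_thickness_mm,
    has_dissection = has_dissection, flap_thickness_mm = flap_thickness_mm,
    flap_arc_range = flap_arc_range, has_graft = has_graft,
    contrast = contrast, voxel_mm = voxel_mm, noise_sd_hu = noise_sd_hu,
    hu_model = hu, margin_mm = margin_mm, seed = as.integer(seed),
    total_length_mm = L, section_ranges = sec), class = "aq_phantom_spec")
}

# Internal candy-cane geometry: limb/arch anchor coordinates in world mm.
.cane_geometry <- function(spec) {
  rmax <- spec$base_radius_mm + spec$bulge_amplitude_mm
  pad <- spec$margin_mm + rmax
  xa <- pad                              # ascending limb x
  cx <- xa + spec$arch_radius_mm         # arch centre x
  yc <- pad                              # tube plane y
  z0 <- pad                              # limb bottom z
  z1 <- z0 + spec$limb_length_mm         # arch centre z
  ext <- c(cx + spec$arch_radius_mm + pad, 2 * pad,
           z1 + spec$arch_radius_mm + pad)
  list(xa = xa, cx = cx, yc = yc, z0 = z0, z1 = z1, extent = ext,
       R = spec$arch_radius_mm, limb = spec$limb_length_mm,
       L = spec$total_length_mm)
}

# Closed-form distance from world points to the candy-cane centreline and the
# arc-length parameter of the closest centreline point.
# pts: n x 3 matrix. Returns list(d, s).
.cane_dist <- function(pts, g) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  # ascending limb (vertical segment at x = xa)
  t1 <- pmin(pmax(z - g$z0, 0), g$limb)
  d1 <- sqrt((x - g$xa)^2 + (y - g$yc)^2 + (z - (g$z0 + t1))^2)
  # arch: half circle centre (cx, yc, z1) from angle 0 (ascending) to pi
  phi <- atan2(z - g$z1, g$cx - x)
  phi <- pmin(pmax(phi, 0), pi)
  qx <- g$cx - g$R * cos(phi); qz <- g$z1 + g$R * sin(phi)
  d2 <- sqrt((x - qx)^2 + (y - g$yc)^2 + (z - qz)^2)
  # descending limb (vertical segment at x = cx + R)
  t3 <- pmin(pmax(g$z1 - z, 0), g$limb)
  d3 <- sqrt((x - (g$cx + g$R))^2 + (y - g$yc)^2 + (z - (g$z1 - t3))^2)
  s1 <- t1
  s2 <- g$limb + g$R * phi
  s3 <- g$limb + pi * g$R + t3
  d <- pmin(d1, d2, d3)
  s <- ifelse(d1 <= d2 & d1 <= d3, s1, ifelse(d2 <= d3, s2, s3))
  list(d = d, s = s)
}

# Evaluate the analytic centreline point at arc length s (vectorized).
.cane_point <- function(s, g) {
  s <- pmin(pmax(s, 0), g$L)
  x <- y <- z <- numeric(length(s))
  a <- s <= g$limb
  b <- s > g$limb & s <= g$limb + pi * g$R
  c3 <- s > g$limb + pi * g$R
  x[a] <- g$xa; y[a] <- g$yc; z[a] <- g$z0 + s[a]
  phi <- (s[b] - g$limb) / g$R
  x[b] <- g$cx - g$R * cos(phi); y[b] <- g$yc; z[b] <- g$z1 + g$R * sin(phi)
  t <- s[c3] - g$limb - pi * g$R
  x[c3] <- g$cx + g$R; y[c3] <- g$yc; z[c3] <- g$z1 - t
  cbind(x, y, z)
}

# Radius closure with a minimal environment (so ground-truth objects do not
# retain the rasterization temporaries of synth_case's frame).
.make_radius_fn <- function(spec) {
  e <- new.env(parent = asNamespace("aortaq"))
  e$sp <- spec
  with(e, function(s) .radius_at(sp, s))
}

.radius_at <- function(spec, s) {
  spec$base_radius_mm + spec$bulge_amplitude_mm *
    exp(-(s - spec$bulge_center_s0)^2 / (2 * spec$bulge_width_sigma_s^2))
}

# Material classification of world points: 0 background, 1 lumen, 2 wall,
# 3 flap, 4 graft.
.classify_points <- function(pts, spec, g) {
  ds <- .cane_dist(pts, g)
  r <- .radius_at(spec, ds$s)
  cls <- integer(nrow(pts))
  lum <- ds$d <= r - spec$wall_thickness_mm
  wall <- !lum & ds$d <= r
  cls[lum] <- 1L
  cls[wall] <- 2L
  if (spec$has_dissection) {
    fl <- lum & ds$s >= spec$flap_arc_range[1] & ds$s <= spec$flap_arc_range[2] &
      abs(pts[, 2] - g$yc) <= spec$flap_thickness_mm / 2
    cls[fl] <- 3L
  }
  if (spec$has_graft) {
    gr <- spec$section_ranges$descending
    grange <- c(mean(gr) - diff(gr) / 6, mean(gr) + diff(gr) / 6)
    gi <- wall & ds$s >= grange[1] & ds$s <= grange[2]
    cls[gi] <- 4L
  }
  cls
}

#' Synthesize a phantom volume with analytic ground truth
#'
#' Rasterizes the candy-cane aorta described by a [phantom_spec()] onto an
#' isotropic grid. Voxels near material interfaces are supersampled (3^3
#' subsamples) so partial-volume intensities behave like band-limited CT;
#' Gaussian noise is then added under the spec's seed, making the volume
#' bit-reproducible.
#'
#' @param spec an `aq_phantom_spec`.
#' @return A list with elements `volume` (an [aq_volume()] of HU values) and
#'   `truth` (an `aq_ground_truth`: dense centreline samples with arc length,
#'   the analytic radius function, the five named landmarks, section ranges,
#'   the dissection label/slice range, and the rasterized true aorta mask).
#' @export
synth_case <- function(spec) {
  stopifnot(inherits(spec, "aq_phantom_spec"))
  g <- .cane_geometry(spec)
  h <- spec$voxel_mm
  nd <- as.integer(ceiling(g$extent / h)) + 1L
  # world coordinates of all voxel centres
  ax <- (seq_len(nd[1]) - 1) * h
  ay <- (seq_len(nd[2]) - 1) * h
  az <- (seq_len(nd[3]) - 1) * h
  pts <- cbind(rep(ax, times = nd[2] * nd[3]),
               rep(rep(ay, each = nd[1]), times = nd[3]),
               rep(az, each = nd[1] * nd[2]))
  ds <- .cane_dist(pts, g)
  r <- .radius_at(spec, ds$s)
  hu <- spec$hu_model
  # coarse classification at voxel centres
  cls <- .classify_points(pts, spec, g)
  val <- c(hu$background, hu$lumen, hu$wall, hu$flap, hu$graft)[cls + 1L]
  aorta_frac <- as.numeric(cls %in% 1:4)
  # boundary band: near the lumen or outer-wall interface, or near the flap
  band <- abs(ds$d - r) <= h | abs(ds$d - (r - spec$wall_thickness_mm)) <= h
  if (spec$has_dissection) {
    band <- band | (cls %in% c(1L, 3L) &
      abs(abs(pts[, 2] - g$yc) - spec$flap_thickness_mm / 2) <= h &
      ds$s >= spec$flap_arc_range[1] - h & ds$s <= spec$flap_arc_range[2] + h)
  }
  bidx <- which(band)
  if (length(bidx)) {
    off <- as.matrix(expand.grid(o1 = c(-1, 0, 1) / 3, o2 = c(-1, 0, 1) / 3,
                                 o3 = c(-1, 0, 1) / 3)) * h
    acc_val <- numeric(length(bidx))
    acc_frac <- numeric(length(bidx))
    for (m in seq_len(nrow(off))) {
      sub <- pts[bidx, , drop = FALSE]
      sub[, 1] <- sub[, 1] + off[m, 1]
      sub[, 2] <- sub[, 2] + off[m, 2]
      sub[, 3] <- sub[, 3] + off[m, 3]
      cs <- .classify_points(sub, spec, g)
      acc_val <- acc_val + c(hu$background, hu$lumen, hu$wall, hu$flap,
                             hu$graft)[cs + 1L]
      acc_frac <- acc_frac + as.numeric(cs %in% 1:4)
    }
    val[bidx] <- acc_val / nrow(off)
    aorta_frac[bidx] <- acc_frac / nrow(off)
  }
  if (spec$noise_sd_hu > 0) {
    set.seed(spec$seed)
    val <- val + rnorm(length(val), 0, spec$noise_sd_hu)
  }
  vol <- aq_volume(array(val, nd), rep(h, 3), c(0, 0, 0))
  mask <- aq_mask(array(aorta_frac >= 0.5, nd), rep(h, 3), c(0, 0, 0))

  s_dense <- seq(0, g$L, by = min(1, h))
  cl_pts <- .cane_point(s_dense, g)
  lm_s <- c(aortic_root = 0,
            brachiocephalic = g$limb + 0.25 * pi * g$R,
            left_common_carotid = g$limb + 0.50 * pi * g$R,
            left_subclavian = g$limb + 0.75 * pi * g$R,
            celiac = g$L)
  lms <- lapply(lm_s, function(sv) as.numeric(.cane_point(sv, g)))
  truth <- structure(list(
    centerline = cl_pts, s = s_dense,
    radius_fn = .make_radius_fn(spec),
    landmarks = lms, landmark_s = lm_s,
    section_ranges = spec$section_ranges,
    total_length_mm = g$L,
    dissection_label = isTRUE(spec$has_dissection),
    dissected_slice_range = if (isTRUE(spec$has_dissection))
      spec$flap_arc_range else numeric(0),
    mask = mask, spec = spec), class = "aq_ground_truth")
  list(volume = vol, truth = truth)
}

#' Analytic ground-truth diameter at an arc-length position
#'
#' @param gt an `aq_ground_truth` from [synth_case()].
#' @param s arc length in mm, within `[0, total length]`.
#' @return Diameter `2 * r(s)` in mm (vectorized over `s`).
#' @export
ground_truth_diameter <- function(gt, s) {
  stopifnot(inherits(gt, "aq_ground_truth"))
  if (any(s < 0 | s > gt$total_length_mm))
    stop("arc length out of range [0, ", round(gt$total_length_mm, 1), "]")
  2 * gt$radius_fn(s)
}

#' Draw a reproducible cohort of phantom specifications
#'
#' Samples per-case phantom parameters uniformly from the given ranges and
#' assigns dissection to exactly `round(n * dissection_prevalence)` cases at
#' seeded-random positions.
#'
#' @param n number of cases.
#' @param dissection_prevalence fraction of dissection-positive cases.
#' @param seed integer seed; the cohort is a pure function of it.
#' @param spec_ranges named list of `c(min, max)` ranges for
#'   `base_radius_mm`, `bulge_amplitude_mm`, `bulge_width_sigma_s`,
#'   `limb_length_mm`, `arch_radius_mm`; and scalars `contrast`,
#'   `noise_sd_hu`, `voxel_mm` applied to all cases.
#' @return A list of `aq_phantom_spec` objects of length `n`.
#' @export
cohort_specs <- function(n, dissection_prevalence = 0.42, seed = 1L,
                         spec_ranges = NULL) {
  stopifnot(n >= 1, dissection_prevalence >= 0, dissection_prevalence <= 1)
  defaults <- list(base_radius_mm = c(12, 18), bulge_amplitude_mm = c(0, 10),
                   bulge_width_sigma_s = c(12, 20),
                   limb_length_mm = c(90, 110), arch_radius_mm = c(30, 40),
                   contrast = TRUE, noise_sd_hu = 10, voxel_mm = 1)
  if (!is.null(spec_ranges) && !length(spec_ranges))
    stop("empty spec_ranges configuration")
  rg <- if (is.null(spec_ranges)) defaults else modifyList(defaults, spec_ranges)
  set.seed(seed)
  npos <- round(n * dissection_prevalence)
  pos <- rep(FALSE, n)
  pos[sample.int(n, npos)] <- TRUE
  ru <- function(rng) runif(1, rng[1], rng[2])
  lapply(seq_len(n), function(i) {
    phantom_spec(
      limb_length_mm = ru(rg$limb_length_mm),
      arch_radius_mm = ru(rg$arch_radius_mm),
      base_radius_mm = ru(rg$base_radius_mm),
      bulge_amplitude_mm = ru(rg$bulge_amplitude_mm),
      bulge_section = sample(c("ascending", "descending"), 1),
      bulge_width_sigma_s = ru(rg$bulge_width_sigma_s),
      has_dissection = pos[i],
      contrast = isTRUE(rg$contrast),
      noise_sd_hu = rg$noise_sd_hu,
      voxel_mm = rg$voxel_mm,
      seed = sample.int(.Machine$integer.max, 1))
  })
}

#' Materialize a phantom cohort
#'
#' Convenience wrapper over [cohort_specs()] + [synth_case()]; prefer
#' iterating over [cohort_specs()] when memory matters.
#'
#' @inheritParams cohort_specs
#' @return List of `list(volume, truth)` cases.
#' @export
make_cohort <- function(n, dissection_prevalence = 0.42, seed = 1L,
                        spec_ranges = NULL) {
  lapply(cohort_specs(n, dissection_prevalence, seed, spec_ranges), synth_case)
}

#' Write a phantom case to disk
#'
#' The volume goes to `<stem>.nii.gz`; the ground truth (centreline samples,
#' landmarks, section ranges, labels) to a `<stem>.truth.json` sidecar and
#' the true mask to `<stem>.mask.nii.gz`.
#'
#' @param case a `list(volume, truth)` from [synth_case()].
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_phantom_case <- function(case, stem) {
  write_volume(case$volume, paste0(stem, ".nii.gz"))
  write_volume(case$truth$mask, paste0(stem, ".mask.nii.gz"))
  tr <- case$truth
  side <- list(
    s = tr$s, centerline = tr$centerline,
    radius = tr$radius_fn(tr$s),
    landmarks = tr$landmarks, landmark_s = as.list(tr$landmark_s),
    section_ranges = tr$section_ranges,
    total_length_mm = tr$total_length_mm,
    dissection_label = tr$dissection_label,
    dissected_slice_range = tr$dissected_slice_range)
  jsonlite::write_json(side, paste0(stem, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
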