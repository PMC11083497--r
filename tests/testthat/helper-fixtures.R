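# Shared fixtures, memoized for the whole test session. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# Standard phantom cases ------------------------------------------------------

fix_case_plain <- function() memo("case_plain",
  synth_case(phantom_spec(bulge_amplitude_mm = 0, noise_sd_hu = 0, seed = 1)))

fix_case_bulge <- function() memo("case_bulge",
  synth_case(phantom_spec(bulge_amplitude_mm = 5, bulge_section = "descending",
                          seed = 7)))

fix_case_dissect <- function() memo("case_dissect",
  synth_case(phantom_spec(has_dissection = TRUE, seed = 5)))

# classical segmentation + 2 mm working mask + partitioned centerline
fix_seg <- function(case_fn, key) memo(key, {
  case <- case_fn()
  m <- classical_segment(case$volume)
  mw <- resample_isotropic(m, 2)
  cl <- extract_centerline(mw, case$truth$landmarks$aortic_root,
                           case$truth$landmarks$celiac)
  cl <- partition_sections(cl, case$truth$landmarks)
  list(case = case, mask = m, mask2 = mw, cl = cl)
})

fix_seg_bulge <- function() fix_seg(fix_case_bulge, "seg_bulge")
fix_seg_dissect <- function() fix_seg(fix_case_dissect, "seg_dissect")

# Analytic masks --------------------------------------------------------------

# Cylinder mask: axis through `origin_pt` along unit `dir`, radius r, world
# box given by dims*spacing.
make_cylinder_mask <- function(dims, spacing, origin_pt, dir, radius) {
  dir <- dir / sqrt(sum(dir^2))
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * spacing[k])
  pts <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
               rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
               rep(ax[[3]], each = dims[1] * dims[2]))
  rel <- sweep(pts, 2, origin_pt)
  t <- rel %*% dir
  d2 <- rowSums(rel^2) - t^2
  aq_mask(array(d2 <= radius^2, dims), spacing, c(0, 0, 0))
}

# Elliptic cylinder along z with in-plane semi-axes (a, b).
make_elliptic_mask <- function(dims, spacing, centre_xy, a, b) {
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * spacing[k])
  pts <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
               rep(rep(ax[[2]], each = dims[1]), times = dims[3]))
  inside <- ((pts[, 1] - centre_xy[1]) / a)^2 +
    ((pts[, 2] - centre_xy[2]) / b)^2 <= 1
  aq_mask(array(inside, dims), spacing, c(0, 0, 0))
}

# Rotate a volume/mask 90 degrees about the z axis (world geometry included).
rotate90_z <- function(v) {
  d <- dim(v$voxels)
  arr <- aperm(v$voxels, c(2, 1, 3))
  arr <- arr[d[2]:1, , , drop = FALSE]   # (x,y) -> (ny-1-y, x)
  out <- if (is.logical(v$voxels)) aq_mask(arr, v$spacing[c(2, 1, 3)], v$origin)
  else aq_volume(arr, v$spacing[c(2, 1, 3)], v$origin)
  out
}

# Matching point transform for rotate90_z (0-based world, origin 0): the voxel
# at index (i,j,k) moves to (ny-1-j, i, k).
rotate90_z_point <- function(p, v) {
  d <- dim(v$voxels)
  idx <- as.numeric(world_to_index(v, rbind(p)))
  c((d[2] - 1 - idx[2]) * v$spacing[2], idx[1] * v$spacing[1],
    idx[3] * v$spacing[3])
}

# A very small trained U-Net for unit tests (coarse phantoms, seconds).
fix_tiny_unet <- function() memo("tiny_unet", {
  cases <- lapply(1:6, function(i)
    synth_case(phantom_spec(voxel_mm = 2, seed = 100 + i,
                            bulge_amplitude_mm = (i %% 3) * 3)))
  cfg <- segmenter_config(depth = 2, base_filters = 4, epochs = 8,
                          patches_per_case = 2, patch_vox = 16,
                          resample_mm = 4, seed = 5)
  list(model = train_segmenter(cases, cfg), cases = cases, cfg = cfg)
})
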