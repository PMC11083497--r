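#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b `aq_mask` objects on the same raster (same dims and spacing).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("masks are on different rasters")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Keep the largest connected component of a mask
#'
#' @param m an `aq_mask`.
#' @param connectivity 6 or 26.
#' @return An `aq_mask` containing only the largest component.
#' @export
largest_component <- function(m, connectivity = 26) {
  lab <- .cpp_label3d(as.logical(m$voxels), dim(m$voxels), connectivity)
  if (max(lab) == 0L) stop("no aorta found: mask is empty")
  tab <- tabulate(lab)
  keep <- which.max(tab)
  aq_mask(array(lab == keep, dim(m$voxels)), m$spacing, m$origin)
}

#' Fill internal holes of a mask
#'
#' Background components not connected (6-connectivity) to the volume border
#' are absorbed into the mask.
#'
#' @param m an `aq_mask`.
#' @return A hole-free `aq_mask`.
#' @export
fill_holes <- function(m) {
  d <- dim(m$voxels)
  lab <- .cpp_label3d(!m$voxels, d, 6)
  arr <- array(lab, d)
  border <- unique(c(arr[1, , ], arr[d[1], , ], arr[, 1, ], arr[, d[2], ],
                     arr[, , 1], arr[, , d[3]]))
  border <- setdiff(border, 0L)
  filled <- m$voxels | (arr != 0L & !(arr %in% border))
  aq_mask(filled, m$spacing, m$origin)
}

# Box morphological closing with radius r voxels.
.close_mask <- function(m, r = 1L) {
  d <- dim(m$voxels)
  x <- .cpp_box_morph(as.logical(m$voxels), d, r, TRUE)
  x <- .cpp_box_morph(x, d, r, FALSE)
  aq_mask(array(x, d), m$spacing, m$origin)
}

#' Intensity-prior aortic segmentation
#'
#' A deterministic classical segmenter for phantom-regime intensities: keep
#' voxels inside the HU band spanned by the vessel materials (lumen, wall,
#' flap, graft) widened by `3 * noise_sd` on either side, then morphological
#' closing (which seals the thin dissection flap so true and false lumen end
#' up in one object), largest connected component, and hole filling.
#'
#' @param v an `aq_volume` of HU values.
#' @param contrast logical; selects the default lumen intensity.
#' @param hu_model optional HU model (see [phantom_spec()]).
#' @param noise_sd_hu assumed noise level in HU.
#' @return An `aq_mask` of the segmented aorta.
#' @export
classical_segment <- function(v, contrast = TRUE, hu_model = NULL,
                              noise_sd_hu = 10) {
  hu <- list(lumen = if (contrast) 300 else 40, wall = 50, flap = 60,
             graft = 500, background = -50)
  if (!is.null(hu_model)) hu <- modifyList(hu, hu_model)
  vessel <- c(hu$lumen, hu$wall, hu$flap, hu$graft)
  # lower cut at the background/vessel midpoint: partial-volume voxels with
  # >= 50% vessel occupancy fall inside the band, matching the ground-truth
  # occupancy convention; never closer than 3 sigma to the background level
  lo <- max((hu$background + min(vessel)) / 2,
            hu$background + 3 * noise_sd_hu)
  hi <- max(vessel) + 3 * noise_sd_hu
  raw <- aq_mask(array(v$voxels >= lo & v$voxels <= hi, dim(v$voxels)),
                 v$spacing, v$origin)
  if (!any(raw$voxels)) stop("no aorta found: empty threshold band")
  fill_holes(largest_component(.close_mask(raw, 1L)))
}
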