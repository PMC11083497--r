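#' Cross-sectional diameters perpendicular to the centerline
#'
#' Samples the segmentation mask on the plane spanned by the local frame
#' `(u, v)` at centerline sample `i`, keeps the in-plane connected component
#' containing the centerline point, and measures chord lengths through the
#' component centroid at `n_rays` uniformly spaced angles. The average
#' diameter is the mean of these chords; on a circular section it equals the
#' true diameter, and it is rotation-robust on irregular sections.
#'
#' @param m an `aq_mask`.
#' @param cl an `aq_centerline` with frames.
#' @param i sample index (1-based).
#' @param inplane_mm in-plane sampling resolution (mm).
#' @param n_rays number of chord angles over 180 degrees.
#' @param window_mm in-plane window extent (mm), centred on the centerline.
#' @return An `aq_cross_section` list: `s`, `centroid` (in-plane mm),
#'   `boundary` polygon, `ray_diameters`, `average_diameter`, `area`;
#'   or `NULL` when the plane misses the mask (a measurement gap).
#' @export
cross_section_diameters <- function(m, cl, i, inplane_mm = 0.5, n_rays = 90,
                                    window_mm = 80) {
  comp <- .inplane_component(m, cl, i, inplane_mm, window_mm)
  if (is.null(comp)) return(NULL)
  M <- comp$M
  ax <- comp$axis
  np <- sum(M)
  area <- np * inplane_mm^2
  idx <- which(M, arr.ind = TRUE)
  centroid <- c(mean(ax[idx[, 1]]), mean(ax[idx[, 2]]))
  chords <- .centroid_chords(M, ax, centroid, n_rays, inplane_mm)
  bnd <- contourLines(ax, ax, M * 1, levels = 0.5)
  boundary <- if (length(bnd)) cbind(bnd[[1]]$x, bnd[[1]]$y) else NULL
  structure(list(s = cl$s[i], centroid = centroid, boundary = boundary,
                 ray_diameters = chords, average_diameter = mean(chords),
                 area = area),
            class = "aq_cross_section")
}

# In-plane binary component containing the centerline point.
# Returns list(M = logical matrix, axis = in-plane coordinates) or NULL.
.inplane_component <- function(m, cl, i, inplane_mm, window_mm) {
  half <- window_mm / 2
  ax <- seq(-half, half, by = inplane_mm)
  ng <- length(ax)
  p <- cl$points[i, ]; u <- cl$u[i, ]; v <- cl$v[i, ]
  ab <- cbind(rep(ax, times = ng), rep(ax, each = ng))
  pts <- cbind(p[1] + ab[, 1] * u[1] + ab[, 2] * v[1],
               p[2] + ab[, 1] * u[2] + ab[, 2] * v[2],
               p[3] + ab[, 1] * u[3] + ab[, 2] * v[3])
  vals <- sample_volume(m, pts, method = "nearest", fill = 0)
  M <- matrix(vals > 0.5, ng, ng)
  if (!any(M)) return(NULL)
  lab <- .cpp_label3d(as.vector(M), c(ng, ng, 1L), 26)
  lab <- matrix(lab, ng, ng)
  ic <- (ng + 1) %/% 2
  centre_lab <- lab[ic, ic]
  if (centre_lab == 0L) {
    # centreline point fell on a background pixel (e.g. flap); take the
    # nearest labelled pixel within 3 mm
    cand <- which(lab > 0L, arr.ind = TRUE)
    dd <- sqrt((ax[cand[, 1]])^2 + (ax[cand[, 2]])^2)
    if (!length(dd) || min(dd) > 3) return(NULL)
    centre_lab <- lab[cand[which.min(dd), , drop = FALSE]]
  }
  list(M = lab == centre_lab, axis = ax)
}

# Chord lengths through `centroid` at n_rays angles over 180 degrees.
.centroid_chords <- function(M, ax, centroid, n_rays, inplane_mm) {
  ng <- length(ax)
  half_step <- inplane_mm / 2
  tmax <- (max(ax) - min(ax))
  tt <- seq(half_step, tmax, by = half_step)
  theta <- (seq_len(n_rays) - 1) * pi / n_rays
  lookup <- function(a, b) {
    ia <- round((a - ax[1]) / inplane_mm) + 1
    ib <- round((b - ax[1]) / inplane_mm) + 1
    ok <- ia >= 1 & ia <= ng & ib >= 1 & ib <= ng
    out <- logical(length(a))
    out[ok] <- M[cbind(ia[ok], ib[ok])]
    out
  }
  vapply(theta, function(th) {
    dx <- cos(th); dy <- sin(th)
    reach <- function(sgn) {
      inside <- lookup(centroid[1] + sgn * tt * dx, centroid[2] + sgn * tt * dy)
      stop_i <- which(!inside)
      if (!length(stop_i)) return(tt[length(tt)])
      # boundary lies between the last inside sample and the first outside one
      tt[stop_i[1]] - half_step / 2
    }
    reach(1) + reach(-1)
  }, numeric(1))
}

#' Maximum average diameter per aortic section
#'
#' Computes the average-diameter profile `d(s)` at every centerline sample,
#' then reports, for the ascending and the descending section, the maximum
#' of the profile and its arc-length location. Samples within
#' `edge_exclusion_mm` of a section boundary (or of the centerline ends) are
#' excluded to avoid partition-jitter artifacts. The arch profile is part of
#' the returned profile but has no reported maximum, mirroring the two-number
#' clinical output.
#'
#' @inheritParams cross_section_diameters
#' @param edge_exclusion_mm exclusion margin at section boundaries (mm).
#' @return An `aq_diameter_report`: list with `ascending` and `descending`
#'   entries (`max_avg_diameter_mm`, `s_mm`), and `profile` (data.frame with
#'   `s`, `diameter`, `section`).
#' @export
max_section_diameters <- function(m, cl, edge_exclusion_mm = 5,
                                  inplane_mm = 0.5, n_rays = 90,
                                  window_mm = 80) {
  if (all(is.na(cl$section)))
    stop("centerline is not partitioned; call partition_sections() first")
  n <- nrow(cl$points)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cs <- cross_section_diameters(m, cl, i, inplane_mm, n_rays, window_mm)
    if (!is.null(cs)) d[i] <- cs$average_diameter
  }
  prof <- data.frame(s = cl$s, diameter = d, section = cl$section)
  rng <- attr(cl, "section_ranges")
  out <- list(profile = prof)
  for (sec in c("ascending", "descending")) {
    lo <- rng[[sec]][1] + edge_exclusion_mm
    hi <- rng[[sec]][2] - edge_exclusion_mm
    ok <- which(cl$section == sec & cl$s >= lo & cl$s <= hi & !is.na(d))
    # also stay clear of the physical centerline ends
    ok <- ok[cl$s[ok] >= edge_exclusion_mm &
               cl$s[ok] <= max(cl$s) - edge_exclusion_mm]
    if (!length(ok)) {
      out[[sec]] <- list(max_avg_diameter_mm = NA_real_, s_mm = NA_real_,
                         flag = "no valid samples")
    } else {
      j <- ok[which.max(d[ok])]
      out[[sec]] <- list(max_avg_diameter_mm = d[j], s_mm = cl$s[j])
    }
  }
  structure(out, class = "aq_diameter_report")
}

#' @export
print.aq_diameter_report <- function(x, ...) {
  cat("<aq_diameter_report>\n")
  for (sec in c("ascending", "descending")) {
    e <- x[[sec]]
    cat(sprintf("  %-10s max average diameter %.1f mm at s = %.1f mm\n",
                sec, e$max_avg_diameter_mm, e$s_mm))
  }
  invisible(x)
}

#' Write a diameter report as JSON
#' @param rep an `aq_diameter_report`.
#' @param path output path.
#' @export
write_diameter_report <- function(rep, path) {
  jsonlite::write_json(
    list(ascending = rep$ascending, descending = rep$descending,
         profile = rep$profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
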