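#' Extract the aortic centerline from a segmentation mask
#'
#' The path is found on the voxel adjacency graph of the mask (26-neighbour
#' connectivity) with edges weighted by physical step length divided by a
#' medialness factor `1 + EDT^2`, where EDT is the Euclidean distance (mm) to
#' the mask boundary. The shortest path from the aortic-root landmark to the
#' celiac landmark therefore hugs the medial axis. The raw voxel path is
#' smoothed by a moving average (window 5), resampled at uniform arc-length
#' steps, and equipped with rotation-minimizing orthonormal frames
#' `(tangent, u, v)` by parallel transport.
#'
#' @param m an `aq_mask`.
#' @param root,celiac 3D world points (mm) marking the two ends; snapped to
#'   the nearest mask voxel if within `snap_mm`.
#' @param step_mm uniform arc-length sampling step (mm).
#' @param snap_mm maximum landmark-to-mask snapping distance (mm).
#' @return An `aq_centerline`: matrix `points` (n x 3 mm), arc length `s`,
#'   unit `tangent`, in-plane `u`, `v` (n x 3 each) and a `section` label
#'   vector (filled by [partition_sections()]).
#' @export
extract_centerline <- function(m, root, celiac, step_mm = 2, snap_mm = 10) {
  d <- dim(m$voxels)
  mask <- as.logical(m$voxels)
  edt <- .cpp_edt3d(mask, d, m$spacing)
  g <- .cpp_mask_graph(mask, d, m$spacing, 1 + edt^2)
  # node world coordinates
  vox0 <- g$voxel - 1L
  ii <- vox0 %% d[1]
  jj <- (vox0 %/% d[1]) %% d[2]
  kk <- vox0 %/% (d[1] * d[2])
  coords <- index_to_world(m, cbind(ii, jj, kk))
  snap <- function(p, what) {
    dd <- sqrt(colSums((t(coords) - p)^2))
    i <- which.min(dd)
    if (dd[i] > snap_mm)
      stop(what, " landmark is ", round(dd[i], 1), " mm from the mask (> ",
           snap_mm, " mm)")
    i
  }
  i_root <- snap(as.numeric(root), "root")
  i_cel <- snap(as.numeric(celiac), "celiac")
  gr <- igraph::make_graph(rbind(g$from, g$to), n = length(g$voxel),
                           directed = FALSE)
  sp <- suppressWarnings(
    igraph::shortest_paths(gr, from = i_root, to = i_cel,
                           weights = g$weight, output = "vpath"))
  path <- as.integer(sp$vpath[[1]])
  if (length(path) < 2)
    stop("disconnected aorta: endpoints lie in different components")
  pts <- coords[path, , drop = FALSE]
  pts <- .moving_average(pts, 5L)
  .centerline_from_points(pts, step_mm, m)
}

.moving_average <- function(pts, w) {
  n <- nrow(pts)
  if (n <= w) return(pts)
  half <- w %/% 2
  out <- pts
  for (i in seq_len(n)) {
    a <- max(1, i - half); b <- min(n, i + half)
    out[i, ] <- colMeans(pts[a:b, , drop = FALSE])
  }
  out
}

# Build an aq_centerline from an ordered polyline: uniform arc-length
# resampling, tangents, parallel-transport frames.
.centerline_from_points <- function(pts, step_mm, vol = NULL) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  s_new <- seq(0, L, by = step_mm)
  rp <- vapply(1:3, function(k) approx(cs, pts[, k], xout = s_new)$y,
               numeric(length(s_new)))
  rp <- matrix(rp, ncol = 3)
  n <- nrow(rp)
  tg <- matrix(0, n, 3)
  tg[2:(n - 1), ] <- rp[3:n, ] - rp[1:(n - 2), ]
  tg[1, ] <- rp[2, ] - rp[1, ]
  tg[n, ] <- rp[n, ] - rp[n - 1, ]
  tg <- tg / sqrt(rowSums(tg^2))
  # parallel transport of an initial in-plane vector
  u <- matrix(0, n, 3)
  v <- matrix(0, n, 3)
  a <- c(1, 0, 0)
  if (abs(sum(a * tg[1, ])) > 0.9) a <- c(0, 1, 0)
  u[1, ] <- a - sum(a * tg[1, ]) * tg[1, ]
  u[1, ] <- u[1, ] / sqrt(sum(u[1, ]^2))
  v[1, ] <- .cross3(tg[1, ], u[1, ])
  for (i in 2:n) {
    ax <- .cross3(tg[i - 1, ], tg[i, ])
    na <- sqrt(sum(ax^2))
    cth <- min(1, max(-1, sum(tg[i - 1, ] * tg[i, ])))
    if (na < 1e-12) {
      u[i, ] <- u[i - 1, ]
    } else {
      u[i, ] <- .rodrigues(u[i - 1, ], ax / na, acos(cth))
    }
    u[i, ] <- u[i, ] - sum(u[i, ] * tg[i, ]) * tg[i, ]
    u[i, ] <- u[i, ] / sqrt(sum(u[i, ]^2))
    v[i, ] <- .cross3(tg[i, ], u[i, ])
  }
  structure(list(points = rp, s = s_new, tangent = tg, u = u, v = v,
                 section = rep(NA_character_, n)),
            class = "aq_centerline")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.rodrigues <- function(p, axis, theta) {
  p * cos(theta) + .cross3(axis, p) * sin(theta) +
    axis * sum(axis * p) * (1 - cos(theta))
}

#' @export
print.aq_centerline <- function(x, ...) {
  cat(sprintf("<aq_centerline> %d samples, length %.1f mm\n",
              nrow(x$points), max(x$s)))
  if (!all(is.na(x$section))) {
    tb <- table(x$section)
    cat("  sections:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partition a centerline into ascending / arch / descending sections
#'
#' Landmarks are projected to their nearest centerline sample; the ascending
#' section runs from the root to the brachiocephalic-artery origin, the arch
#' from there to the left subclavian artery, and the descending section from
#' the left subclavian to the distal end — the standard reading conventions
#' for thoracic aortic measurements.
#'
#' @param cl an `aq_centerline`.
#' @param landmarks named list of 3D points (mm); must contain at least
#'   `brachiocephalic` and `left_subclavian`.
#' @return The centerline with its `section` labels filled, plus a
#'   `section_ranges` attribute mapping each section to its `[s_start, s_end)`
#'   arc-length interval.
#' @export
partition_sections <- function(cl, landmarks) {
  need <- c("brachiocephalic", "left_subclavian")
  miss <- setdiff(need, names(landmarks))
  if (length(miss))
    stop("missing landmark(s) for partition: ", paste(miss, collapse = ", "))
  proj <- function(nm) {
    p <- as.numeric(landmarks[[nm]])
    which.min(colSums((t(cl$points) - p)^2))
  }
  i_bca <- proj("brachiocephalic")
  i_lsa <- proj("left_subclavian")
  n <- nrow(cl$points)
  if (!(1 < i_bca && i_bca < i_lsa && i_lsa < n)) {
    bad <- if (i_bca >= i_lsa) "left_subclavian" else "brachiocephalic"
    stop("landmark projections out of anatomical order near ", bad)
  }
  sec <- rep("descending", n)
  sec[seq_len(i_bca - 1)] <- "ascending"
  sec[i_bca:(i_lsa - 1)] <- "arch"
  cl$section <- sec
  attr(cl, "section_ranges") <- list(
    ascending = c(0, cl$s[i_bca]),
    arch = c(cl$s[i_bca], cl$s[i_lsa]),
    descending = c(cl$s[i_lsa], max(cl$s)))
  cl
}

#' Serialize / restore a centerline as JSON
#' @param cl an `aq_centerline`.
#' @param path output JSON path.
#' @export
write_centerline <- function(cl, path) {
  jsonlite::write_json(
    list(points = cl$points, s = cl$s, tangent = cl$tangent, u = cl$u,
         v = cl$v, section = cl$section), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(points = as.matrix(j$points), s = as.numeric(j$s),
                 tangent = as.matrix(j$tangent), u = as.matrix(j$u),
                 v = as.matrix(j$v), section = as.character(j$section)),
            class = "aq_centerline")
}
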