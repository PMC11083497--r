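#' Straighten the aorta along its centerline
#'
#' Curved planar reformation: the HU volume is resampled on planes
#' perpendicular to the centerline at a fixed 2.0 mm slice spacing and
#' 1.0 mm in-plane resolution, and each slice is masked to the in-plane
#' aortic component, yielding a rectangular volume stretched along the
#' vessel. Frames between centerline samples are obtained by linear
#' interpolation followed by re-orthonormalization.
#'
#' @param v an `aq_volume` of HU values.
#' @param m the corresponding `aq_mask`.
#' @param cl an `aq_centerline` (any sampling step; slices are placed at
#'   `seq(0, L, by = spacing_mm)` along its arc length).
#' @param window_mm in-plane window extent (mm).
#' @param inplane_mm in-plane resolution (mm).
#' @param spacing_mm slice spacing along the centerline (mm).
#' @return An `aq_straightened`: list of `slices`, each with `hu` (matrix,
#'   `NA` outside the aortic component), `comp` (logical component matrix),
#'   `s`, `section` and `valid`; plus `inplane_mm`, `spacing_mm`, `axis`.
#' @export
straighten <- function(v, m, cl, window_mm = 80, inplane_mm = 1,
                       spacing_mm = 2) {
  L <- max(cl$s)
  s_out <- seq(0, floor(L / spacing_mm) * spacing_mm, by = spacing_mm)
  half <- window_mm / 2
  ax <- seq(-half, half, by = inplane_mm)
  ng <- length(ax)
  ab <- cbind(rep(ax, times = ng), rep(ax, each = ng))
  interp_frame <- function(sv) {
    i <- findInterval(sv, cl$s, all.inside = TRUE)
    w <- (sv - cl$s[i]) / max(cl$s[i + 1] - cl$s[i], 1e-9)
    p <- (1 - w) * cl$points[i, ] + w * cl$points[i + 1, ]
    tg <- (1 - w) * cl$tangent[i, ] + w * cl$tangent[i + 1, ]
    u <- (1 - w) * cl$u[i, ] + w * cl$u[i + 1, ]
    tg <- tg / sqrt(sum(tg^2))
    u <- u - sum(u * tg) * tg
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) return(NULL)
    u <- u / nu
    list(p = p, u = u, v = .cross3(tg, u),
         section = cl$section[if (w < 0.5) i else i + 1])
  }
  slices <- lapply(s_out, function(sv) {
    fr <- interp_frame(sv)
    if (is.null(fr))
      return(list(hu = NULL, comp = NULL, s = sv, section = NA, valid = FALSE))
    pts <- cbind(fr$p[1] + ab[, 1] * fr$u[1] + ab[, 2] * fr$v[1],
                 fr$p[2] + ab[, 1] * fr$u[2] + ab[, 2] * fr$v[2],
                 fr$p[3] + ab[, 1] * fr$u[3] + ab[, 2] * fr$v[3])
    mk <- matrix(sample_volume(m, pts, "nearest", fill = 0) > 0.5, ng, ng)
    if (!any(mk))
      return(list(hu = NULL, comp = NULL, s = sv, section = fr$section,
                  valid = FALSE))
    lab <- matrix(.cpp_label3d(as.vector(mk), c(ng, ng, 1L), 26), ng, ng)
    ic <- (ng + 1) %/% 2
    cl0 <- lab[ic, ic]
    if (cl0 == 0L) {
      cand <- which(lab > 0L, arr.ind = TRUE)
      dd <- (ax[cand[, 1]])^2 + (ax[cand[, 2]])^2
      if (min(dd) > 9)
        return(list(hu = NULL, comp = NULL, s = sv, section = fr$section,
                    valid = FALSE))
      cl0 <- lab[cand[which.min(dd), , drop = FALSE]]
    }
    comp <- lab == cl0
    hu <- matrix(sample_volume(v, pts, "linear", fill = NA_real_), ng, ng)
    hu[!comp] <- NA_real_
    list(hu = hu, comp = comp, s = sv, section = fr$section, valid = TRUE)
  })
  structure(list(slices = slices, inplane_mm = inplane_mm,
                 spacing_mm = spacing_mm, axis = ax),
            class = "aq_straightened")
}

#' @export
print.aq_straightened <- function(x, ...) {
  cat(sprintf("<aq_straightened> %d slices (%d valid), %.1f mm spacing, %.1f mm in-plane\n",
              length(x$slices), sum(vapply(x$slices, `[[`, TRUE, "valid")),
              x$spacing_mm, x$inplane_mm))
  invisible(x)
}

# Feature names, fixed order (length 18).
.dissection_feature_names <- c(
  "area_mm2", "equiv_diameter_mm", "eccentricity",
  "hu_mean", "hu_sd", "hu_skewness", "hu_kurtosis",
  paste0("hist_bin", 1:8),
  "ridge_response_max", "dark_fraction", "radial_profile_var")

#' Per-slice dissection features
#'
#' An 18-value hand-crafted descriptor of one straightened cross-sectional
#' slice: component area and equivalent diameter, eccentricity from second
#' moments, HU mean/SD/skewness/excess kurtosis inside the lumen component,
#' an 8-bin intensity histogram (normalized, fixed -100..500 HU range), the
#' maximum dark-ridge (membrane) filter response, the fraction of pixels
#' more than 50 HU below the component median, and the variance of mean HU
#' across five concentric radial rings. A dissection flap — a thin dark
#' membrane crossing an enhanced lumen — raises the ridge response, the dark
#' fraction, the SD and the radial-profile variance.
#'
#' @param slice one element of `aq_straightened$slices`.
#' @param inplane_mm in-plane resolution of the slice (mm).
#' @return Numeric vector of length 18 with a `valid` attribute; all zeros
#'   with `valid = FALSE` for an empty slice.
#' @export
slice_features <- function(slice, inplane_mm = 1) {
  f <- stats::setNames(numeric(18), .dissection_feature_names)
  if (is.null(slice$comp) || !isTRUE(slice$valid) || !any(slice$comp)) {
    attr(f, "valid") <- FALSE
    return(f)
  }
  comp <- slice$comp
  hu <- slice$hu
  vals <- hu[comp]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    attr(f, "valid") <- FALSE
    return(f)
  }
  area <- sum(comp) * inplane_mm^2
  f["area_mm2"] <- area
  f["equiv_diameter_mm"] <- 2 * sqrt(area / pi)
  idx <- which(comp, arr.ind = TRUE)
  cx <- idx[, 1] - mean(idx[, 1]); cy <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(cx^2); mu02 <- mean(cy^2); mu11 <- mean(cx * cy)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  f["eccentricity"] <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  mu <- mean(vals); sdv <- sd(vals)
  f["hu_mean"] <- mu
  f["hu_sd"] <- if (is.finite(sdv)) sdv else 0
  if (is.finite(sdv) && sdv > 1e-9) {
    z <- (vals - mu) / sdv
    f["hu_skewness"] <- mean(z^3)
    f["hu_kurtosis"] <- mean(z^4) - 3
  }
  br <- seq(-100, 500, length.out = 9)
  hcounts <- tabulate(findInterval(pmin(pmax(vals, -100), 500 - 1e-9), br,
                                   rightmost.closed = TRUE), 8)
  f[paste0("hist_bin", 1:8)] <- hcounts / length(vals)
  f["ridge_response_max"] <- .ridge_response(hu, comp)
  medv <- median(vals)
  f["dark_fraction"] <- mean(vals < medv - 50)
  rr <- sqrt((idx[, 1] - mean(idx[, 1]))^2 + (idx[, 2] - mean(idx[, 2]))^2)
  ring <- findInterval(rr, seq(0, max(rr) + 1e-9, length.out = 6),
                       rightmost.closed = TRUE)
  hv <- hu[comp]
  ring_means <- tapply(hv, ring, mean, na.rm = TRUE)
  ring_means <- ring_means[is.finite(ring_means)]
  f["radial_profile_var"] <- if (length(ring_means) > 1) var(ring_means) else 0
  attr(f, "valid") <- TRUE
  f
}

# Maximum dark-ridge response inside the component: a pixel much darker than
# both flanking pixels (offset 2) along one of four orientations.
.ridge_response <- function(hu, comp) {
  ng <- nrow(hu)
  if (ng < 5) return(0)
  shifts <- list(c(2, 0), c(0, 2), c(2, 2), c(2, -2))
  core <- 3:(ng - 2)
  best <- matrix(-Inf, length(core), length(core))
  centre <- hu[core, core]
  for (o in shifts) {
    a <- hu[core + o[1], core + o[2]]
    b <- hu[core - o[1], core - o[2]]
    resp <- pmin(a - centre, b - centre)
    resp[is.na(resp)] <- -Inf
    best <- pmax(best, resp)
  }
  ok <- comp[core, core] & is.finite(best)
  if (!any(ok)) return(0)
  max(0, max(best[ok]))
}

# Feature matrix for all slices of a straightened volume.
.sv_features <- function(sv) {
  X <- t(vapply(sv$slices, function(sl) as.numeric(slice_features(sl, sv$inplane_mm)),
                numeric(18)))
  colnames(X) <- .dissection_feature_names
  valid <- vapply(sv$slices, function(sl) isTRUE(sl$valid), logical(1))
  list(X = X, valid = valid,
       s = vapply(sv$slices, `[[`, numeric(1), "s"))
}

#' Train the slice-level dissection classifier
#'
#' Standardizes the 18 slice features on the training set and fits an
#' RBF-kernel SVM with probability calibration; cost and kernel width are
#' selected by seeded 3-fold cross-validated grid search on slice accuracy.
#'
#' @param cohort list of cases, each `list(sv = <aq_straightened>,
#'   labels = <logical per slice>)`; slice labels typically derive from the
#'   phantom ground truth's dissected arc-length range.
#' @param cost_grid,gamma_grid candidate SVM hyperparameters.
#' @param seed integer seed for fold assignment and calibration.
#' @return An `aq_dissection_model` (SVM + feature standardization + chosen
#'   hyperparameters).
#' @export
train_dissection_classifier <- function(cohort,
                                        cost_grid = c(1, 10, 100),
                                        gamma_grid = c(0.01, 1 / 18, 0.25),
                                        seed = 1L) {
  feats <- lapply(cohort, function(cs) .sv_features(cs$sv))
  X <- do.call(rbind, lapply(feats, `[[`, "X"))
  valid <- unlist(lapply(feats, `[[`, "valid"))
  y <- unlist(lapply(seq_along(cohort), function(i) cohort[[i]]$labels))
  stopifnot(length(y) == nrow(X))
  X <- X[valid, , drop = FALSE]; y <- y[valid]
  if (length(unique(y)) < 2)
    stop("training data contains a single class")
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  scl[scl < 1e-9] <- 1
  Xs <- scale(X, ctr, scl)
  yf <- factor(y, levels = c(FALSE, TRUE))
  set.seed(seed)
  folds <- sample(rep_len(1:3, nrow(Xs)))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_acc <- vapply(seq_len(nrow(grid)), function(gi) {
    acc <- vapply(1:3, function(fd) {
      tr <- folds != fd
      fit <- e1071::svm(Xs[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = grid$cost[gi], gamma = grid$gamma[gi],
                        scale = FALSE)
      mean(predict(fit, Xs[!tr, , drop = FALSE]) == yf[!tr])
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  best <- which.max(cv_acc)
  set.seed(seed)
  fit <- e1071::svm(Xs, yf, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], probability = TRUE,
                    scale = FALSE)
  structure(list(svm = fit, center = ctr, scale = scl,
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_accuracy = cv_acc[best], grid = cbind(grid, cv_acc)),
            class = "aq_dissection_model")
}

#' Pool slice probabilities into a patient-level probability
#'
#' Mean of the top-k slice probabilities with
#' `k = max(k_min, ceiling(k_frac * n))`, capped at `n`. Raising any slice
#' probability can never lower the pooled value.
#'
#' @param probs slice probabilities in `[0, 1]`.
#' @param k_min,k_frac pooling parameters.
#' @return List with `probability` and the `k` used.
#' @export
pool_probabilities <- function(probs, k_min = 3, k_frac = 0.1) {
  if (!length(probs)) return(list(probability = NA_real_, k = 0L))
  k <- min(length(probs), max(k_min, ceiling(k_frac * length(probs))))
  list(probability = mean(sort(probs, decreasing = TRUE)[seq_len(k)]), k = k)
}

#' Patient-level dissection prediction
#'
#' Scores every valid slice with the slice SVM and pools the probabilities
#' into one patient-level probability as the mean of the top-k slice
#' probabilities, `k = max(k_min, ceiling(k_frac * n_slices))` — robust both
#' to isolated noisy slices and to dissections that span only a short
#' segment of the aorta.
#'
#' @param model an `aq_dissection_model`.
#' @param sv an `aq_straightened` volume.
#' @param k_min,k_frac pooling parameters.
#' @param threshold patient-level decision threshold.
#' @return An `aq_dissection_result`: `slice_probabilities`,
#'   `patient_probability`, `decision`, `threshold`, `indeterminate`.
#' @export
predict_dissection <- function(model, sv, k_min = 3, k_frac = 0.1,
                               threshold = 0.5) {
  fe <- .sv_features(sv)
  probs <- rep(NA_real_, nrow(fe$X))
  if (any(fe$valid)) {
    Xs <- scale(fe$X[fe$valid, , drop = FALSE], model$center, model$scale)
    pr <- predict(model$svm, Xs, probability = TRUE)
    pm <- attr(pr, "probabilities")
    probs[fe$valid] <- pm[, "TRUE"]
  }
  nv <- sum(fe$valid)
  indet <- nv < 3
  pv <- probs[fe$valid]
  pooled <- pool_probabilities(pv, k_min, k_frac)
  patient <- pooled$probability
  k <- pooled$k
  structure(list(slice_probabilities = probs, s = fe$s,
                 patient_probability = patient,
                 decision = isTRUE(patient >= threshold),
                 threshold = threshold, k = k, indeterminate = indet),
            class = "aq_dissection_result")
}

#' @export
print.aq_dissection_result <- function(x, ...) {
  cat(sprintf("<aq_dissection_result> patient probability %.3f -> %s (threshold %.2f%s)\n",
              x$patient_probability,
              if (x$decision) "DISSECTION" else "no dissection", x$threshold,
              if (x$indeterminate) "; INDETERMINATE: <3 valid slices" else ""))
  invisible(x)
}

# Per-slice labels for a straightened volume from ground truth.
.slice_labels <- function(sv, truth) {
  s <- vapply(sv$slices, `[[`, numeric(1), "s")
  rng <- truth$dissected_slice_range
  if (!length(rng)) return(rep(FALSE, length(s)))
  s >= rng[1] & s <= rng[2]
}
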