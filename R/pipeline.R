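#' Pipeline configuration
#'
#' @param segmenter `"classical"` for the intensity-prior segmenter, or a
#'   trained `aq_unet` model.
#' @param landmark_provider `"oracle"` (use ground-truth landmarks, phantom
#'   runs only), `"mask"` (mask-topology provider), a named list of points
#'   (mm), a path to a landmark JSON, or a (list of) `aq_landmark_agents`.
#' @param measure_resample_mm isotropic resolution (mm) at which geometry
#'   and diameters are measured; `NULL` measures on the segmenter's raster.
#' @param centerline_step_mm centerline sampling step (mm).
#' @param cutoff U-Net probability cutoff.
#' @param contrast intensity regime for the classical segmenter.
#' @param edge_exclusion_mm diameter edge exclusion at section boundaries.
#' @param inplane_mm,n_rays cross-section measurement settings.
#' @param dissection_model optional `aq_dissection_model` enabling the
#'   dissection stage.
#' @param seed integer seed stamped into the report (the default pipeline is
#'   deterministic given its inputs).
#' @return An `aq_pipeline_config` list.
#' @export
pipeline_config <- function(segmenter = "classical",
                            landmark_provider = "mask",
                            measure_resample_mm = 2,
                            centerline_step_mm = 2, cutoff = 0.5,
                            contrast = TRUE, edge_exclusion_mm = 5,
                            inplane_mm = 0.5, n_rays = 90,
                            dissection_model = NULL, seed = 1L) {
  structure(list(segmenter = segmenter,
                 landmark_provider = landmark_provider,
                 measure_resample_mm = measure_resample_mm,
                 centerline_step_mm = centerline_step_mm, cutoff = cutoff,
                 contrast = contrast, edge_exclusion_mm = edge_exclusion_mm,
                 inplane_mm = inplane_mm, n_rays = n_rays,
                 dissection_model = dissection_model, seed = as.integer(seed)),
            class = "aq_pipeline_config")
}

.resolve_landmarks <- function(cfg, v, mask, truth) {
  lp <- cfg$landmark_provider
  if (is.character(lp) && length(lp) == 1) {
    if (lp == "oracle") {
      if (is.null(truth)) stop("oracle landmark provider needs ground truth")
      return(oracle_landmarks(truth))
    }
    if (lp == "mask") return(landmarks_from_mask(mask))
    if (file.exists(lp)) {
      j <- jsonlite::read_json(lp, simplifyVector = TRUE)
      return(lapply(j, as.numeric))
    }
    stop("unknown landmark provider: ", lp)
  }
  if (inherits(lp, "aq_landmark_agents") ||
      (is.list(lp) && all(vapply(lp, inherits, TRUE, "aq_landmark_agents"))))
    return(detect_landmarks(lp, v, seed = cfg$seed))
  if (is.list(lp)) return(lp)   # explicit named points
  stop("unsupported landmark provider")
}

#' Run the full quantification pipeline on one volume
#'
#' Segmentation, landmark detection, centerline extraction and partition,
#' per-section maximal diameters, and (when a dissection model is supplied)
#' dissection screening. Stage failures are isolated: a later stage's error
#' is recorded in the report without discarding earlier results.
#'
#' @param volume an `aq_volume` or a path to a NIfTI file.
#' @param cfg an [pipeline_config()].
#' @param truth optional `aq_ground_truth` (for the oracle landmark
#'   provider).
#' @return An `aq_report`: `landmarks`, `diameters` (an
#'   `aq_diameter_report`), `dissection` (an `aq_dissection_result` or
#'   `NULL`), `errors` (named list of stage error messages), `provenance`.
#' @export
run_pipeline <- function(volume, cfg = pipeline_config(), truth = NULL) {
  if (is.character(volume)) volume <- read_volume(volume)
  errors <- list()
  mask <- landmarks <- cl <- diam <- diss <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  mask <- stage("segmentation", {
    if (inherits(cfg$segmenter, "aq_unet"))
      segment(cfg$segmenter, volume, cutoff = cfg$cutoff)$mask
    else
      classical_segment(volume, contrast = cfg$contrast)
  })
  mwork <- mask
  if (!is.null(mask) && !is.null(cfg$measure_resample_mm) &&
      max(abs(mask$spacing - cfg$measure_resample_mm)) > 1e-9)
    mwork <- resample_isotropic(mask, cfg$measure_resample_mm)
  landmarks <- if (!is.null(mwork))
    stage("landmarks", .resolve_landmarks(cfg, volume, mwork, truth))
  cl <- if (!is.null(mwork) && !is.null(landmarks))
    stage("centerline", {
      c0 <- extract_centerline(mwork, landmarks$aortic_root,
                               landmarks$celiac,
                               step_mm = cfg$centerline_step_mm)
      partition_sections(c0, landmarks)
    })
  diam <- if (!is.null(cl))
    stage("diametry", max_section_diameters(
      mwork, cl, edge_exclusion_mm = cfg$edge_exclusion_mm,
      inplane_mm = cfg$inplane_mm, n_rays = cfg$n_rays))
  diss <- if (!is.null(cl) && !is.null(cfg$dissection_model))
    stage("dissection", {
      sv <- straighten(volume, mwork, cl)
      predict_dissection(cfg$dissection_model, sv)
    })
  structure(list(
    landmarks = landmarks, diameters = diam, dissection = diss,
    centerline = cl, mask = mask, errors = errors,
    provenance = list(package_version = as.character(utils::packageVersion("aortaq")),
                      seed = cfg$seed,
                      segmenter = if (inherits(cfg$segmenter, "aq_unet"))
                        "unet" else cfg$segmenter,
                      measure_resample_mm = cfg$measure_resample_mm)),
    class = "aq_report")
}

#' @export
print.aq_report <- function(x, ...) {
  cat("<aq_report>\n")
  if (!is.null(x$diameters)) print(x$diameters)
  if (!is.null(x$dissection)) print(x$dissection)
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report as JSON
#' @param report an `aq_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(
    landmarks = report$landmarks,
    diameters = if (!is.null(report$diameters))
      list(ascending = report$diameters$ascending,
           descending = report$diameters$descending,
           profile = report$diameters$profile),
    dissection = if (!is.null(report$dissection))
      report$dissection[c("patient_probability", "decision", "threshold",
                          "indeterminate")],
    errors = report$errors, provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Evaluate the pipeline over a phantom cohort
#'
#' Runs [run_pipeline()] on every case, compares the automated per-section
#' maxima against the analytic ground-truth maxima with the full agreement
#' battery, and (when a dissection model is in the config) tallies the
#' dissection decisions against the ground-truth labels into diagnostic
#' metrics. Failed cases are excluded and counted.
#'
#' @param cases list of `list(volume, truth)` cases (e.g. [make_cohort()]).
#' @param cfg an [pipeline_config()].
#' @param verbose print per-case progress.
#' @return An `aq_cohort_eval`: `per_case` data.frame, `agreement` (overall,
#'   on per-case largest diameters), `agreement_by_section`, `diagnostics`
#'   (or `NULL`), `n_excluded`, `excluded_cases`.
#' @export
evaluate_cohort <- function(cases, cfg = pipeline_config(), verbose = FALSE) {
  rows <- list()
  excluded <- integer(0)
  decisions <- logical(0); labels <- logical(0)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    rep <- run_pipeline(cs$volume, cfg, truth = cs$truth)
    ok <- !is.null(rep$diameters) &&
      is.finite(rep$diameters$ascending$max_avg_diameter_mm) &&
      is.finite(rep$diameters$descending$max_avg_diameter_mm)
    if (!ok) {
      excluded <- c(excluded, i)
      if (verbose) message(sprintf("case %d excluded (%s)", i,
                                   paste(names(rep$errors), collapse = ",")))
      next
    }
    tr <- cs$truth
    truth_max <- function(rng) {
      sg <- seq(rng[1], rng[2] - 1e-9, by = 0.5)
      max(2 * tr$radius_fn(sg))
    }
    asc_t <- truth_max(tr$section_ranges$ascending)
    des_t <- truth_max(tr$section_ranges$descending)
    rows[[length(rows) + 1]] <- data.frame(
      case = i,
      auto_ascending = rep$diameters$ascending$max_avg_diameter_mm,
      truth_ascending = asc_t,
      auto_descending = rep$diameters$descending$max_avg_diameter_mm,
      truth_descending = des_t,
      auto_overall = max(rep$diameters$ascending$max_avg_diameter_mm,
                         rep$diameters$descending$max_avg_diameter_mm),
      truth_overall = max(asc_t, des_t))
    if (!is.null(rep$dissection) && !rep$dissection$indeterminate) {
      decisions <- c(decisions, rep$dissection$decision)
      labels <- c(labels, tr$dissection_label)
    }
    if (verbose) message(sprintf("case %d/%d done", i, length(cases)))
  }
  per_case <- do.call(rbind, rows)
  agr <- agreement_stats(paired_measurements(per_case$auto_overall,
                                             per_case$truth_overall))
  agr_sec <- list(
    ascending = agreement_stats(paired_measurements(
      per_case$auto_ascending, per_case$truth_ascending)),
    descending = agreement_stats(paired_measurements(
      per_case$auto_descending, per_case$truth_descending)))
  diag <- NULL
  if (length(decisions)) {
    tp <- sum(decisions & labels); fp <- sum(decisions & !labels)
    tn <- sum(!decisions & !labels); fn <- sum(!decisions & labels)
    diag <- diagnostic_metrics(tp, fp, tn, fn)
  }
  structure(list(per_case = per_case, agreement = agr,
                 agreement_by_section = agr_sec, diagnostics = diag,
                 n_excluded = length(excluded), excluded_cases = excluded,
                 n_processed = nrow(per_case)),
            class = "aq_cohort_eval")
}

#' @export
print.aq_cohort_eval <- function(x, ...) {
  cat(sprintf("<aq_cohort_eval> %d processed, %d excluded\n",
              x$n_processed, x$n_excluded))
  print(x$agreement)
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}
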