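# Cohort-level benchmark of the dissection screen: generate a seeded phantom
# cohort, run segmentation -> centerline -> straightening per case, train the
# slice SVM on the training split and score the held-out cases.

# Rank-based AUC (Mann-Whitney); probs for positives vs negatives.
.auc <- function(probs, labels) {
  r <- rank(probs)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Seeded end-to-end dissection screening benchmark
#'
#' Generates a phantom cohort (half dissection-positive by default), runs
#' the deterministic segmentation + centerline + straightening path per
#' case, trains the slice-level RBF-SVM on the training split (slice labels
#' from the phantom's dissected arc range) and evaluates patient-level
#' pooled predictions on the held-out cases.
#'
#' @param n cohort size.
#' @param prevalence dissection prevalence.
#' @param n_test held-out cases (taken from the end of the seeded cohort
#'   order).
#' @param seed cohort and classifier seed.
#' @param threshold patient-level decision threshold.
#' @param verbose print per-case progress.
#' @return List: `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `diagnostics` (an `aq_diagnostic`), `probs`, `labels` on the test
#'   split, and the fitted `model`.
#' @export
dissection_benchmark <- function(n = 60, prevalence = 0.5, n_test = 20,
                                 seed = 1L, threshold = 0.5,
                                 verbose = FALSE) {
  stopifnot(n_test < n)
  specs <- cohort_specs(n, prevalence, seed = seed)
  svs <- vector("list", n)
  labels <- logical(n)
  slice_labels <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- synth_case(specs[[i]])
    m <- resample_isotropic(classical_segment(cs$volume), 2)
    cl <- extract_centerline(m, cs$truth$landmarks$aortic_root,
                             cs$truth$landmarks$celiac)
    svs[[i]] <- straighten(cs$volume, m, cl)
    labels[i] <- cs$truth$dissection_label
    slice_labels[[i]] <- .slice_labels(svs[[i]], cs$truth)
    if (verbose) message(sprintf("case %d/%d straightened", i, n))
  }
  tr <- seq_len(n - n_test)
  te <- (n - n_test + 1):n
  cohort <- lapply(tr, function(i)
    list(sv = svs[[i]], labels = slice_labels[[i]]))
  model <- train_dissection_classifier(cohort, seed = seed)
  probs <- vapply(te, function(i)
    predict_dissection(model, svs[[i]], threshold = threshold)$patient_probability,
    numeric(1))
  dec <- probs >= threshold
  lab <- labels[te]
  tp <- sum(dec & lab); fp <- sum(dec & !lab)
  tn <- sum(!dec & !lab); fn <- sum(!dec & lab)
  dg <- diagnostic_metrics(tp, fp, tn, fn)
  list(auc = .auc(probs, lab),
       sensitivity = dg$sensitivity$estimate,
       specificity = dg$specificity$estimate,
       accuracy = dg$accuracy$estimate,
       diagnostics = dg, probs = probs, labels = lab, model = model)
}
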