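# End-to-end pipeline: records -> duplexes -> candidates -> features ->
# feature selection -> boosted ensemble -> ranked site predictions.

# duplex alignments (stem-extended) for a list of records
prepare_duplexes <- function(records, pad = 10L) {
  out <- lapply(records, function(r) extend_stem(build_duplex(r), pad))
  names(out) <- vapply(records, function(r) r$id, character(1))
  out
}

# candidate tables for all records; records whose annotated site admits no
# window are skipped (with the enumerate_candidates warning)
prepare_candidates <- function(records, duplexes, site_type, window = 22L) {
  tabs <- lapply(records, function(r)
    enumerate_candidates(duplexes[[r$id]], r, site_type, window))
  do.call(rbind, tabs)
}

# true anchor of a record in arm coordinates, or NA
true_anchor <- function(pre, d, site_type) {
  arm <- site_arm(site_type)
  ann <- arm_annotation(pre, arm)
  if (is.null(ann)) return(NA_integer_)
  pos <- if (grepl("_5$", site_type)) ann$start else ann$end
  if (arm == "5p") as.integer(pos)
  else as.integer(pos - (nchar(pre$sequence) - d$arm3_len))
}

#' Train a processing-site model
#'
#' Runs the full training pipeline for one site type: duplex construction
#' with 10-bp stem extension, 22-nt candidate enumeration, feature
#' extraction, feature ranking with the <=0-score filter, K-means
#' balancing and AdaBoost-SVM training.
#'
#' @param records List of annotated [pre_mirna()] records (multibranch
#'   structures already excluded, e.g. by [load_hairpins()]).
#' @param site_type `"P5_5"`, `"P5_3"`, `"P3_5"` or `"P3_3"`.
#' @param mode Feature mode, `"structured"` or `"sequence_only"`.
#' @param selection `"IG"` (default), `"CHI"`, `"Relief"`, or `"none"`.
#' @param k Optional cap on the number of selected features.
#' @param T Boosting rounds.
#' @param balance Apply K-means undersampling of negatives?
#' @param threshold Balancing threshold (clusters / undersampling factor).
#' @param window Candidate window length (nt).
#' @param pad Stem-extension pairs.
#' @param seed Integer seed.
#' @param C_grid,g_grid,folds,cv_max_n Per-round grid-search settings.
#' @return A `matsite_ensemble` ready for [mat_predict()].
#' @export
mat_train <- function(records, site_type = "P5_5",
                      mode = c("structured", "sequence_only"),
                      selection = c("IG", "CHI", "Relief", "none"),
                      k = NULL, T = 5L, balance = TRUE, threshold = 10L,
                      window = 22L, pad = 10L, seed = 1L,
                      C_grid = 2^c(-1, 3, 7), g_grid = 2^c(-7, -3, 1),
                      folds = 2L, cv_max_n = 600L) {
  mode <- match.arg(mode)
  selection <- match.arg(selection)
  duplexes <- prepare_duplexes(records, pad)
  cands <- prepare_candidates(records, duplexes, site_type, window)
  if (is.null(cands) || nrow(cands) == 0L) stop("no training candidates")
  if (!any(cands$label == 1L)) stop("no positive candidates; are records annotated?")
  m <- build_matrix(cands, duplexes, mode)
  if (selection == "none") {
    selected <- m$catalog
    thresholds <- NULL
  } else {
    scores <- score_features(m, selection, seed = seed)
    selected <- rank_and_select(scores, k)$selected
    thresholds <- binarize(m)$thresholds
  }
  ms <- m
  ms$x <- m$x[, selected, drop = FALSE]
  ms$catalog <- selected
  ens <- adaboost_train(ms, T = T, threshold = threshold, balance = balance,
                        seed = seed, C_grid = C_grid, g_grid = g_grid,
                        folds = folds, cv_max_n = cv_max_n)
  ens$catalog <- m$catalog
  ens$selected <- selected
  ens$thresholds <- thresholds
  ens$window <- as.integer(window)
  ens$pad <- as.integer(pad)
  ens
}

#' Predict ranked processing-site candidates for new hairpins
#'
#' @param ensemble A trained `matsite_ensemble`.
#' @param records List of [pre_mirna()] records (annotations, if any, are
#'   ignored for scoring).
#' @return Data frame with one row per candidate: `pre_id`, `anchor`
#'   (1-based arm coordinate), `score`, `hard_label`, `rank`
#'   (1 = best per hairpin).
#' @export
mat_predict <- function(ensemble, records) {
  duplexes <- prepare_duplexes(records, ensemble$pad)
  out <- list()
  for (r in records) {
    cand <- suppressWarnings(
      enumerate_candidates(duplexes[[r$id]], r, ensemble$site_type,
                           ensemble$window))
    if (nrow(cand) == 0L) {
      # unannotated or short-arm records still get scored if windows exist
      stripped <- r; stripped$matures <- NULL
      cand <- enumerate_candidates(duplexes[[r$id]], stripped,
                                   ensemble$site_type, ensemble$window)
      if (nrow(cand) == 0L) next
    }
    m <- build_matrix(cand, duplexes[r$id], ensemble$mode)
    ranked <- ensemble_predict(ensemble, m$x[, ensemble$selected, drop = FALSE])
    out[[r$id]] <- data.frame(pre_id = r$id,
                              anchor = m$anchor[ranked$row],
                              score = ranked$score,
                              hard_label = ranked$hard_label,
                              rank = ranked$rank)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Evaluate ranked predictions against annotated records
#'
#' @param predictions Output of [mat_predict()].
#' @param records The annotated [pre_mirna()] records that were predicted.
#' @param ensemble The ensemble used (for site type and padding).
#' @param max_dev,top_k Passed to [deviation_table()].
#' @return An `evaluation_report`, with the absence-information
#'   stratification attached as `$by_absence`.
#' @export
mat_evaluate <- function(predictions, records, ensemble, max_dev = 5L,
                         top_k = 5L) {
  duplexes <- prepare_duplexes(records, 0L)
  truths <- vapply(records, function(r)
    true_anchor(r, duplexes[[r$id]], ensemble$site_type), integer(1))
  names(truths) <- vapply(records, function(r) r$id, character(1))
  truths <- truths[!is.na(truths)]
  preds <- predictions[predictions$pre_id %in% names(truths), , drop = FALSE]
  rep <- deviation_table(preds, truths, max_dev = max_dev, top_k = top_k)
  rep$by_absence <- stratify_by_absence(preds, truths, duplexes, top_k)
  rep
}
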