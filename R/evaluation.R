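# Evaluation: exact-site accuracy, average position deviation, the
# per-deviation accuracy table (first candidate and top-five candidates)
# and stratification by absence information.

#' Exact prediction accuracy
#'
#' Fraction of hairpins whose predicted anchor equals the true anchor.
#'
#' @param predicted,truth Equal-length vectors of anchors (one per hairpin).
#' @return Accuracy in `[0, 1]`.
#' @export
site_accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(truth) == 0L) stop("no hairpins to evaluate")
  mean(predicted == truth)
}

#' Average position deviation (APD)
#'
#' Mean absolute difference, in nucleotides, between predicted and true
#' site positions.
#'
#' @inheritParams site_accuracy
#' @return APD in nt.
#' @export
apd <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(truth) == 0L) stop("no hairpins to evaluate")
  mean(abs(predicted - truth))
}

# per-hairpin deviations of the rank-1 candidate and of the best (minimum
# |deviation|, ties to the higher-ranked candidate) of the top k
rank_deviations <- function(ranked, truths, top_k = 5L) {
  ids <- unique(ranked$pre_id)
  stopifnot(all(ids %in% names(truths)))
  dev1 <- devk <- numeric(length(ids))
  names(dev1) <- names(devk) <- ids
  for (id in ids) {
    sub <- ranked[ranked$pre_id == id, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    devs <- abs(sub$anchor - truths[[id]])
    dev1[id] <- devs[1L]
    devk[id] <- min(devs[seq_len(min(top_k, length(devs)))])
  }
  list(first = dev1, topk = devk)
}

#' Position-deviation accuracy table
#'
#' For each deviation `d = 0..max_dev`, the fraction of hairpins whose
#' rank-1 candidate deviates from the true site by exactly `d` nt (first
#' row), and the same using the minimum deviation among the top `top_k`
#' candidates (second row); the `Total` column is the fraction within
#' `max_dev`. APD is reported for the rank-1 candidate and for the best of
#' the top `top_k`.
#'
#' @param ranked Data frame of ranked predictions with columns `pre_id`,
#'   `anchor`, `rank`.
#' @param truths Named vector of true anchors, indexed by `pre_id`.
#' @param max_dev Largest tabulated deviation (default 5).
#' @param top_k Candidates considered for the top-k row (default 5).
#' @return Object of class `evaluation_report`: `table` (2 x (max_dev+2)
#'   matrix), `apd_first`, `apd_topk`, `n`.
#' @export
deviation_table <- function(ranked, truths, max_dev = 5L, top_k = 5L) {
  dv <- rank_deviations(ranked, truths, top_k)
  n <- length(dv$first)
  row_of <- function(devs) {
    cells <- vapply(0:max_dev, function(d) mean(devs == d), numeric(1))
    c(cells, Total = sum(cells))
  }
  tab <- rbind(first = row_of(dv$first), topk = row_of(dv$topk))
  colnames(tab) <- c(paste0("pm", 0:max_dev, "nt"), "Total")
  rownames(tab) <- c("first_candidate", paste0("top", top_k, "_candidates"))
  structure(list(table = tab, apd_first = mean(dv$first),
                 apd_topk = mean(dv$topk), n = n,
                 max_dev = max_dev, top_k = top_k,
                 deviations = dv),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n = ", x$n, " hairpins\n", sep = "")
  print(round(x$table, 4))
  cat("APD (first candidate): ", round(x$apd_first, 3), " nt; APD (best of top ",
      x$top_k, "): ", round(x$apd_topk, 3), " nt\n", sep = "")
  invisible(x)
}

#' Accuracy stratified by absence information
#'
#' Bins hairpins by the whole-duplex count of `-` symbols (0-2, 3-5, 6-8,
#' 9-11, 12+) and reports exact first-candidate and top-k accuracy per
#' populated bin; empty bins are absent from the output.
#'
#' @param ranked,truths As in [deviation_table()].
#' @param duplexes Named list of `duplex_alignment`s (before padding or
#'   after — padding contributes no `-`).
#' @param top_k Candidates for the top-k accuracy.
#' @return Data frame with columns `bin`, `n`, `acc_first`, `acc_topk`.
#' @export
stratify_by_absence <- function(ranked, truths, duplexes, top_k = 5L) {
  dv <- rank_deviations(ranked, truths, top_k)
  ids <- names(dv$first)
  absence <- vapply(ids, function(id)
    count_absence(NULL, duplexes[[id]], "whole"), numeric(1))
  bin <- cut(absence, breaks = c(-0.5, 2.5, 5.5, 8.5, 11.5, Inf),
             labels = c("0-2", "3-5", "6-8", "9-11", "12+"))
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    in_bin <- bin == b
    if (!any(in_bin)) return(NULL)
    data.frame(bin = b, n = sum(in_bin),
               acc_first = mean(dv$first[in_bin] == 0),
               acc_topk = mean(dv$topk[in_bin] == 0))
  }))
  out
}
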