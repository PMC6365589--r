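# Feature extraction for candidate windows on the structured sequence.
#
# In "structured" mode the catalog has 101 features:
#   own-strand mono fractions over {A,C,G,U,-}                5
#   own-strand dinucleotide fractions (gap pairs pooled)     17
#   opposite-strand mono fractions over {A,C,G,U,-}           5
#   column-state fractions {paired, top/bottom bulge, iloop}  4
#   absence counts (window, 10 cols upstream, 10 downstream)  3
#   gap-run statistics (openings, max run, total) x 2 strands 6
#   anchor-local one-hot, offsets -2..+2, both strands       50
#   anchor-local pairing state, offsets -3..+3                7
#   anchor distance to terminal loop / stem base (columns)    2
#   window GC fraction                                        1
#   window pairing fraction                                   1
# "sequence_only" drops every '-'-dependent and pairing feature (45 left).

STRUCT_ALPHA <- c("A", "C", "G", "U", "-")
SEQ_ALPHA <- c("A", "C", "G", "U")

#' Feature catalog names
#'
#' @param mode `"structured"` or `"sequence_only"`.
#' @return Character vector of feature names, in matrix column order.
#' @export
feature_catalog <- function(mode = c("structured", "sequence_only")) {
  mode <- match.arg(mode)
  sym <- function(s) ifelse(s == "-", "gap", s)
  if (mode == "structured") {
    dinuc <- as.vector(outer(SEQ_ALPHA, SEQ_ALPHA, function(a, b) paste0(a, b)))
    c(paste0("own_frac_", sym(STRUCT_ALPHA)),
      paste0("own_dinuc_", dinuc), "own_dinuc_gap",
      paste0("opp_frac_", sym(STRUCT_ALPHA)),
      paste0("state_frac_", c("paired", "top_bulge", "bottom_bulge", "internal_loop")),
      paste0("absence_", c("window", "upstream10", "downstream10")),
      paste0("gap_", c("openings", "maxrun", "total")) |>
        outer(c("own", "opp"), FUN = function(a, b) paste0(b, "_", a)) |> as.vector(),
      as.vector(outer(STRUCT_ALPHA, -2:2, function(s, o)
        paste0("own_at_", ifelse(o < 0, paste0("m", -o), paste0("p", o)), "_", sym(s)))),
      as.vector(outer(STRUCT_ALPHA, -2:2, function(s, o)
        paste0("opp_at_", ifelse(o < 0, paste0("m", -o), paste0("p", o)), "_", sym(s)))),
      paste0("paired_at_", c("m3", "m2", "m1", "p0", "p1", "p2", "p3")),
      c("dist_to_loop", "dist_to_base"),
      "gc_fraction", "pairing_fraction")
  } else {
    dinuc <- as.vector(outer(SEQ_ALPHA, SEQ_ALPHA, function(a, b) paste0(a, b)))
    c(paste0("own_frac_", SEQ_ALPHA),
      paste0("own_dinuc_", dinuc),
      paste0("opp_frac_", SEQ_ALPHA),
      as.vector(outer(SEQ_ALPHA, -2:2, function(s, o)
        paste0("own_at_", ifelse(o < 0, paste0("m", -o), paste0("p", o)), "_", s))),
      "gc_fraction")
  }
}

# Oriented view of the alignment for one arm: column indices ordered along
# the arm 5'->3' (ascending columns for the 5' arm, descending for the 3').
# Offsets past the loop-side end are filled from the terminal-loop sequence
# (virtual unpaired columns); past the base-side end is an error (the stem
# padding already supplies that context in the actual columns).
oriented_view <- function(d, arm) {
  nc <- length(d$top)
  ord <- if (arm == "5p") seq_len(nc) else rev(seq_len(nc))
  own <- if (arm == "5p") d$top[ord] else d$bottom[ord]
  opp <- if (arm == "5p") d$bottom[ord] else d$top[ord]
  own_idx <- if (arm == "5p") d$top_index[ord] else d$bottom_index[ord]
  list(nc = nc, ord = ord, own = own, opp = opp, own_idx = own_idx,
       paired = d$paired[ord], state = d$state[ord],
       loop = strsplit(d$loop_seq, "", fixed = TRUE)[[1]], arm = arm)
}

# Column symbols at oriented position k, with terminal-loop fill.
# For the 5' arm k > nc steps into the loop from its 5' side; for the 3'
# arm the reversal puts the loop at k > nc as well (one step past the
# column nearest the loop).
view_col <- function(v, k) {
  if (k >= 1 && k <= v$nc) {
    return(list(own = v$own[k], opp = v$opp[k], paired = v$paired[k]))
  }
  if (k < 1)
    stop("anchor-local offset runs past the stem base beyond the padding")
  r <- k - v$nc
  L <- length(v$loop)
  if (r > L)
    stop("anchor-local offset runs past the terminal loop (loop length ", L, ")")
  if (v$arm == "5p")
    list(own = v$loop[r], opp = v$loop[L + 1L - r], paired = FALSE)
  else
    list(own = v$loop[L + 1L - r], opp = v$loop[r], paired = FALSE)
}

frac_table <- function(symbols, alphabet) {
  n <- length(symbols)
  counts <- vapply(alphabet, function(a) sum(symbols == a), numeric(1))
  if (n == 0) counts else counts / n
}

gap_run_stats <- function(symbols) {
  r <- rle(symbols == "-")
  runs <- r$lengths[r$values]
  c(openings = length(runs),
    maxrun = if (length(runs)) max(runs) else 0,
    total = sum(runs))
}

#' Count absence information ('-' symbols) in a duplex region
#'
#' @param cand One candidate row (as produced by [enumerate_candidates()]),
#'   or `NULL` for `region = "whole"`.
#' @param d The `duplex_alignment`.
#' @param region `"window"`, `"upstream10"` (10 columns on the stem-base
#'   side of the window), `"downstream10"` (10 columns on the loop side),
#'   or `"whole"`.
#' @return Integer count of `-` symbols over both strands.
#' @export
count_absence <- function(cand, d, region = c("window", "upstream10",
                                              "downstream10", "whole")) {
  region <- match.arg(region)
  nc <- length(d$top)
  if (region == "whole") {
    cols <- seq_len(nc)
  } else {
    stopifnot(!is.null(cand))
    lo <- cand$col_lo; hi <- cand$col_hi
    cols <- switch(region,
      window = lo:hi,
      upstream10 = if (lo > 1L) seq.int(max(1L, lo - 10L), lo - 1L) else integer(0),
      downstream10 = if (hi < nc) seq.int(hi + 1L, min(nc, hi + 10L)) else integer(0))
  }
  sum(d$top[cols] == "-") + sum(d$bottom[cols] == "-")
}

#' Extract the feature vector of one candidate window
#'
#' @param cand One row of the candidate table from [enumerate_candidates()].
#' @param d The matching `duplex_alignment` (normally stem-extended so the
#'   anchor-local offsets near the base fall on padding columns).
#' @param mode `"structured"` (default) or `"sequence_only"` (ablation
#'   without absence/pairing information).
#' @return Named numeric vector matching [feature_catalog()].
#' @export
extract_features <- function(cand, d, mode = c("structured", "sequence_only")) {
  mode <- match.arg(mode)
  arm <- site_arm(cand$site_type)
  v <- oriented_view(d, arm)
  span_actual <- cand$col_lo:cand$col_hi
  # oriented positions of the span (contiguous either way)
  pos <- match(span_actual, v$ord)
  pos <- sort(pos)
  own_sp <- v$own[pos]; opp_sp <- v$opp[pos]
  own_nt <- own_sp[own_sp != "-"]
  anchor_pos <- pos[which(v$own_idx[pos] == cand$anchor)]
  anchor_col_actual <- v$ord[anchor_pos]
  nc <- v$nc

  gc <- mean(own_nt %in% c("G", "C"))

  onehot <- function(sym, alphabet) as.numeric(alphabet == sym)

  if (mode == "structured") {
    dinuc_pairs <- paste0(own_sp[-length(own_sp)], own_sp[-1])
    dinuc_names <- as.vector(outer(SEQ_ALPHA, SEQ_ALPHA, function(a, b) paste0(a, b)))
    ndn <- length(dinuc_pairs)
    dinuc_frac <- vapply(dinuc_names, function(p) sum(dinuc_pairs == p) / ndn, numeric(1))
    dinuc_gap <- sum(grepl("-", dinuc_pairs, fixed = TRUE)) / ndn
    states <- v$state[pos]
    state_frac <- vapply(c("paired", "top_bulge", "bottom_bulge", "internal_loop"),
                         function(s) mean(states == s), numeric(1))
    absence <- c(count_absence(cand, d, "window"),
                 count_absence(cand, d, "upstream10"),
                 count_absence(cand, d, "downstream10"))
    gaps <- c(gap_run_stats(own_sp), gap_run_stats(opp_sp))
    loc_own <- unlist(lapply(-2:2, function(o)
      onehot(view_col(v, anchor_pos + o)$own, STRUCT_ALPHA)))
    loc_opp <- unlist(lapply(-2:2, function(o)
      onehot(view_col(v, anchor_pos + o)$opp, STRUCT_ALPHA)))
    loc_pair <- vapply(-3:3, function(o)
      as.numeric(view_col(v, anchor_pos + o)$paired), numeric(1))
    vals <- c(frac_table(own_sp, STRUCT_ALPHA),
              dinuc_frac, dinuc_gap,
              frac_table(opp_sp, STRUCT_ALPHA),
              state_frac, absence, gaps,
              loc_own, loc_opp, loc_pair,
              nc - anchor_col_actual, anchor_col_actual - 1,
              gc, mean(v$paired[pos]))
  } else {
    dinuc_pairs <- paste0(own_nt[-length(own_nt)], own_nt[-1])
    dinuc_names <- as.vector(outer(SEQ_ALPHA, SEQ_ALPHA, function(a, b) paste0(a, b)))
    ndn <- length(dinuc_pairs)
    dinuc_frac <- vapply(dinuc_names, function(p) sum(dinuc_pairs == p) / ndn, numeric(1))
    opp_nt <- opp_sp[opp_sp != "-"]
    # anchor-local nucleotides along the ungapped own arm (padding and loop
    # supply flanking sequence context)
    nongap <- which(v$own != "-")
    a_idx <- match(anchor_pos, nongap)
    loc_own <- unlist(lapply(-2:2, function(o) {
      k <- a_idx + o
      s <- if (k >= 1 && k <= length(nongap)) v$own[nongap[k]]
           else view_col(v, v$nc + (k - length(nongap)))$own
      onehot(s, SEQ_ALPHA)
    }))
    vals <- c(frac_table(own_nt, SEQ_ALPHA),
              dinuc_frac,
              frac_table(opp_nt, SEQ_ALPHA),
              loc_own, gc)
  }
  names(vals) <- feature_catalog(mode)
  vals
}

#' Build the feature matrix for a candidate table
#'
#' Rows are ordered deterministically by (`pre_id`, `anchor`).
#'
#' @param candidates Candidate table (rows from [enumerate_candidates()],
#'   possibly several records concatenated).
#' @param duplexes Named list of `duplex_alignment` objects, indexed by
#'   `pre_id`.
#' @param mode Passed to [extract_features()].
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, one row per candidate), `labels` (+1/-1), `pre_id`, `anchor`,
#'   `catalog`, `mode`, `site_type`.
#' @export
build_matrix <- function(candidates, duplexes, mode = c("structured", "sequence_only")) {
  mode <- match.arg(mode)
  ord <- order(candidates$pre_id, candidates$anchor)
  candidates <- candidates[ord, , drop = FALSE]
  catalog <- feature_catalog(mode)
  x <- matrix(NA_real_, nrow = nrow(candidates), ncol = length(catalog),
              dimnames = list(NULL, catalog))
  for (r in seq_len(nrow(candidates))) {
    cand <- candidates[r, ]
    d <- duplexes[[cand$pre_id]]
    if (is.null(d)) stop("no duplex alignment for record '", cand$pre_id, "'")
    x[r, ] <- extract_features(cand, d, mode)
  }
  if (!all(is.finite(x))) stop("non-finite feature values")
  structure(list(x = x, labels = candidates$label, pre_id = candidates$pre_id,
                 anchor = candidates$anchor, catalog = catalog, mode = mode,
                 site_type = unique(candidates$site_type)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " candidates x ", ncol(x$x),
      " features (", x$mode, "), ", sum(x$labels == 1L), " positive\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' Columns: `pre_id`, `anchor`, the feature catalog, `label`.
#'
#' @param m A `feature_matrix`.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(pre_id = m$pre_id, anchor = m$anchor, m$x,
                   label = m$labels, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
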