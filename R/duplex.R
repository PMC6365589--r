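# The "structured sequence": a gapped two-strand alignment of the hairpin
# stem. Each column holds the 5'-arm symbol (top), the 3'-arm symbol
# (bottom, written 3'->5' so that base-paired partners share a column), and
# the pairing state. '-' marks a nucleotide absent from one strand because
# of a bulge or internal loop ("absence information").

#' Build the duplex alignment of a single-stem hairpin
#'
#' Walks the pair table from the stem base to the terminal loop. Paired
#' positions share a column; a 5'-arm bulged nucleotide gets a column with
#' bottom `-`; a 3'-arm bulged nucleotide a column with top `-`. Internal
#' loops emit the 5'-side block of columns first, then the 3'-side block.
#' The terminal loop is not columnized; its sequence is retained on the
#' object as window-external context.
#'
#' @param pre A [pre_mirna()] record (multibranch structures are rejected).
#' @return An object of class `duplex_alignment` with per-column vectors
#'   `top`, `bottom`, `paired`, `state`, the arm coordinate maps
#'   `top_index`/`bottom_index` (NA on gaps and padding), the padding count
#'   `n_pad`, and the terminal-loop sequence `loop_seq`.
#' @export
build_duplex <- function(pre) {
  pt <- pair_table(pre$dotbracket)
  if (!any(pt > 0)) stop("record '", pre$id, "': structure has zero base pairs")
  if (has_multibranch(pre$dotbracket))
    stop("record '", pre$id, "': multibranch structure; exclude before alignment")
  chars <- strsplit(pre$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  lp <- terminal_loop(pt)
  loop_lo <- lp[1] + 1L
  loop_hi <- lp[2] - 1L
  loop_seq <- if (loop_hi >= loop_lo) paste(chars[loop_lo:loop_hi], collapse = "") else ""
  arm5_len <- lp[1]                 # 5' arm = 1 .. innermost 5' paired nt
  arm3_len <- n - lp[2] + 1L        # 3' arm = innermost 3' paired nt .. n
  loop_end <- lp[2] - 1L            # rel index of 3'-arm nt at pos p: p - loop_end

  top <- character(0); bottom <- character(0); paired <- logical(0)
  top_index <- integer(0); bottom_index <- integer(0)
  i <- 1L; j <- n
  while (i <= lp[1] && j >= lp[2]) {
    if (pt[i] == j) {
      top <- c(top, chars[i]); bottom <- c(bottom, chars[j])
      paired <- c(paired, TRUE)
      top_index <- c(top_index, i); bottom_index <- c(bottom_index, j - loop_end)
      i <- i + 1L; j <- j - 1L
    } else if (pt[i] == 0L) {
      top <- c(top, chars[i]); bottom <- c(bottom, "-")
      paired <- c(paired, FALSE)
      top_index <- c(top_index, i); bottom_index <- c(bottom_index, NA_integer_)
      i <- i + 1L
    } else if (pt[j] == 0L) {
      top <- c(top, "-"); bottom <- c(bottom, chars[j])
      paired <- c(paired, FALSE)
      top_index <- c(top_index, NA_integer_); bottom_index <- c(bottom_index, j - loop_end)
      j <- j - 1L
    } else {
      stop("record '", pre$id, "': inconsistent pairing at (", i, ",", j,
           "); not a single stem")
    }
  }
  d <- structure(list(pre_id = pre$id,
                      top = top, bottom = bottom, paired = paired,
                      top_index = top_index, bottom_index = bottom_index,
                      n_pad = 0L, loop_seq = loop_seq,
                      arm5_len = arm5_len, arm3_len = arm3_len),
                 class = "duplex_alignment")
  d$state <- column_states(d)
  d
}

# Classify each column: paired / top_bulge (unpaired nt on the 5' strand) /
# bottom_bulge (unpaired nt on the 3' strand) / internal_loop (run of
# unpaired columns with nucleotides on both strands).
column_states <- function(d) {
  nc <- length(d$top)
  state <- ifelse(d$paired, "paired",
                  ifelse(d$bottom == "-", "top_bulge", "bottom_bulge"))
  if (nc == 0L) return(character(0))
  runs <- rle(d$paired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) {
      idx <- starts[k]:ends[k]
      if (any(d$bottom[idx] == "-") && any(d$top[idx] == "-"))
        state[idx] <- "internal_loop"
    }
  }
  state
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("<duplex_alignment> ", x$pre_id, ": ", length(x$top), " columns (",
      x$n_pad, " padding), arms ", x$arm5_len, "/", x$arm3_len,
      " nt, loop ", nchar(x$loop_seq), " nt\n", sep = "")
  invisible(x)
}

#' Render a duplex alignment as a three-line text block
#'
#' Top strand, a pairing row of `|`/` `, and the bottom strand, for visual
#' inspection.
#'
#' @param d A `duplex_alignment`.
#' @return Character vector of three lines.
#' @export
duplex_text <- function(d) {
  c(paste(d$top, collapse = ""),
    paste(ifelse(d$paired, "|", " "), collapse = ""),
    paste(d$bottom, collapse = ""))
}

#' Extend the stem base with artificial perfectly-paired columns
#'
#' Prepends `n` paired columns at the stem base, alternating G-C with C-G
#' pairs. Padding columns map to no arm coordinate and are never candidate
#' anchors; they supply flanking context for windows and anchor-local
#' features near the stem base.
#'
#' @param d A `duplex_alignment`.
#' @param n Number of padding pairs (default 10).
#' @return The extended `duplex_alignment` with `n_pad` incremented by `n`.
#' @export
extend_stem <- function(d, n = 10L) {
  stopifnot(inherits(d, "duplex_alignment"), n >= 0L)
  if (n == 0L) return(d)
  odd <- seq_len(n) %% 2L == 1L
  pad_top <- ifelse(odd, "G", "C")
  pad_bottom <- ifelse(odd, "C", "G")
  d$top <- c(pad_top, d$top)
  d$bottom <- c(pad_bottom, d$bottom)
  d$paired <- c(rep(TRUE, n), d$paired)
  d$state <- c(rep("paired", n), d$state)
  d$top_index <- c(rep(NA_integer_, n), d$top_index)
  d$bottom_index <- c(rep(NA_integer_, n), d$bottom_index)
  d$n_pad <- d$n_pad + as.integer(n)
  d
}

#' Ungapped arm sequences recovered from a duplex alignment
#'
#' @param d A `duplex_alignment`.
#' @return List with `arm5` (5'->3') and `arm3` (5'->3') sequences;
#'   padding columns are excluded via the arm coordinate maps.
#' @export
ungap_duplex <- function(d) {
  top <- d$top[!is.na(d$top_index)]
  bottom <- d$bottom[!is.na(d$bottom_index)]
  list(arm5 = paste(top, collapse = ""),
       arm3 = paste(rev(bottom), collapse = ""))
}

# first mature annotation on the given arm; message if several
arm_annotation <- function(pre, arm) {
  if (is.null(pre$matures)) return(NULL)
  rows <- pre$matures[pre$matures$arm == arm, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  if (nrow(rows) > 1L)
    message("record '", pre$id, "': ", nrow(rows), " matures on the ", arm,
            " arm; using the first")
  rows[1L, ]
}

#' Enumerate candidate processing-site windows
#'
#' Slides a fixed-length window along the arm addressed by `site_type`.
#' Start-site types (`P5_5`, `P3_5`) anchor the window at its 5' end
#' (arm positions `a .. a+window-1`); end-site types (`P5_3`, `P3_3`) at
#' its 3' end (`a-window+1 .. a`). Arm positions are read 5'->3' along the
#' arm; windows never cross the terminal loop, and padding columns are not
#' valid anchors. The candidate matching the annotated mature start (for
#' `*_5`) or end (for `*_3`) is labelled `+1`, all others `-1`.
#'
#' @param d `duplex_alignment` of `pre` (extended or not).
#' @param pre The [pre_mirna()] record.
#' @param site_type One of `"P5_5"`, `"P5_3"`, `"P3_5"`, `"P3_3"`.
#' @param window Window length in nucleotides (default 22).
#' @return Data frame with columns `pre_id`, `site_type`, `anchor` (1-based
#'   arm coordinate), `col_lo`, `col_hi` (alignment column span), `label`.
#'   Zero rows (with a warning) if the record is annotated but its true
#'   site admits no window.
#' @export
enumerate_candidates <- function(d, pre, site_type, window = 22L) {
  site_type <- match.arg(site_type, c("P5_5", "P5_3", "P3_5", "P3_3"))
  arm <- site_arm(site_type)
  own <- if (arm == "5p") d$top_index else d$bottom_index
  arm_len <- if (arm == "5p") d$arm5_len else d$arm3_len
  is_start <- site_type %in% c("P5_5", "P3_5")
  if (arm_len < window) {
    warning("record '", pre$id, "': ", arm, " arm (", arm_len,
            " nt) shorter than the ", window, "-nt window; skipped")
    return(empty_candidates())
  }
  anchors <- if (is_start) seq_len(arm_len - window + 1L)
             else seq.int(window, arm_len)
  ann <- arm_annotation(pre, arm)
  true_anchor <- NA_integer_
  if (!is.null(ann)) {
    pos <- if (grepl("_5$", site_type)) ann$start else ann$end
    true_anchor <- if (arm == "5p") as.integer(pos)
                   else as.integer(pos - (nchar(pre$sequence) - d$arm3_len))
    if (!true_anchor %in% anchors) {
      warning("record '", pre$id, "': annotated ", site_type, " site (arm pos ",
              true_anchor, ") admits no ", window, "-nt window; skipped")
      return(empty_candidates())
    }
  }
  lo <- if (is_start) anchors else anchors - window + 1L
  hi <- if (is_start) anchors + window - 1L else anchors
  col_of <- function(a) {
    cols <- which(!is.na(own) & own >= lo[a] & own <= hi[a])
    c(min(cols), max(cols))
  }
  spans <- vapply(seq_along(anchors), col_of, integer(2))
  data.frame(pre_id = pre$id, site_type = site_type, anchor = anchors,
             col_lo = spans[1, ], col_hi = spans[2, ],
             label = ifelse(!is.na(true_anchor) & anchors == true_anchor, 1L, -1L),
             stringsAsFactors = FALSE)
}

empty_candidates <- function() {
  data.frame(pre_id = character(0), site_type = character(0),
             anchor = integer(0), col_lo = integer(0), col_hi = integer(0),
             label = integer(0), stringsAsFactors = FALSE)
}
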