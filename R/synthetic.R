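# Seeded synthetic hairpin generator: self-consistent sequence/dot-bracket
# pairs built column-by-column (no folding engine needed), controllable
# bulge density, and a plantable sequence/structure signal at the true
# processing sites. Stands in for real precursor data in tests and
# benchmarks; it emulates stem-loop geometry and bulge statistics, not
# thermodynamics or genomic base composition.

RNA_BASES <- c("A", "C", "G", "U")
WC <- c(A = "U", U = "A", G = "C", C = "G")

#' Specification for the synthetic hairpin generator
#'
#' @param n_hairpins Number of hairpins per dataset.
#' @param arm_length Range (min, max) of the annotated arm length in nt;
#'   minimum 30 so 22-nt windows exist with slack.
#' @param bulge_rate Per-column probability of emitting a single-strand
#'   bulge column instead of a base pair.
#' @param loop_length Range of terminal-loop lengths.
#' @param signal_strength Probability, per motif position, that the planted
#'   signal (motif nucleotide + suppressed bulge) is enforced.
#' @param motif_start,motif_end 5-nt motifs planted at offsets -2..+2
#'   around the true mature start and end.
#' @param arm Arm carrying the mature (`"5p"` or `"3p"`).
#' @param gu_rate Fraction of paired columns drawn as G-U wobbles.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_hairpins = 100L, arm_length = c(36L, 44L),
                           bulge_rate = 0.08, loop_length = c(8L, 12L),
                           signal_strength = 0.9,
                           motif_start = "GCUAG", motif_end = "CAGUC",
                           arm = c("5p", "3p"), gu_rate = 0.1) {
  arm <- match.arg(arm)
  stopifnot(arm_length[1] >= 30L, arm_length[2] >= arm_length[1],
            bulge_rate >= 0, bulge_rate < 1,
            signal_strength >= 0, signal_strength <= 1,
            loop_length[1] >= 3L, loop_length[2] >= loop_length[1],
            nchar(motif_start) == 5L, nchar(motif_end) == 5L)
  structure(list(n_hairpins = as.integer(n_hairpins),
                 arm_length = as.integer(arm_length),
                 bulge_rate = bulge_rate,
                 loop_length = as.integer(loop_length),
                 signal_strength = signal_strength,
                 motif_start = strsplit(toupper(motif_start), "")[[1]],
                 motif_end = strsplit(toupper(motif_end), "")[[1]],
                 arm = arm, gu_rate = gu_rate),
            class = "synthetic_spec")
}

# paired partner of `top`, GU wobble with probability gu_rate where possible
partner_of <- function(top, gu_rate) {
  if (top %in% c("G", "U") && runif(1) < gu_rate)
    return(if (top == "G") "U" else "G")
  WC[[top]]
}

#' Generate one synthetic hairpin
#'
#' The duplex is built column by column from stem base to loop: with
#' probability `1 - bulge_rate` a complementary pair (Watson-Crick, with
#' G-U wobbles at `gu_rate`), otherwise a bulge on a random strand. A true
#' mature interval of 22 nt is placed uniformly on the annotated arm; with
#' probability `signal_strength` per position, motif nucleotides are
#' written at offsets -2..+2 around its start and end and bulges there are
#' suppressed. For `arm = "3p"` the finished duplex is strand-flipped, so
#' the planted motifs appear mirrored on the 3' arm.
#'
#' Uses the current RNG stream; seed with `set.seed()` or via
#' [generate_dataset()].
#'
#' @param spec A [synthetic_spec()].
#' @param id Record identifier.
#' @return A [pre_mirna()] record with one mature annotation.
#' @export
generate_hairpin <- function(spec, id = "synth") {
  L <- sample(seq.int(spec$arm_length[1], spec$arm_length[2]), 1L)
  loop_len <- sample(seq.int(spec$loop_length[1], spec$loop_length[2]), 1L)
  m_start <- sample(seq.int(3L, L - 23L), 1L)
  m_end <- m_start + 21L
  motif_at <- integer(0)
  motif_sym <- character(0)
  for (o in -2:2) {
    motif_at <- c(motif_at, m_start + o, m_end + o)
    motif_sym <- c(motif_sym, spec$motif_start[o + 3L], spec$motif_end[o + 3L])
  }
  planted <- runif(length(motif_at)) < spec$signal_strength
  sym_of <- function(p) {
    hit <- which(motif_at == p & planted)
    if (length(hit)) motif_sym[hit[1L]] else sample(RNA_BASES, 1L)
  }
  protect <- motif_at[planted]
  top <- character(0); bottom <- character(0); paired <- logical(0)
  p <- 1L
  while (p <= L) {
    protected <- p %in% protect
    if (!protected && runif(1) < spec$bulge_rate) {
      if (runif(1) < 0.5) {           # bulge on the annotated (top) strand
        top <- c(top, sym_of(p)); bottom <- c(bottom, "-")
        paired <- c(paired, FALSE)
        p <- p + 1L
      } else {                        # bulge on the opposite strand
        top <- c(top, "-"); bottom <- c(bottom, sample(RNA_BASES, 1L))
        paired <- c(paired, FALSE)
      }
    } else {
      nt <- sym_of(p)
      top <- c(top, nt); bottom <- c(bottom, partner_of(nt, spec$gu_rate))
      paired <- c(paired, TRUE)
      p <- p + 1L
    }
  }
  loop <- sample(RNA_BASES, loop_len, replace = TRUE)
  if (spec$arm == "3p") {             # strand flip: mature moves to the 3' arm
    tmp <- top; top <- bottom; bottom <- tmp
    L3 <- sum(bottom != "-")
    arm5 <- top[top != "-"]
    rel_start <- L3 - m_end + 1L      # positions mirror under the flip
    m_start_full <- length(arm5) + loop_len + rel_start
    m_end_full <- m_start_full + 21L
  } else {
    arm5 <- top[top != "-"]
    m_start_full <- m_start
    m_end_full <- m_end
  }
  arm3 <- rev(bottom[bottom != "-"])
  sequence <- paste(c(arm5, loop, arm3), collapse = "")
  db5 <- ifelse(paired[top != "-"], "(", ".")
  db3 <- rev(ifelse(paired[bottom != "-"], ")", "."))
  dotbracket <- paste(c(db5, rep(".", loop_len), db3), collapse = "")
  pre_mirna(id, sequence, dotbracket,
            matures = data.frame(arm = spec$arm, start = m_start_full,
                                 end = m_end_full))
}

#' Generate a synthetic dataset (records and interface files)
#'
#' Writes the three files the real pipeline consumes: FASTA sequences,
#' RNAfold-style structures, and the mature-annotation TSV.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; generation is bit-reproducible.
#' @param dir Output directory, or `NULL` to skip writing files.
#' @return List with `records` (list of [pre_mirna()]) and `paths`
#'   (named file paths, if written).
#' @export
generate_dataset <- function(spec, seed = 1L, dir = NULL) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ids <- sprintf("synth_%04d", seq_len(spec$n_hairpins))
  records <- lapply(ids, function(id) generate_hairpin(spec, id))
  names(records) <- ids
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    seqs <- vapply(records, function(r) r$sequence, character(1))
    structs <- vapply(records, function(r) r$dotbracket, character(1))
    ann <- do.call(rbind, lapply(records, function(r)
      data.frame(id = r$id, arm = r$matures$arm, start = r$matures$start,
                 end = r$matures$end)))
    paths <- c(fasta = file.path(dir, "hairpins.fa"),
               fold = file.path(dir, "hairpins.fold"),
               annot = file.path(dir, "matures.tsv"))
    write_fasta(seqs, paths[["fasta"]])
    write_vienna_fold(seqs, structs, paths[["fold"]])
    write.table(ann, paths[["annot"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(records = records, paths = paths)
}
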