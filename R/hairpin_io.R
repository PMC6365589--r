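# Reading/writing hairpin sequences, secondary structures and mature
# annotations; arm assignment and train/test splitting.
#
# Coordinates are 1-based inclusive everywhere (miRBase convention), both at
# file interfaces and internally.

#' Construct a pre-miRNA record
#'
#' Bundles a precursor sequence, its secondary structure in Vienna
#' dot-bracket notation, and zero or more mature-miRNA annotations.
#'
#' @param id Record identifier.
#' @param sequence RNA sequence over `A,C,G,U` (DNA input is converted).
#' @param dotbracket Dot-bracket structure string of the same length.
#' @param matures `NULL` or a data frame with columns `start`, `end`
#'   (1-based inclusive) and optionally `arm` (`"5p"` or `"3p"`).
#' @return An object of class `pre_mirna`.
#' @export
pre_mirna <- function(id, sequence, dotbracket, matures = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_rna(sequence)
  if (nchar(dotbracket) != nchar(sequence))
    stop("record '", id, "': structure length (", nchar(dotbracket),
         ") != sequence length (", nchar(sequence), ")")
  pair_table(dotbracket)  # validates balance and alphabet
  if (!is.null(matures)) {
    matures <- as.data.frame(matures)
    stopifnot(all(c("start", "end") %in% names(matures)))
    n <- nchar(sequence)
    bad <- matures$start < 1 | matures$end > n | matures$start > matures$end
    if (any(bad))
      stop("record '", id, "': mature interval outside [1, ", n, "]")
  }
  structure(list(id = id, sequence = sequence, dotbracket = dotbracket,
                 matures = matures),
            class = "pre_mirna")
}

#' @export
print.pre_mirna <- function(x, ...) {
  cat("<pre_mirna> ", x$id, " (", nchar(x$sequence), " nt, ",
      if (is.null(x$matures)) 0L else nrow(x$matures), " mature annotation(s))\n",
      sep = "")
  invisible(x)
}

normalize_rna <- function(x) {
  x <- chartr("t", "u", tolower(x))
  x <- toupper(x)
  if (grepl("[^ACGU]", x))
    stop("sequence contains characters outside the RNA alphabet: ",
         gsub("[ACGU]", "", x))
  x
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and `T` is mapped to `U`; record order is
#' preserved. Duplicate identifiers and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(duplicated(ids)))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  seqs <- vapply(seqs, normalize_rna, character(1), USE.NAMES = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read secondary structures from RNAfold-style text output
#'
#' Expects records of the form header line (`>id`), sequence line, then a
#' structure line optionally suffixed by the folding energy in parentheses,
#' e.g. `"((..)) (-1.20)"`. The energy suffix is stripped.
#'
#' @param path Path to the fold file.
#' @return Named character vector mapping id to dot-bracket string.
#' @export
read_vienna_fold <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no records found in fold file '", path, "'")
  out <- character(0)
  for (k in seq_along(hdr)) {
    i <- hdr[k]
    last <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    if (last < i + 2L)
      stop("fold record '", lines[i], "': expected sequence and structure lines")
    id <- sub("\\s.*$", "", sub("^>", "", lines[i]))
    seq <- trimws(lines[i + 1L])
    struct <- trimws(lines[i + 2L])
    # strip trailing " (energy)" such as " (-25.40)"
    struct <- sub("\\s*\\([-+ 0-9.]+\\)\\s*$", "", struct)
    if (nchar(struct) != nchar(seq))
      stop("fold record '", id, "': structure length (", nchar(struct),
           ") != sequence length (", nchar(seq), ")")
    pair_table(struct)  # errors on unbalanced brackets
    if (id %in% names(out)) stop("duplicate fold id: ", id)
    out[id] <- struct
  }
  out
}

#' Write sequences and structures in RNAfold-style text format
#'
#' @param seqs Named character vector of sequences.
#' @param structs Named character vector of dot-bracket strings; names must
#'   match `seqs`.
#' @param path Output path.
#' @export
write_vienna_fold <- function(seqs, structs, path) {
  stopifnot(setequal(names(seqs), names(structs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(c(paste0(">", id), seqs[[id]], structs[[id]]), con)
  }
  invisible(path)
}

#' Pair table of a dot-bracket structure
#'
#' @param dotbracket Structure string over `( ) .`.
#' @return Integer vector `pt` with `pt[i] = j` if positions i and j pair,
#'   0 if unpaired.
#' @export
pair_table <- function(dotbracket) {
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (length(chars) && any(!chars %in% c("(", ")", ".")))
    stop("invalid dot-bracket characters: ",
         paste(unique(chars[!chars %in% c("(", ")", ".")]), collapse = ""))
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  pt
}

#' Does a structure contain a multibranch point?
#'
#' TRUE iff more than one helix emanates from any loop: i.e. some enclosing
#' pair (or the top level) contains two or more disjoint outermost-nested
#' bracket groups.
#'
#' @param dotbracket Dot-bracket string; must be balanced.
#' @return Logical scalar.
#' @export
has_multibranch <- function(dotbracket) {
  pt <- pair_table(dotbracket)
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  # children count per parent: parent -1 is the exterior loop
  children <- c(root = 0L)
  stack <- integer(0)  # open pair positions
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      parent <- if (length(stack)) as.character(stack[length(stack)]) else "root"
      children[parent] <- if (parent %in% names(children)) children[[parent]] + 1L else 1L
      children[as.character(i)] <- 0L
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      stack <- stack[-length(stack)]
    }
  }
  any(children >= 2L)
}

# innermost pair (ip, jp) of a single-stem hairpin; the terminal loop is
# (ip+1)..(jp-1)
terminal_loop <- function(pt) {
  pairs_i <- which(pt > seq_along(pt))
  if (length(pairs_i) == 0L) stop("structure has zero base pairs")
  ip <- max(pairs_i)
  c(ip, pt[ip])
}

#' Assign a mature annotation to the 5' or 3' arm
#'
#' The arm is `"5p"` if the mature midpoint precedes the terminal-loop
#' midpoint, `"3p"` if it follows. Matures straddling the loop midpoint are
#' rejected with an error (their candidate windows would cross the loop).
#'
#' @param pre A [pre_mirna()] record with a single-stem structure.
#' @param start,end Mature interval, 1-based inclusive.
#' @return `"5p"` or `"3p"`.
#' @export
assign_arm <- function(pre, start, end) {
  pt <- pair_table(pre$dotbracket)
  lp <- terminal_loop(pt)
  loop_mid <- (lp[1] + lp[2]) / 2
  if (start <= loop_mid && end >= loop_mid)
    stop("record '", pre$id, "': mature [", start, ",", end,
         "] straddles the terminal loop midpoint")
  if ((start + end) / 2 < loop_mid) "5p" else "3p"
}

#' Read a mature-annotation table
#'
#' Tab-separated with columns `id`, `start`, `end` and optionally `arm`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "start", "end") %in% names(df)))
  df
}

#' Load and assemble pre-miRNA records
#'
#' Joins sequences, structures and annotations by id; assigns each mature
#' annotation to an arm (computed from the structure when the table gives
#' none). Records with multibranch structures and annotations straddling
#' the terminal loop are dropped with a message.
#'
#' @param fasta,fold,annot File paths (FASTA, RNAfold text output,
#'   annotation TSV), or objects already read by the corresponding readers.
#' @return List of [pre_mirna()] records.
#' @export
load_hairpins <- function(fasta, fold, annot = NULL) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta(fasta) else fasta
  structs <- if (is.character(fold) && length(fold) == 1L && file.exists(fold))
    read_vienna_fold(fold) else fold
  ann <- if (is.null(annot)) NULL
         else if (is.data.frame(annot)) annot
         else read_annotations(annot)
  missing_struct <- setdiff(names(seqs), names(structs))
  if (length(missing_struct))
    stop("no structure for record(s): ", paste(missing_struct, collapse = ", "))
  out <- list()
  dropped <- character(0)
  for (id in names(seqs)) {
    db <- structs[[id]]
    if (has_multibranch(db)) {
      dropped <- c(dropped, id)
      next
    }
    mat <- NULL
    if (!is.null(ann)) {
      rows <- ann[ann$id == id, , drop = FALSE]
      if (nrow(rows)) {
        pre0 <- pre_mirna(id, seqs[[id]], db)
        arms <- character(nrow(rows))
        keep <- logical(nrow(rows))
        for (r in seq_len(nrow(rows))) {
          arms[r] <- tryCatch(assign_arm(pre0, rows$start[r], rows$end[r]),
                              error = function(e) NA_character_)
          keep[r] <- !is.na(arms[r])
        }
        if (any(!keep))
          message("record '", id, "': dropped ", sum(!keep),
                  " annotation(s) straddling the terminal loop")
        rows <- rows[keep, , drop = FALSE]
        if (nrow(rows)) {
          rows$arm <- arms[keep]
          mat <- rows[, c("arm", "start", "end")]
        }
      }
    }
    out[[id]] <- pre_mirna(id, seqs[[id]], db, mat)
  }
  if (length(dropped))
    message("excluded ", length(dropped), " multibranch record(s): ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  out
}

site_arm <- function(site_type) {
  switch(match.arg(site_type, c("P5_5", "P5_3", "P3_5", "P3_3")),
         P5_5 = "5p", P5_3 = "5p", P3_5 = "3p", P3_3 = "3p")
}

#' Split records into training and test sets
#'
#' Multibranch records are assumed already removed (by [load_hairpins()]).
#' Only records carrying at least one mature annotation on the arm matching
#' `site_type` are retained; the rest are dropped with a message.
#'
#' @param records List of [pre_mirna()] records.
#' @param site_type One of `"P5_5"`, `"P5_3"`, `"P3_5"`, `"P3_3"`.
#' @param test_fraction Fraction(s) of records per test set; a named vector
#'   produces several disjoint test sets.
#' @param seed Integer RNG seed; identical seeds give identical splits.
#' @return List with elements `train` (records), `test_sets` (named list of
#'   record lists) and `site_type`.
#' @export
build_splits <- function(records, site_type, test_fraction = 0.1, seed = 1L) {
  site_type <- match.arg(site_type, c("P5_5", "P5_3", "P3_5", "P3_3"))
  arm <- site_arm(site_type)
  eligible <- vapply(records, function(p) {
    !is.null(p$matures) && any(p$matures$arm == arm)
  }, logical(1))
  if (any(!eligible))
    message("dropped ", sum(!eligible), " record(s) without a ", arm,
            " mature annotation")
  records <- records[eligible]
  n <- length(records)
  sizes <- floor(n * test_fraction)
  if (is.null(names(sizes)))
    names(sizes) <- paste0("test", seq_along(sizes))
  if (sum(sizes) >= n)
    stop("test sets (", sum(sizes), " records) leave no training data (n = ", n, ")")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm <- sample.int(n)
  test_sets <- list()
  used <- 0L
  for (k in seq_along(sizes)) {
    idx <- perm[seq.int(used + 1L, used + sizes[k])]
    test_sets[[names(sizes)[k]]] <- records[idx]
    used <- used + sizes[k]
  }
  train <- records[perm[seq.int(used + 1L, n)]]
  list(train = train, test_sets = test_sets, site_type = site_type)
}

# Seed handling: set a reproducible seed without clobbering the caller's
# RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
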