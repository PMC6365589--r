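test_that("FASTA reading normalizes case and alphabet and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">b", "GU"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(x = "ACGU", b = "GU"))
})

test_that("FASTA reader rejects duplicate ids and empty sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GU"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(c(">a", "AC", ">empty", "", ">c", "GG"), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA and fold files round-trip exactly", {
  recs <- random_hairpins(5, seed = 31)
  seqs <- vapply(recs, function(r) r$sequence, character(1))
  structs <- vapply(recs, function(r) r$dotbracket, character(1))
  fa <- withr::local_tempfile(fileext = ".fa")
  fo <- withr::local_tempfile(fileext = ".fold")
  write_fasta(seqs, fa)
  write_vienna_fold(seqs, structs, fo)
  expect_identical(read_fasta(fa), seqs)
  expect_identical(read_vienna_fold(fo), structs)
})

test_that("fold parsing strips the energy suffix and checks lengths", {
  f <- withr::local_tempfile(fileext = ".fold")
  writeLines(c(">h1", "ACGGCU", "((..)) (-1.20)"), f)
  expect_identical(read_vienna_fold(f), c(h1 = "((..))"))
  writeLines(c(">h1", "ACGGCUA", "((..))"), f)
  expect_error(read_vienna_fold(f), "length")
  writeLines(c(">h1", "ACGGCU", "((..)("), f)
  expect_error(read_vienna_fold(f), "unbalanced")
})

test_that("pair_table maps partners and rejects unbalanced input", {
  expect_identical(pair_table("((..))"), c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_identical(pair_table("...."), rep(0L, 4))
  expect_error(pair_table("(()"), "unbalanced")
  expect_error(pair_table("ab"), "invalid")
})

test_that("multibranch detection handles canonical cases", {
  expect_false(has_multibranch("((((....))))"))
  expect_true(has_multibranch("((..))((..))"))
  # two sibling helices inside an enclosing pair
  expect_true(has_multibranch("((..((..))..((..))..))"))
  expect_false(has_multibranch("((..((....))..))"))
})

test_that("multibranch detection agrees with a brute-force loop-degree scan", {
  for (len in 2:8) {
    for (db in all_dotbrackets(len)) {
      expect_identical(has_multibranch(db), oracle_multibranch(db), info = db)
    }
  }
  set.seed(99)
  alph <- c("(", ")", ".")
  tried <- 0L
  while (tried < 300L) {
    db <- paste(sample(alph, 12, replace = TRUE), collapse = "")
    ok <- !inherits(try(pair_table(db), silent = TRUE), "try-error")
    if (!ok) next
    tried <- tried + 1L
    expect_identical(has_multibranch(db), oracle_multibranch(db), info = db)
  }
})

test_that("arm assignment follows the mature midpoint against the loop", {
  # 60-nt hairpin, loop at [28, 33]
  db <- paste0(strrep("(", 27), "......", strrep(")", 27))
  seq <- paste0(strrep("G", 27), "AAAAAA", strrep("C", 27))
  pre <- pre_mirna("h", seq, db)
  expect_identical(assign_arm(pre, 2, 10), "5p")
  expect_identical(assign_arm(pre, 40, 58), "3p")
  expect_error(assign_arm(pre, 25, 45), "straddles")
})

test_that("arm assignment is total over annotations of generated records", {
  recs <- random_hairpins(50, seed = 17)
  for (r in recs) {
    for (i in seq_len(nrow(r$matures))) {
      expect_identical(assign_arm(r, r$matures$start[i], r$matures$end[i]),
                       r$matures$arm[i])
    }
  }
})

test_that("load_hairpins drops multibranch records and joins annotations", {
  recs <- random_hairpins(4, seed = 5)
  seqs <- vapply(recs, function(r) r$sequence, character(1))
  structs <- vapply(recs, function(r) r$dotbracket, character(1))
  # corrupt one structure into a two-stem multibranch of the same length
  n1 <- nchar(seqs[[1]])
  half <- (n1 - n1 %% 2L) / 2L
  stem <- function(w) paste0(strrep("(", (w - 4) %/% 2), strrep(".", w - 2 * ((w - 4) %/% 2)), strrep(")", (w - 4) %/% 2))
  structs[[1]] <- paste0(stem(half), stem(n1 - half))
  ann <- do.call(rbind, lapply(recs, function(r)
    data.frame(id = r$id, start = r$matures$start, end = r$matures$end)))
  expect_message(out <- load_hairpins(seqs, structs, ann), "multibranch")
  expect_identical(length(out), 3L)
  expect_true(all(vapply(out, function(r) nrow(r$matures) == 1L, logical(1))))
  expect_identical(out[[1]]$matures$arm, "5p")
})

test_that("splits are disjoint, seeded, and sized as requested", {
  recs <- random_hairpins(40, seed = 23)
  s1 <- build_splits(recs, "P5_5", test_fraction = 0.5, seed = 9)
  expect_identical(length(s1$train), 20L)
  expect_identical(length(s1$test_sets$test1), 20L)
  ids <- function(x) vapply(x, function(r) r$id, character(1))
  expect_length(intersect(ids(s1$train), ids(s1$test_sets$test1)), 0L)
  s2 <- build_splits(recs, "P5_5", test_fraction = 0.5, seed = 9)
  expect_identical(ids(s1$train), ids(s2$train))
  expect_error(build_splits(recs, "P5_5", test_fraction = 1.0, seed = 9),
               "no training data")
})
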