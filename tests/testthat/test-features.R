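cand_of <- function(r, d, site_type = "P5_5", which = 1L) {
  cand <- enumerate_candidates(d, r, site_type)
  cand[which, , drop = FALSE]
}

test_that("the structured catalog has 101 features and vectors match it", {
  expect_length(feature_catalog("structured"), 101L)
  r <- random_hairpins(1, seed = 2)[[1]]
  d <- extend_stem(build_duplex(r), 10)
  fv <- extract_features(cand_of(r, d), d, "structured")
  expect_identical(names(fv), feature_catalog("structured"))
  expect_true(all(is.finite(fv)))
})

test_that("composition-fraction groups each sum to one", {
  recs <- random_hairpins(10, seed = 19, bulge_rate = 0.15)
  groups <- list(grep("^own_frac_", feature_catalog("structured")),
                 grep("^own_dinuc_", feature_catalog("structured")),
                 grep("^opp_frac_", feature_catalog("structured")),
                 grep("^state_frac_", feature_catalog("structured")))
  for (r in recs) {
    d <- extend_stem(build_duplex(r), 10)
    cand <- enumerate_candidates(d, r, "P5_5")
    for (k in c(1L, nrow(cand))) {
      fv <- extract_features(cand[k, ], d, "structured")
      for (g in groups) expect_equal(sum(fv[g]), 1, tolerance = 1e-9)
    }
  }
})

test_that("a fully paired gap-free window has zero absence and pairing fraction one", {
  pre <- pre_mirna("p", paste0(strrep("G", 30), "AAAA", strrep("C", 30)),
                   paste0(strrep("(", 30), "....", strrep(")", 30)))
  d <- extend_stem(build_duplex(pre), 10)
  stripped <- pre; stripped$matures <- NULL
  cand <- enumerate_candidates(d, stripped, "P5_5")[1, ]
  fv <- extract_features(cand, d, "structured")
  expect_identical(unname(fv[c("absence_window", "absence_upstream10",
                               "absence_downstream10")]), c(0, 0, 0))
  expect_identical(unname(fv["pairing_fraction"]), 1)
  expect_identical(unname(fv["own_gap_openings"]), 0)
})

test_that("gap-run statistics count openings, maximum and total length", {
  # one 2-column gap run on the top strand inside the window
  seq <- paste0(strrep("G", 10), strrep("A", 4), strrep("C", 12))
  db <- paste0(strrep("(", 10), "....", strrep(")", 10), "..")
  pre <- pre_mirna("g", seq, db)   # two 3'-dangling nts -> top-gap columns
  d <- build_duplex(pre)
  expect_identical(sum(d$top == "-"), 2L)
  expect_equal(unname(matsite:::gap_run_stats(d$top)), c(1, 2, 2))
})

test_that("composition features equal brute-force symbol counting", {
  recs <- random_hairpins(20, seed = 83, bulge_rate = 0.2)
  for (r in recs) {
    d <- extend_stem(build_duplex(r), 10)
    cand <- enumerate_candidates(d, r, "P5_5")
    k <- max(1L, nrow(cand) %/% 2L)
    cw <- cand[k, ]
    fv <- extract_features(cw, d, "structured")
    cols <- cw$col_lo:cw$col_hi
    for (s in c("A", "C", "G", "U", "-")) {
      nm <- paste0("own_frac_", if (s == "-") "gap" else s)
      expect_equal(unname(fv[nm]), sum(d$top[cols] == s) / length(cols))
      nm2 <- paste0("opp_frac_", if (s == "-") "gap" else s)
      expect_equal(unname(fv[nm2]), sum(d$bottom[cols] == s) / length(cols))
    }
    own_nt <- d$top[cols][d$top[cols] != "-"]
    expect_identical(length(own_nt), 22L)
    expect_equal(unname(fv["gc_fraction"]), mean(own_nt %in% c("G", "C")))
    expect_equal(unname(fv["pairing_fraction"]), mean(d$paired[cols]))
  }
})

test_that("absence counts respect regions and the report binning", {
  r <- random_hairpins(1, seed = 4, bulge_rate = 0.2)[[1]]
  d <- extend_stem(build_duplex(r), 10)
  whole <- count_absence(NULL, d, "whole")
  expect_identical(whole, sum(d$top == "-") + sum(d$bottom == "-"))
  cand <- enumerate_candidates(d, r, "P5_5")[1, ]
  up <- count_absence(cand, d, "upstream10")
  win <- count_absence(cand, d, "window")
  down <- count_absence(cand, d, "downstream10")
  expect_true(all(c(up, win, down) >= 0))
  expect_lte(win, whole)
})

test_that("feature matrices are deterministic with labels preserved", {
  recs <- random_hairpins(3, seed = 6)
  duplexes <- lapply(recs, function(r) extend_stem(build_duplex(r), 10))
  names(duplexes) <- names(recs)
  cands <- do.call(rbind, lapply(recs, function(r)
    enumerate_candidates(duplexes[[r$id]], r, "P5_5")))
  m1 <- build_matrix(cands, duplexes, "structured")
  m2 <- build_matrix(cands, duplexes, "structured")
  expect_identical(m1$x, m2$x)
  expect_identical(dim(m1$x), c(nrow(cands), 101L))
  expect_identical(sum(m1$labels == 1L), 3L)
})

test_that("sequence-only vectors project out all structure information", {
  r <- random_hairpins(1, seed = 21, bulge_rate = 0.15)[[1]]
  d <- extend_stem(build_duplex(r), 10)
  cand <- cand_of(r, d)
  fv <- extract_features(cand, d, "sequence_only")
  expect_identical(names(fv), feature_catalog("sequence_only"))
  expect_length(fv, 45L)
  expect_false(any(grepl("gap|paired|absence|state|dist", names(fv))))
  # its composition agrees with counting on the ungapped 22-nt window
  cols <- cand$col_lo:cand$col_hi
  own_nt <- d$top[cols][d$top[cols] != "-"]
  for (s in c("A", "C", "G", "U"))
    expect_equal(unname(fv[paste0("own_frac_", s)]), mean(own_nt == s))
})
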