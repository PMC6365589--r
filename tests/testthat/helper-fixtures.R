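# Shared fixtures. The synthetic benchmark (200 training + 100 test
# hairpins, signal 0.9, bulge rate 0.08, T = 5 boosting rounds) is trained
# once per test run and memoised so several test files can interrogate it.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixtures)) assign(key, fn(), envir = .fixtures)
  get(key, envir = .fixtures)
}

bench_records <- function(which = c("train", "test"), signal = 0.9,
                          bulge = 0.08) {
  which <- match.arg(which)
  n <- if (which == "train") 200L else 100L
  seed <- if (which == "train") 101L else 202L
  if (signal == 0) seed <- seed + 202L
  memo(sprintf("rec_%s_%g_%g", which, signal, bulge), function()
    generate_dataset(synthetic_spec(n_hairpins = n, signal_strength = signal,
                                    bulge_rate = bulge), seed = seed)$records)
}

bench_model <- function(mode = "structured", balance = TRUE, signal = 0.9) {
  memo(sprintf("model_%s_%d_%g", mode, balance, signal), function()
    mat_train(bench_records("train", signal), "P5_5", mode = mode,
              balance = balance, T = 5L, seed = 11L))
}

bench_report <- function(mode = "structured", balance = TRUE, signal = 0.9) {
  memo(sprintf("report_%s_%d_%g", mode, balance, signal), function() {
    ens <- bench_model(mode, balance, signal)
    test <- bench_records("test", signal)
    mat_evaluate(mat_predict(ens, test), test, ens)
  })
}

# small quickly-trained model for structural checks
tiny_model <- function() {
  memo("tiny_model", function() {
    recs <- generate_dataset(synthetic_spec(n_hairpins = 30L), seed = 7L)$records
    mat_train(recs, "P5_5", T = 2L, seed = 3L,
              C_grid = 2^c(0, 4), g_grid = 2^c(-5, -1), folds = 2L)
  })
}

random_hairpins <- function(n, seed, ...) {
  generate_dataset(synthetic_spec(n_hairpins = n, ...), seed = seed)$records
}

# independent brute-force multibranch oracle: for every loop (enclosed
# region of a pair, or the top level), count the helices emanating from it
# by an O(n^2) scan of the pair table
oracle_multibranch <- function(db) {
  pt <- pair_table(db)
  n <- length(pt)
  outermost_in <- function(lo, hi) {
    count <- 0L
    k <- lo
    while (k <= hi) {
      if (pt[k] > k) {
        count <- count + 1L
        k <- pt[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    count
  }
  if (n == 0L) return(FALSE)
  if (outermost_in(1L, n) >= 2L) return(TRUE)
  for (i in seq_len(n)) {
    if (pt[i] > i && outermost_in(i + 1L, pt[i] - 1L) >= 2L) return(TRUE)
  }
  FALSE
}

# all dot-bracket strings of a given length (for exhaustive oracles)
all_dotbrackets <- function(len) {
  alph <- c("(", ")", ".")
  grid <- do.call(expand.grid, c(rep(list(alph), len),
                                 stringsAsFactors = FALSE))
  strs <- do.call(paste0, grid)
  ok <- vapply(strs, function(s) {
    depth <- 0L
    for (ch in strsplit(s, "")[[1]]) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
    depth == 0L
  }, logical(1))
  strs[ok]
}
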