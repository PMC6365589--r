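# independent brute-force oracles --------------------------------------

# mutual information of a 2x2 count table (class x presence), base-2
oracle_mi <- function(n_pt, n_pn, n_nt, n_nn) {
  n <- n_pt + n_pn + n_nt + n_nn
  joint <- matrix(c(n_pt, n_pn, n_nt, n_nn), 2, byrow = TRUE) / n
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (sum(joint[i, ]) * sum(joint[, j])))
  }
  mi
}

# literal per-class chi-square association score, max over classes
oracle_chi <- function(n_pt, n_pn, n_nt, n_nn) {
  n <- n_pt + n_pn + n_nt + n_nn
  p <- unname(c(n_pt, n_pn, n_nt, n_nn) / n)
  names(p) <- c("pt", "pn", "nt", "nn")
  p_c <- c(pos = unname(p["pt"] + p["pn"]), neg = unname(p["nt"] + p["nn"]))
  p_t <- unname(p["pt"] + p["nt"])
  sc <- function(cpt, cpn, opt, opn, pc, po) {
    den <- pc * p_t * po * (1 - p_t)
    if (den == 0) 0 else (cpt * opn - opt * cpn) / den
  }
  max(sc(p["pt"], p["pn"], p["nt"], p["nn"], p_c["pos"], p_c["neg"]),
      sc(p["nt"], p["nn"], p["pt"], p["pn"], p_c["neg"], p_c["pos"]))
}

# plain-loop Relief re-implementation (same probe sequence via same seed)
oracle_relief <- function(x, y, iterations, seed) {
  n <- nrow(x)
  rng <- apply(x, 2, function(c) diff(range(c)))
  z <- x
  for (j in seq_len(ncol(x)))
    z[, j] <- if (rng[j] > 0) (x[, j] - min(x[, j])) / rng[j] else 0
  set.seed(seed)
  probes <- sample.int(n, iterations, replace = iterations > n)
  w <- numeric(ncol(x))
  for (p in probes) {
    best_h <- best_m <- NA; dh <- dm <- Inf
    for (q in seq_len(n)) {
      if (q == p) next
      d <- sum((z[p, ] - z[q, ])^2)
      if (y[q] == y[p] && d < dh) { dh <- d; best_h <- q }
      if (y[q] != y[p] && d < dm) { dm <- d; best_m <- q }
    }
    for (j in seq_len(ncol(x)))
      w[j] <- w[j] - abs(z[p, j] - z[best_h, j]) / iterations +
                     abs(z[p, j] - z[best_m, j]) / iterations
  }
  w
}

expand_counts <- function(n_pt, n_pn, n_nt, n_nn) {
  present <- c(rep(TRUE, n_pt), rep(FALSE, n_pn), rep(TRUE, n_nt), rep(FALSE, n_nn))
  labels <- c(rep(1L, n_pt + n_pn), rep(-1L, n_nt + n_nn))
  list(present = present, labels = labels)
}

# tests -----------------------------------------------------------------

test_that("median binarization thresholds and reuses correctly", {
  x <- cbind(f1 = c(0, 1, 2, 3), f2 = c(0, 1, 0, 1), f3 = rep(2, 4))
  b <- binarize(x)
  expect_equal(unname(b$thresholds["f1"]), 1.5)
  expect_identical(unname(b$presence[, "f1"]), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(unname(b$presence[, "f2"]), c(FALSE, TRUE, FALSE, TRUE))
  expect_true(b$degenerate[["f3"]])
  b2 <- binarize(matrix(c(0, 2), ncol = 1, dimnames = list(NULL, "f1")),
                 thresholds = b$thresholds["f1"])
  expect_identical(unname(b2$presence[, 1]), c(FALSE, TRUE))
})

test_that("information gain matches closed forms and exhaustive mutual information", {
  # class-independent feature
  e <- expand_counts(2, 2, 2, 2)
  expect_equal(info_gain(e$present, e$labels), 0, tolerance = 1e-12)
  # perfect predictor of a balanced class: 1 bit
  e <- expand_counts(4, 0, 0, 4)
  expect_equal(info_gain(e$present, e$labels), 1, tolerance = 1e-12)
  # exhaustive oracle over all 2x2 tables with cell counts <= 6
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (dd in 0:6) {
    if (a + b == 0 || cc + dd == 0) next  # both classes must occur
    e <- expand_counts(a, b, cc, dd)
    expect_equal(info_gain(e$present, e$labels), oracle_mi(a, b, cc, dd),
                 tolerance = 1e-10)
  }
})

test_that("information gain is nonnegative on random tables", {
  set.seed(12)
  for (rep in 1:200) {
    cnt <- rmultinom(1, sample(8:40, 1), runif(4))[, 1]
    if (cnt[1] + cnt[2] == 0 || cnt[3] + cnt[4] == 0) next
    e <- expand_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_gte(info_gain(e$present, e$labels), -1e-12)
  }
})

test_that("chi-square scores match direct substitution and the oracle", {
  e <- expand_counts(2, 2, 2, 2)
  expect_equal(chi_square(e$present, e$labels), 0, tolerance = 1e-12)
  # P(C,t) = P(!C,!t) = 0.5 -> (0.25 - 0) / 0.5^4 = 4
  e <- expand_counts(5, 0, 0, 5)
  expect_equal(chi_square(e$present, e$labels), 4, tolerance = 1e-12)
  set.seed(34)
  for (rep in 1:200) {
    cnt <- rmultinom(1, sample(8:40, 1), runif(4))[, 1]
    if (cnt[1] + cnt[2] == 0 || cnt[3] + cnt[4] == 0) next
    e <- expand_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(chi_square(e$present, e$labels),
                 oracle_chi(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
  }
})

test_that("relief weights behave on degenerate and separable features", {
  # constant feature gets weight 0; a cleanly separating feature, positive
  x <- cbind(sep = c(0, 0.1, 0.9, 1), const = rep(1, 4), noise = c(0.4, 0.6, 0.5, 0.45))
  y <- c(-1, -1, 1, 1)
  w <- relief(x, y, iterations = 4, seed = 5)
  expect_equal(unname(w["const"]), 0)
  expect_gt(unname(w["sep"]), 0)
  expect_gt(unname(w["sep"]), unname(w["noise"]))
  expect_error(relief(cbind(a = 1:3), c(1, -1, -1), seed = 1), "two samples")
})

test_that("relief matches a brute-force re-implementation, same seed", {
  set.seed(88)
  x <- matrix(runif(10 * 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(1, -1), each = 5)
  for (seed in c(1, 9)) {
    w <- relief(x, y, iterations = 10, seed = seed)
    expect_equal(unname(w), oracle_relief(x, y, 10, seed), tolerance = 1e-12)
  }
  # reproducibility bit-for-bit
  expect_identical(relief(x, y, seed = 2), relief(x, y, seed = 2))
})

test_that("rank_and_select drops non-contributing features and is idempotent", {
  scores <- c(a = 0.5, b = -0.1, c = 0.2)
  sel <- rank_and_select(scores)
  expect_identical(sel$selected, c("a", "c"))
  expect_identical(rank_and_select(scores, k = 1)$selected, "a")
  # idempotence: selecting from the survivors changes nothing
  expect_identical(rank_and_select(scores[sel$selected])$selected, sel$selected)
  expect_error(rank_and_select(c(a = 0, b = -2)), "no feature")
  # ties broken by catalog order
  expect_identical(rank_and_select(c(x = 0.3, y = 0.3))$selected, c("x", "y"))
})
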