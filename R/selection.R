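# Feature ranking by information gain, chi-square statistic and Relief,
# plus the <=0-score filter that discards non-contributing features.
#
# IG and CHI operate on binarized features (continuous values thresholded
# at the training-set median); Relief operates on the raw values.

#' Binarize a feature matrix at per-feature medians
#'
#' Each feature is thresholded at its training-set median; "presence" of
#' feature t means value > threshold. Thresholds are returned for reuse on
#' test data. Constant features are flagged degenerate (their selection
#' score is defined as 0).
#'
#' @param m A `feature_matrix` or plain numeric matrix.
#' @param thresholds Optional stored thresholds (reuse on test data).
#' @return List with `presence` (logical matrix), `thresholds`,
#'   `degenerate` (logical per feature).
#' @export
binarize <- function(m, thresholds = NULL) {
  x <- if (inherits(m, "feature_matrix")) m$x else m
  if (is.null(thresholds)) thresholds <- apply(x, 2, median)
  presence <- sweep(x, 2, thresholds, ">")
  degenerate <- apply(x, 2, function(col) length(unique(col)) == 1L)
  list(presence = presence, thresholds = thresholds, degenerate = degenerate)
}

# joint/marginal probabilities of one binarized feature vs the class
contingency <- function(present, labels) {
  n <- length(labels)
  list(p_c = c(pos = mean(labels == 1L), neg = mean(labels == -1L)),
       p_t = mean(present),
       joint = c(pos_t = sum(labels == 1L & present) / n,
                 pos_nt = sum(labels == 1L & !present) / n,
                 neg_t = sum(labels == -1L & present) / n,
                 neg_nt = sum(labels == -1L & !present) / n))
}

xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Information gain of a binarized feature
#'
#' `IG(t) = sum_i [ -P(C_i) log P(C_i) + P(t) P(C_i|t) log P(C_i|t)
#'  + P(!t) P(C_i|!t) log P(C_i|!t) ]`, base-2 logs, `0 log 0 := 0`.
#' Equals the mutual information between the feature and the class.
#'
#' @param present Logical vector (feature presence per sample).
#' @param labels Vector over `{+1, -1}`.
#' @return Nonnegative score in bits.
#' @export
info_gain <- function(present, labels) {
  ct <- contingency(present, labels)
  p_t <- ct$p_t; p_nt <- 1 - p_t
  total <- 0
  for (cls in c("pos", "neg")) {
    p_c <- ct$p_c[[cls]]
    p_ct <- ct$joint[[paste0(cls, "_t")]]
    p_cnt <- ct$joint[[paste0(cls, "_nt")]]
    cond_t <- if (p_t > 0) p_ct / p_t else 0
    cond_nt <- if (p_nt > 0) p_cnt / p_nt else 0
    total <- total - xlogx(p_c) + p_t * xlogx(cond_t) + p_nt * xlogx(cond_nt)
  }
  total
}

#' Chi-square association score of a binarized feature
#'
#' Per class: `[P(C,t) P(!C,!t) - P(!C,t) P(C,!t)] /
#' [P(C) P(t) P(!C) P(!t)]`; the feature score is the maximum over the two
#' classes. Zero marginals give score 0 (degenerate).
#'
#' @inheritParams info_gain
#' @return Score (0 for class-independent features).
#' @export
chi_square <- function(present, labels) {
  ct <- contingency(present, labels)
  p_t <- ct$p_t; p_nt <- 1 - p_t
  scores <- vapply(c("pos", "neg"), function(cls) {
    other <- if (cls == "pos") "neg" else "pos"
    p_c <- ct$p_c[[cls]]; p_o <- ct$p_c[[other]]
    denom <- p_c * p_t * p_o * p_nt
    if (denom == 0) return(0)
    num <- ct$joint[[paste0(cls, "_t")]] * ct$joint[[paste0(other, "_nt")]] -
           ct$joint[[paste0(other, "_t")]] * ct$joint[[paste0(cls, "_nt")]]
    num / denom
  }, numeric(1))
  max(scores)
}

#' Relief feature weights
#'
#' Classic Kira-Rendell Relief: for `iterations` randomly probed samples,
#' each feature weight moves away from the nearest same-class neighbour
#' difference and toward the nearest other-class neighbour difference:
#' `W_j <- W_j - diff(j, x, H(x))/m + diff(j, x, M(x))/m`, with
#' `diff(j, a, b) = |a_j - b_j| / (max_j - min_j)` and nearest hit/miss by
#' Euclidean distance in min-max normalized feature space.
#'
#' @param m A `feature_matrix` (or plain matrix plus `labels`).
#' @param labels Required if `m` is a plain matrix.
#' @param iterations Number of probes `m`; default `min(N, 200)`.
#' @param seed Integer seed for the probe sampling.
#' @return Named numeric vector of feature weights.
#' @export
relief <- function(m, labels = NULL, iterations = NULL, seed = 1L) {
  x <- if (inherits(m, "feature_matrix")) m$x else m
  y <- if (inherits(m, "feature_matrix")) m$labels else labels
  n <- nrow(x)
  if (min(table(factor(y, levels = c(-1, 1)))) < 2L)
    stop("relief needs at least two samples in each class (no nearest hit otherwise)")
  rng <- apply(x, 2, function(col) diff(range(col)))
  ok <- rng > 0
  z <- x
  z[, ok] <- sweep(sweep(x[, ok, drop = FALSE], 2,
                         apply(x[, ok, drop = FALSE], 2, min)), 2, rng[ok], "/")
  z[, !ok] <- 0
  if (is.null(iterations)) iterations <- min(n, 200L)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  probes <- sample.int(n, iterations, replace = iterations > n)
  w <- numeric(ncol(x))
  for (p in probes) {
    dist2 <- rowSums(sweep(z, 2, z[p, ])^2)
    dist2[p] <- Inf
    same <- which(y == y[p])
    diffc <- which(y != y[p])
    h <- same[which.min(dist2[same])]
    mm <- diffc[which.min(dist2[diffc])]
    w <- w - abs(z[p, ] - z[h, ]) / iterations + abs(z[p, ] - z[mm, ]) / iterations
  }
  names(w) <- colnames(x)
  w
}

#' Score every feature of a matrix with one selection method
#'
#' @param m A `feature_matrix`.
#' @param method `"IG"`, `"CHI"` or `"Relief"`.
#' @param seed Seed for Relief probing.
#' @return Named numeric score vector (degenerate features score 0).
#' @export
score_features <- function(m, method = c("IG", "CHI", "Relief"), seed = 1L) {
  method <- match.arg(method)
  if (method == "Relief") return(relief(m, seed = seed))
  b <- binarize(m)
  scorer <- if (method == "IG") info_gain else chi_square
  scores <- vapply(seq_len(ncol(m$x)), function(j) {
    if (b$degenerate[j]) 0 else scorer(b$presence[, j], m$labels)
  }, numeric(1))
  names(scores) <- m$catalog
  scores
}

#' Filter and rank features by score
#'
#' Features scoring at or below zero are deleted; survivors are sorted by
#' descending score (ties broken by catalog order) and optionally cut to
#' the top `k`.
#'
#' @param scores Named score vector (names = catalog).
#' @param k Keep only the top `k` features; `NULL` keeps all survivors.
#' @return List with `selected` (ordered names), `scores` (full vector).
#' @export
rank_and_select <- function(scores, k = NULL) {
  keep <- which(scores > 0)
  if (length(keep) == 0L) stop("no feature has a positive selection score")
  ord <- keep[order(-scores[keep], keep)]
  if (!is.null(k)) ord <- ord[seq_len(min(k, length(ord)))]
  list(selected = names(scores)[ord], scores = scores)
}
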