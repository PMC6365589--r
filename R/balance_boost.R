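# Class-imbalance handling (K-means centroid-proximity undersampling of
# negatives) and the AdaBoost driver with misclassified-sample
# accumulation, per-hairpin max-probability relabeling, and ensemble
# prediction.

#' K-means centroid-proximity undersampling of negative candidates
#'
#' Partitions the negatives into `threshold` clusters by Lloyd iterations
#' (Euclidean assignment, mean centroids, stop when assignments stabilize),
#' then keeps from each cluster its samples nearest the centroid, with
#' per-cluster quotas allocated by largest remainder so the total selected
#' is exactly `floor(n / threshold)` — one `threshold`-th of the data, the
#' fraction that restores a roughly balanced positive:negative ratio when
#' the imbalance is about 1:`threshold`.
#'
#' @param x Numeric matrix of negative-candidate feature vectors.
#' @param threshold Number of clusters and undersampling factor (default 10).
#' @param seed Seed for centroid initialization.
#' @param max_iter Cap on Lloyd iterations.
#' @return Object of class `balance_result`: `cluster` (assignment),
#'   `centroids`, `selected` (row indices into `x`), `E` (final sum of
#'   squared sample-centroid distances), `E_trace` (E after each
#'   assignment step).
#' @export
kmeans_balance <- function(x, threshold = 10L, seed = 1L, max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- as.integer(threshold)
  if (n < k) stop("need at least ", k, " negatives to form ", k, " clusters")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # farthest-point seeding after a random first centroid
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  if (k > 1L) {
    d2 <- sq_dist(x, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      nxt <- which.max(d2)
      centers[j, ] <- x[nxt, ]
      d2 <- pmin(d2, sq_dist(x, centers[j, , drop = FALSE])[, 1L])
    }
  }
  assign_prev <- rep(0L, n)
  E_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D2 <- sq_dist(x, centers)
    cl <- max.col(-D2, ties.method = "first")
    E_trace <- c(E_trace, sum(D2[cbind(seq_len(n), cl)]))
    # empty cluster: re-seed at the sample farthest from its centroid,
    # never stealing a singleton or reusing a sample twice in one sweep
    for (j in seq_len(k)) {
      if (!any(cl == j)) {
        eligible <- which(tabulate(cl, k)[cl] > 1L)
        if (length(eligible) == 0L) break
        far <- eligible[which.max(D2[cbind(eligible, cl[eligible])])]
        cl[far] <- j
        centers[j, ] <- x[far, ]
      }
    }
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
    for (j in seq_len(k)) {
      if (any(cl == j))
        centers[j, ] <- colMeans(x[cl == j, , drop = FALSE])
    }
  }
  D2 <- sq_dist(x, centers)
  dist_own <- D2[cbind(seq_len(n), cl)]
  E <- sum(dist_own)
  # largest-remainder quotas so the grand total is exactly floor(n/threshold)
  sizes <- tabulate(cl, nbins = k)
  total <- n %/% k
  base <- sizes %/% k
  deficit <- total - sum(base)
  rem_order <- order(-(sizes %% k), seq_len(k))
  quota <- base
  if (deficit > 0) quota[rem_order[seq_len(deficit)]] <- quota[rem_order[seq_len(deficit)]] + 1L
  selected <- integer(0)
  for (j in seq_len(k)) {
    members <- which(cl == j)
    members <- members[order(dist_own[members], members)]
    selected <- c(selected, members[seq_len(min(quota[j], length(members)))])
  }
  structure(list(cluster = cl, centroids = centers, selected = sort(selected),
                 E = E, E_trace = E_trace, threshold = k),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat("<balance_result> ", length(x$cluster), " negatives -> ", x$threshold,
      " clusters, ", length(x$selected), " selected, E = ", format(x$E), "\n",
      sep = "")
  invisible(x)
}

#' AdaBoost classifier weight
#'
#' `alpha_t = log((1 - e_t) / e_t) / 2` (natural log). Positive iff the
#' weighted error is below 1/2.
#'
#' @param e_t Weighted training error in `[0, 1)`.
#' @return The classifier weight.
#' @export
adaboost_alpha <- function(e_t) {
  stopifnot(e_t >= 0, e_t < 1)
  0.5 * log((1 - e_t) / e_t)
}

#' AdaBoost sample-weight update
#'
#' `P_{t+1,i} = P_{t,i} exp(-alpha_t y_i G_t(x_i)) / Z_t` with `Z_t` the
#' normalizer, so the updated distribution sums to 1.
#'
#' @param D Current sample distribution (sums to 1).
#' @param alpha Classifier weight of the round.
#' @param y True labels over `{+1, -1}`.
#' @param G Weak-classifier labels over `{+1, -1}`.
#' @return The updated distribution.
#' @export
boost_update_weights <- function(D, alpha, y, G) {
  upd <- D * exp(-alpha * y * G)
  upd / sum(upd)
}

# Per-hairpin relabeling: within each group the candidate with the largest
# P(+1) is called +1, all others -1.
relabel_by_group <- function(prob, groups) {
  G <- rep(-1, length(prob))
  for (ids in split(seq_along(prob), groups)) {
    G[ids[which.max(prob[ids])]] <- 1
  }
  G
}

#' Train an AdaBoost ensemble of probability-output RBF-SVMs
#'
#' Round `t` trains a weak SVM (with a fresh grid search) on the subset
#' `S_t = S_pos + S_neg1 + all previously misclassified samples`, where
#' `S_neg1` is the K-means-balanced negative subset. Weak predictions are
#' relabeled per hairpin (max-probability candidate is +1); the weighted
#' error `e_t` over all samples sets the classifier weight
#' `alpha_t = log((1 - e_t)/e_t) / 2` and the exponential weight update
#' with normalizer `Z_t`. Training stops early when `e_t >= 0.5` (the
#' round is discarded) or `e_t = 0` (alpha capped with `eps = 1/N`, round
#' kept).
#'
#' @param m A `feature_matrix` of all training candidates (grouped by
#'   `pre_id`).
#' @param T Maximum boosting rounds.
#' @param threshold K-means balancing threshold (clusters/undersampling).
#' @param balance Balance negatives with [kmeans_balance()]? `FALSE` trains
#'   on all samples from round 1.
#' @param seed Integer seed (balancing, grid search folds).
#' @param C_grid,g_grid,folds,cv_max_n Grid-search configuration per round.
#' @return Object of class `matsite_ensemble`: `models` (weak classifiers
#'   with `alpha_t` set), `alphas`, `history` (per-round e_t, alpha_t, C,
#'   g, subset size), plus the feature bookkeeping filled in by
#'   [mat_train()].
#' @export
adaboost_train <- function(m, T = 10L, threshold = 10L, balance = TRUE,
                           seed = 1L, C_grid = 2^c(-1, 3, 7),
                           g_grid = 2^c(-7, -3, 1), folds = 2L,
                           cv_max_n = 600L) {
  stopifnot(inherits(m, "feature_matrix"), T >= 1L)
  x <- m$x; y <- m$labels; groups <- m$pre_id
  N <- nrow(x)
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  pos <- which(y == 1); neg <- which(y == -1)
  if (balance && length(neg) >= threshold) {
    bal <- kmeans_balance(x[neg, , drop = FALSE], threshold = threshold, seed = seed)
    S <- sort(c(pos, neg[bal$selected]))
  } else {
    bal <- NULL
    S <- seq_len(N)
  }
  D <- rep(1 / N, N)
  models <- list()
  history <- data.frame()
  for (t in seq_len(T)) {
    wS <- D[S] / sum(D[S])
    gs <- grid_search(x[S, , drop = FALSE], y[S], wS, C_grid = C_grid,
                      g_grid = g_grid, folds = folds, seed = seed + t,
                      cv_max_n = cv_max_n)
    model <- train_weighted_svm(x[S, , drop = FALSE], y[S], wS,
                                C = gs$C, g = gs$g)
    p_all <- predict(model, x, type = "prob")
    G <- relabel_by_group(p_all, groups)
    e_t <- sum(D[G != y])
    if (e_t >= 0.5) {
      if (length(models) == 0L)
        stop("first weak classifier is no better than chance (e_1 = ",
             format(e_t), "); cannot boost")
      break
    }
    capped <- e_t <= 0
    alpha <- adaboost_alpha(if (capped) 1 / N else e_t)
    model$alpha_t <- alpha
    models[[length(models) + 1L]] <- model
    history <- rbind(history, data.frame(round = t, e_t = e_t, alpha_t = alpha,
                                         C = gs$C, g = gs$g, n_subset = length(S)))
    if (capped) break
    D <- boost_update_weights(D, alpha, y, G)
    mis <- which(G != y)
    S <- sort(union(S, mis))
  }
  structure(list(models = models,
                 alphas = vapply(models, function(mo) mo$alpha_t, numeric(1)),
                 history = history, balance = bal,
                 site_type = m$site_type, mode = m$mode,
                 catalog = m$catalog, selected = m$catalog,
                 thresholds = NULL, window = NA_integer_, pad = NA_integer_),
            class = "matsite_ensemble")
}

#' @export
print.matsite_ensemble <- function(x, ...) {
  cat("<matsite_ensemble> ", x$site_type, " (", x$mode, "): ",
      length(x$models), " weak classifier(s), ", length(x$selected),
      " features\n", sep = "")
  if (nrow(x$history)) print(x$history, row.names = FALSE)
  invisible(x)
}

#' Score and rank the candidates of one hairpin with an ensemble
#'
#' The graded score is the alpha-weighted mean of the weak classifiers'
#' calibrated probabilities, `sum_t alpha_t P_t(+1|x) / sum_t alpha_t`; the
#' hard ensemble label (sign of `sum_t alpha_t G_t(x)`, with each weak
#' vote relabeled per hairpin) is reported alongside.
#'
#' @param ensemble A `matsite_ensemble`.
#' @param newx Feature matrix of the candidates of one hairpin (columns =
#'   the ensemble's selected features).
#' @return Data frame ordered by decreasing score: `row` (input row),
#'   `score`, `hard_label`, `rank`.
#' @export
ensemble_predict <- function(ensemble, newx) {
  newx <- as.matrix(newx)
  if (nrow(newx) == 0L) stop("no candidates to score")
  alphas <- ensemble$alphas
  P <- vapply(ensemble$models, function(mo) predict(mo, newx, type = "prob"),
              numeric(nrow(newx)))
  P <- matrix(P, nrow = nrow(newx))
  score <- drop(P %*% alphas) / sum(alphas)
  votes <- apply(P, 2, function(p) {
    v <- rep(-1, length(p)); v[which.max(p)] <- 1; v
  })
  votes <- matrix(votes, nrow = nrow(newx))
  hard <- sign(drop(votes %*% alphas))
  ord <- order(-score, seq_len(nrow(newx)))
  data.frame(row = ord, score = score[ord], hard_label = hard[ord],
             rank = seq_along(ord))
}
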