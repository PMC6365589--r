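# Weak learner: soft-margin RBF-kernel SVM with per-sample penalties
# (carrying the boosting distribution into the solver), sigmoid calibration
# of margins, and pairwise-coupling probability estimates.

#' RBF kernel value
#'
#' `K(x, x') = exp(-g ||x - x'||^2)`, identifying `g` with `1/(2 delta^2)`
#' of the Gaussian-width parameterization.
#'
#' @param x,y Equal-length numeric vectors.
#' @param g Kernel width parameter, `g > 0`.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, g) {
  stopifnot(length(x) == length(y), g > 0)
  exp(-g * sum((x - y)^2))
}

# cross matrix of squared Euclidean distances
sq_dist <- function(X, Y = X) {
  xn <- rowSums(X^2)
  yn <- rowSums(Y^2)
  d <- outer(xn, yn, "+") - 2 * tcrossprod(X, Y)
  d[d < 0] <- 0
  d
}

rbf_kernel_matrix <- function(X, Y = X, g) exp(-g * sq_dist(X, Y))

#' Train a weighted soft-margin RBF-SVM with probability calibration
#'
#' Solves the soft-margin dual with per-sample penalties
#' `C_i = C * w_i * N` (weighted hinge loss), then fits a sigmoid mapping
#' training margins to class probabilities (with the standard regularized
#' targets), so the model outputs the pairwise probability estimate
#' `P(+1 | x)` of the binary pair.
#'
#' @param x Numeric feature matrix (rows = samples) or a `feature_matrix`.
#' @param y Labels over `{+1, -1}` (taken from `x` if a `feature_matrix`).
#' @param weights Nonnegative sample weights summing to 1; default uniform.
#' @param C Penalty parameter.
#' @param g RBF width parameter.
#' @param eps SMO stopping tolerance on the KKT gap.
#' @return Object of class `weak_svm` (support vectors, dual coefficients,
#'   bias, calibration, `C`, `g`; `alpha_t` slot for the ensemble weight).
#' @export
train_weighted_svm <- function(x, y = NULL, weights = NULL, C = 1, g = 0.1,
                               eps = 1e-3) {
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n, all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-6)
  Ci <- C * weights * n
  K <- rbf_kernel_matrix(x, g = g)
  sol <- .smo_solve(K, as.numeric(y), Ci, eps = eps)
  if (sol$gap > 10 * eps)
    stop("SVM solver did not converge: KKT gap ", format(sol$gap),
         " after ", sol$iter, " updates (C = ", C, ", g = ", g, ")")
  alpha <- sol$alpha
  sv <- alpha > 1e-12
  model <- structure(list(sv = x[sv, , drop = FALSE],
                          coef = alpha[sv] * y[sv],
                          b = sol$b, C = C, g = g,
                          platt = NULL, alpha_t = NA_real_),
                     class = "weak_svm")
  f <- svm_margin(model, x)
  model$platt <- fit_platt(f, y, weights)
  model
}

svm_margin <- function(model, newx) {
  if (nrow(model$sv) == 0L) return(rep(model$b, nrow(newx)))
  drop(rbf_kernel_matrix(newx, model$sv, model$g) %*% model$coef) + model$b
}

# Sigmoid calibration of margins -> P(+1), with Platt's regularized targets
# so perfectly separated training data does not send the slope to infinity.
fit_platt <- function(f, y, weights) {
  npos <- sum(y == 1); nneg <- sum(y == -1)
  t <- ifelse(y == 1, (npos + 1) / (npos + 2), 1 / (nneg + 2))
  fit <- tryCatch(
    suppressWarnings(glm(t ~ f, family = quasibinomial(),
                         weights = weights * length(y))),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(coef(fit))))
    return(c(intercept = 0, slope = 1))
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

#' Predict with a weak probability-SVM
#'
#' @param object A `weak_svm`.
#' @param newx Matrix of candidates (same feature space).
#' @param type `"prob"` for `P(+1|x)` (calibrated pairwise estimate passed
#'   through the probability-coupling solution), `"margin"` for the raw
#'   decision value, `"class"` for its sign.
#' @param ... Unused.
#' @return Numeric vector (or `{-1, +1}` for `"class"`).
#' @export
predict.weak_svm <- function(object, newx, type = c("prob", "margin", "class"), ...) {
  type <- match.arg(type)
  f <- svm_margin(object, as.matrix(newx))
  if (type == "margin") return(f)
  if (type == "class") return(ifelse(f >= 0, 1, -1))
  r <- plogis(object$platt["intercept"] + object$platt["slope"] * f)
  # binary coupling: P_{+1} equals the pairwise estimate r_{+1,-1}
  vapply(r, function(ri) couple_probabilities(ri)$P[1], numeric(1))
}

#' Couple pairwise probability estimates into class probabilities
#'
#' Solves `min 1/2 sum_i sum_{j!=i} (r_ji P_i - r_ij P_j)^2` subject to
#' `sum_i P_i = 1` via the KKT linear system `[Q e; e' 0] [P; b] = [0; 1]`,
#' with `Q_ii = sum_{s!=i} r_si^2` and `Q_ij = -r_ji r_ij`. For the binary
#' case the solution is the closed form `P_1 = r_12`.
#'
#' @param r Either a scalar `r_12` in (0, 1) (binary case) or a `k x k`
#'   matrix of pairwise estimates with `r_ji = 1 - r_ij`.
#' @return List with `P` (class probabilities, summing to 1), `Q`, and
#'   `singular` (TRUE if the KKT system was singular and the normalized
#'   diagonal fallback was used).
#' @export
couple_probabilities <- function(r) {
  if (is.matrix(r)) {
    R <- r
  } else {
    stopifnot(length(r) == 1L, r > 0, r < 1)
    R <- matrix(c(NA, r, 1 - r, NA), 2, 2, byrow = TRUE)
  }
  k <- nrow(R)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    Q[i, j] <- if (i == j) sum(R[setdiff(seq_len(k), i), i]^2)
               else -R[j, i] * R[i, j]
  }
  A <- rbind(cbind(Q, 1), c(rep(1, k), 0))
  sol <- tryCatch(solve(A, c(rep(0, k), 1)), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) {
    p <- diag(Q)
    p <- if (sum(p) > 0) p / sum(p) else rep(1 / k, k)
    return(list(P = p, Q = Q, singular = TRUE))
  }
  list(P = sol[seq_len(k)], Q = Q, singular = FALSE)
}

#' Grid search over (C, g) by weighted cross-validation
#'
#' Exhaustive search over the conventional grid-search ranges
#' `C in 2^(-5..15 step 2)`, `g in 2^(-15..3 step 2)` by default; selects
#' the pair maximizing weighted cross-validated accuracy, ties broken
#' toward the smallest `C` then the smallest `g`. For large inputs the CV
#' fits can run on a seeded stratified subsample (`cv_max_n`); the returned
#' pair is then used to train on all samples.
#'
#' @param x Feature matrix (or `feature_matrix`).
#' @param y Labels (if `x` is a plain matrix).
#' @param weights Sample weights (sum 1); default uniform.
#' @param C_grid,g_grid Candidate values.
#' @param folds Number of CV folds (>= 2).
#' @param seed Seed for fold assignment (and subsampling).
#' @param cv_max_n Cap on the number of samples used in the CV fits.
#' @return List with `C`, `g`, and `cv_accuracy` (the winning weighted CV
#'   accuracy).
#' @export
grid_search <- function(x, y = NULL, weights = NULL,
                        C_grid = 2^seq(-5, 15, 2), g_grid = 2^seq(-15, 3, 2),
                        folds = 5L, seed = 1L, cv_max_n = NULL) {
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$x
  }
  stopifnot(length(C_grid) >= 1L, length(g_grid) >= 1L, folds >= 2L)
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1 / n, n)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- seq_len(n)
  if (!is.null(cv_max_n) && n > cv_max_n) {
    pos <- which(y == 1); neg <- which(y == -1)
    npos <- max(2L, round(cv_max_n * length(pos) / n))
    idx <- sort(c(sample(pos, min(length(pos), npos)),
                  sample(neg, min(length(neg), cv_max_n - npos))))
  }
  xs <- x[idx, , drop = FALSE]; ys <- y[idx]; ws <- weights[idx]
  m <- length(idx)
  # stratified folds so every training fold sees both classes
  fold <- integer(m)
  for (cls in c(1, -1)) {
    members <- which(ys == cls)
    fold[members] <- sample(rep_len(seq_len(folds), length(members)))
  }
  D2 <- sq_dist(xs)
  best <- list(C = NA_real_, g = NA_real_, cv_accuracy = -Inf)
  for (C in sort(C_grid)) for (g in sort(g_grid)) {
    correct <- 0; total <- 0
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- !tr
      if (length(unique(ys[tr])) < 2L || !any(te)) next
      Ktr <- exp(-g * D2[tr, tr, drop = FALSE])
      wtr <- ws[tr] / sum(ws[tr])
      sol <- .smo_solve(Ktr, as.numeric(ys[tr]), C * wtr * sum(tr))
      f <- drop(exp(-g * D2[te, tr, drop = FALSE]) %*% (sol$alpha * ys[tr])) + sol$b
      pred <- ifelse(f >= 0, 1, -1)
      correct <- correct + sum(ws[te] * (pred == ys[te]))
      total <- total + sum(ws[te])
    }
    acc <- if (total > 0) correct / total else 0
    if (acc > best$cv_accuracy + 1e-12) best <- list(C = C, g = g, cv_accuracy = acc)
  }
  best
}
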