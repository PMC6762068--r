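# One-class SVM from the Schoelkopf formulation, implemented from scratch.
# The dual
#   min_alpha 1/2 sum_ij alpha_i alpha_j k(x_i, x_j)
#   s.t.      0 <= alpha_i <= 1/(nu * l),  sum_i alpha_i = 1
# is solved by a pairwise working-set method (src/smo.cpp); the decision
# function is f(x) = sum_i alpha_i k(x_i, x) - rho.

#' Gaussian RBF kernel
#'
#' `k(x, y) = exp(-gamma * ||x - y||^2)`, the only kernel the package uses.
#' `gamma` controls the radius of influence of each training sample: large
#' values give tight, irregular decision boundaries, small values act as
#' regularization.
#'
#' @param x,y Numeric feature vectors of equal length.
#' @param gamma Positive kernel coefficient.
#' @return A scalar in `(0, 1]`.
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop_input("gamma must be a positive scalar")
  if (length(x) != length(y))
    stop_input("dimension mismatch: length(x) = %d, length(y) = %d",
               length(x), length(y))
  exp(-gamma * sum((x - y)^2))
}

as_feature_rows <- function(x) {
  if (inherits(x, "feature_matrix")) return(unname(x$Z))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  unname(as.matrix(x))
}

#' Train a one-class SVM
#'
#' Solves the dual problem by sequential minimal optimization with
#' first-order KKT-violation pair selection, then derives the bias `rho` as
#' the mean of `sum_j alpha_j k(x_j, x_i)` over margin support vectors
#' (those with `0 < alpha_i < 1/(nu*l)` strictly, inside a numerical guard
#' band); if no margin support vector exists, the midpoint of the
#' KKT-implied interval for `rho` is used.
#'
#' @param features A `feature_matrix` or plain numeric matrix of training
#'   rows.
#' @param nu Boundary-violation budget in `(0, 1]`: upper-bounds the
#'   fraction of training outliers and lower-bounds the support-vector
#'   fraction.
#' @param gamma RBF kernel coefficient (> 0).
#' @param tol Convergence tolerance on the maximal KKT violation.
#' @param max_iter Iteration cap; default `max(1e5, 100 * l)`.
#' @return An `ocsvm_model`: `support_vectors`, `alpha` (dual coefficients of
#'   the support vectors), `rho`, `gamma`, `nu`, `l`, `n_features`,
#'   `training_score`, `dual_objective` and solver diagnostics.
#' @export
ocsvm_train <- function(features, nu, gamma, tol = 1e-6, max_iter = NULL) {
  X <- as_feature_rows(features)
  l <- nrow(X)
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0 || nu > 1)
    stop_input("nu must lie in (0, 1], got %s", format(nu))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop_input("gamma must be > 0")
  if (l < ceiling(1 / nu))
    stop_input("infeasible: need at least ceiling(1/nu) = %d training rows, got %d",
               ceiling(1 / nu), l)
  if (is.null(max_iter)) max_iter <- max(1e5, 100 * l)

  C <- 1 / (nu * l)
  K <- rbf_kernel_matrix_cpp(X, X, gamma)
  sol <- smo_solve_cpp(K, C, tol, as.integer(max_iter))
  if (!sol$converged)
    stop_train("SMO did not converge: violation %.3g after %d iterations",
               sol$max_violation, sol$iterations, data = sol)

  alpha <- sol$alpha
  g <- sol$gradient                      # g_i = sum_j alpha_j k(x_j, x_i)
  sv <- alpha > C * 1e-8
  margin <- alpha > C * 1e-6 & alpha < C * (1 - 1e-6)
  rho <- if (any(margin)) {
    mean(g[margin])
  } else {
    at_c <- alpha >= C * (1 - 1e-6)
    at_0 <- alpha <= C * 1e-6
    lo <- if (any(at_c)) max(g[at_c]) else -Inf
    hi <- if (any(at_0)) min(g[at_0]) else Inf
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(lo)) lo else hi
  }

  model <- structure(
    list(support_vectors = X[sv, , drop = FALSE], alpha = alpha[sv],
         rho = rho, gamma = gamma, nu = nu, l = l, n_features = ncol(X),
         dual_objective = sol$objective, iterations = sol$iterations,
         max_violation = sol$max_violation, tol = tol,
         anchor = if (inherits(features, "feature_matrix"))
           features$anchor else NULL,
         scaler = if (inherits(features, "feature_matrix"))
           features$scaler else NULL,
         training_score = NA_real_),
    class = "ocsvm_model"
  )
  model$training_score <- ocsvm_score(model, X)
  model
}

#' @export
print.ocsvm_model <- function(x, ...) {
  cat(sprintf(
    "<ocsvm_model> nu=%g, gamma=%g, l=%d, %d SVs, rho=%.4g, training score %.3f\n",
    x$nu, x$gamma, x$l, length(x$alpha), x$rho, x$training_score))
  invisible(x)
}

#' Signed decision value
#'
#' Returns `sum_i alpha_i k(x_i, x) - rho`: positive on the inlier side of
#' the decision boundary, negative outside, zero on the boundary.
#'
#' @param model A trained `ocsvm_model`.
#' @param x A feature row, matrix of rows, or `feature_matrix`.
#' @return Numeric vector of signed margins, one per row of `x`.
#' @export
ocsvm_decision <- function(model, x) {
  stopifnot(inherits(model, "ocsvm_model"))
  X <- as_feature_rows(x)
  if (ncol(X) != model$n_features)
    stop_input("input has %d features, model expects %d",
               ncol(X), model$n_features)
  Kx <- rbf_kernel_matrix_cpp(X, model$support_vectors, model$gamma)
  as.numeric(Kx %*% model$alpha) - model$rho
}

#' Classify samples against the baseline model
#'
#' A sample is an inlier iff its decision value is `> 0`; an exact zero (a
#' point on the boundary, e.g. a margin support vector) counts as inlier.
#' This tie rule matters because the compliance index is a fraction of
#' inliers. In finite precision the decision value of a margin support
#' vector is only determined to within the solver's convergence tolerance,
#' so the boundary rule is applied with that tolerance as a guard band:
#' inlier iff `decision >= -tol`.
#'
#' @inheritParams ocsvm_decision
#' @return Character vector of `"inlier"` / `"outlier"` labels.
#' @export
ocsvm_predict <- function(model, x) {
  tol <- if (is.null(model$tol)) 1e-6 else model$tol
  ifelse(ocsvm_decision(model, x) >= -tol, "inlier", "outlier")
}

#' Fraction of samples classified as inliers
#'
#' The model score: the fraction of correct classifications when all rows
#' are baseline data (for one-class baseline data, "correct" means inlier).
#' On the training set this is the training score; on independent baseline
#' data, the test score.
#'
#' @inheritParams ocsvm_decision
#' @param features Feature rows to score.
#' @return A fraction in `[0, 1]`.
#' @export
ocsvm_score <- function(model, features) {
  X <- as_feature_rows(features)
  if (nrow(X) == 0) stop_input("cannot score an empty feature set")
  mean(ocsvm_predict(model, X) == "inlier")
}
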