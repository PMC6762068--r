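# Diagnostic layer: the Model Compliance Index (MCI), scenario summaries,
# (nu, gamma) grid search and rank-sum scenario comparison.

#' Model Compliance Index
#'
#' `MCI = N_inliers / N_samples`: the fraction of a recording's feature rows
#' that fall inside the baseline model's decision boundary. 1 means full
#' agreement with the healthy-valve baseline; progressive valve degradation
#' shows as a declining MCI. Identical to [ocsvm_score()] by construction.
#'
#' @param model A trained `ocsvm_model`.
#' @param features A `feature_matrix` (preprocessed with the same
#'   conventions as the training data) or plain matrix.
#' @return A fraction in `[0, 1]`.
#' @export
compute_mci <- function(model, features) {
  ocsvm_score(model, features)
}

#' Summarize per-recording MCIs for one scenario
#'
#' Median and interquartile range over the recordings of one scenario,
#' using linear interpolation between order statistics for the percentiles.
#'
#' @param mcis Numeric vector of per-recording MCI values in `[0, 1]`.
#' @param scenario Scenario label.
#' @return An `mci_report` with `scenario`, `per_recording_mci`, `median`,
#'   `iqr`, `n_recordings`.
#' @export
summarize_scenario <- function(mcis, scenario = "unnamed") {
  if (length(mcis) < 1) stop_input("need at least one MCI value")
  if (any(mcis < 0 | mcis > 1)) stop_input("MCI values must lie in [0, 1]")
  q <- unname(quantile(mcis, c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(scenario = scenario, per_recording_mci = as.numeric(mcis),
         median = q[2], iqr = q[3] - q[1], n_recordings = length(mcis)),
    class = "mci_report"
  )
}

#' @export
print.mci_report <- function(x, ...) {
  cat(sprintf("<mci_report> %s: median MCI %.3f (iqr %.3f, n = %d)\n",
              x$scenario, x$median, x$iqr, x$n_recordings))
  invisible(x)
}

#' Hyperparameter grid search
#'
#' For every `(nu, gamma)` cell: train a one-class SVM on the pooled baseline
#' features and evaluate the sensitivity of the MCI towards pathological
#' flow, i.e. the average separation between baseline and regurgitant
#' recordings: `mean(MCI_baseline) - mean(MCI_AR)`. Returns the full
#' sensitivity matrix and its argmax.
#'
#' @param baseline_features List of `feature_matrix` objects (>= 2
#'   recordings), used both to train and to evaluate the baseline MCI.
#' @param ar_features List of `feature_matrix` objects from degraded-valve
#'   recordings (>= 1).
#' @param nu_grid,gamma_grid Hyperparameter grids. Defaults span hard/soft
#'   margins and strong/weak regularization around the working optimum
#'   (nu = 0.05, gamma = 7).
#' @param tol SMO convergence tolerance.
#' @return A `grid_search_result`: `nu_grid`, `gamma_grid`, `sensitivity`
#'   matrix (`length(nu_grid)` x `length(gamma_grid)`), and `best` (list with
#'   `nu`, `gamma`, `sensitivity`).
#' @export
grid_search <- function(baseline_features, ar_features,
                        nu_grid = c(0.01, 0.05, 0.1, 0.2),
                        gamma_grid = c(0.1, 1, 7, 20, 100),
                        tol = 1e-6) {
  if (length(nu_grid) < 1 || length(gamma_grid) < 1)
    stop_input("empty hyperparameter grid")
  if (length(baseline_features) < 2)
    stop_input("need >= 2 baseline recordings (one to train, one to score)")
  if (length(ar_features) < 1)
    stop_input("need >= 1 degraded-valve recording")
  pooled <- pool_features(baseline_features)
  sens <- matrix(NA_real_, length(nu_grid), length(gamma_grid),
                 dimnames = list(nu = as.character(nu_grid),
                                 gamma = as.character(gamma_grid)))
  for (i in seq_along(nu_grid)) {
    for (j in seq_along(gamma_grid)) {
      model <- ocsvm_train(pooled, nu = nu_grid[i], gamma = gamma_grid[j],
                           tol = tol)
      mci_base <- vapply(baseline_features, compute_mci, 0, model = model)
      mci_ar <- vapply(ar_features, compute_mci, 0, model = model)
      sens[i, j] <- mean(mci_base) - mean(mci_ar)
    }
  }
  best_idx <- which(sens == max(sens), arr.ind = TRUE)[1, ]
  structure(
    list(nu_grid = nu_grid, gamma_grid = gamma_grid, sensitivity = sens,
         best = list(nu = nu_grid[best_idx[1]],
                     gamma = gamma_grid[best_idx[2]],
                     sensitivity = max(sens))),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> best: nu=%g, gamma=%g (sensitivity %.3f)\n",
              x$best$nu, x$best$gamma, x$best$sensitivity))
  print(round(x$sensitivity, 3))
  invisible(x)
}

#' Compare two scenarios with a one-sided rank-sum test
#'
#' One-sided Wilcoxon rank-sum (Mann-Whitney) test of the hypothesis that
#' scenario A's MCIs are stochastically greater than scenario B's. The exact
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param report_a,report_b `mci_report` objects or plain numeric vectors of
#'   per-recording MCIs.
#' @param alpha Significance level (default 0.01).
#' @return A `scenario_comparison`: `statistic` (Mann-Whitney U of A over B),
#'   `p_value`, `significant`, `exact`, `alpha`.
#' @export
compare_scenarios <- function(report_a, report_b, alpha = 0.01) {
  a <- if (inherits(report_a, "mci_report")) report_a$per_recording_mci
       else as.numeric(report_a)
  b <- if (inherits(report_b, "mci_report")) report_b$per_recording_mci
       else as.numeric(report_b)
  if (length(a) < 3 || length(b) < 3)
    stop_input("need >= 3 recordings per scenario for a meaningful test")
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "greater", exact = exact,
                correct = !exact)
  )
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         significant = wt$p.value < alpha, exact = exact, alpha = alpha,
         n_a = length(a), n_b = length(b)),
    class = "scenario_comparison"
  )
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf(
    "<scenario_comparison> U = %g, one-sided p = %.4g (%s), %ssignificant at %g%%\n",
    x$statistic, x$p_value, if (x$exact) "exact" else "normal approx.",
    if (x$significant) "" else "not ", 100 * x$alpha))
  invisible(x)
}

#' Monitor MCI over time
#'
#' Scores a time-ordered sequence of recordings against the baseline model
#' and fits a linear trend: a persistent negative slope indicates
#' progressive valve degradation.
#'
#' @param model A trained `ocsvm_model`.
#' @param feature_list Time-ordered list of `feature_matrix` objects.
#' @param timestamps Optional numeric timestamps (default `1, 2, ...`).
#' @return An `mci_timeseries`: `timestamps`, `mci`, `slope` (MCI per unit
#'   time).
#' @export
monitor_mci <- function(model, feature_list, timestamps = NULL) {
  if (length(feature_list) < 1) stop_input("empty recording list")
  if (is.null(timestamps)) timestamps <- seq_along(feature_list)
  if (length(timestamps) != length(feature_list))
    stop_input("timestamps length does not match recordings")
  mci <- vapply(feature_list, compute_mci, 0, model = model)
  slope <- if (length(mci) >= 2)
    unname(coef(lm(mci ~ timestamps))[2]) else NA_real_
  structure(
    list(timestamps = timestamps, mci = mci, slope = slope),
    class = "mci_timeseries"
  )
}

#' @export
print.mci_timeseries <- function(x, ...) {
  cat(sprintf("<mci_timeseries> %d recordings, MCI %.3f -> %.3f, slope %.4g\n",
              length(x$mci), x$mci[1], x$mci[length(x$mci)], x$slope))
  invisible(x)
}
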