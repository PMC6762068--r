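# Condenses a multi-beat recording into a standardized phase/flow feature
# cloud: fit A*sin(2*pi*f*t + phi) + b to estimate period and phase of the
# first harmonic, slice at the fitted sinusoid's extrema, map every sample
# onto one cycle via tau = t mod T, then z-score each feature axis.

#' Fit a sinusoid to a flow recording
#'
#' Least-squares fit of `A * sin(2*pi*f*t + phi) + b` by a
#' Levenberg-Marquardt iteration. The sinusoid is a poor model of the cardiac
#' waveform itself but a robust estimator of its base frequency and phase,
#' which is all the downstream phase mapping needs. The frequency is
#' initialized from the dominant nonzero peak of the signal's spectrum
#' (unless given), amplitude from `sqrt(2) * sd`, offset from the mean, and
#' the fit is restarted at four phase offsets (0, pi/2, pi, 3*pi/2), keeping
#' the lowest residual, to escape the phase local minima characteristic of
#' sinusoid fitting.
#'
#' @param recording A [flow_recording()].
#' @param initial_frequency Starting frequency in Hz, or `NULL` to take it
#'   from the spectral peak.
#' @param max_iter Maximum Levenberg-Marquardt iterations per restart.
#' @return A `sinusoid_model` with fields `amplitude` (>= 0), `frequency`
#'   (Hz), `phase` (in `[0, 2*pi)`), `offset`, plus fit diagnostics
#'   `residual_norm`, `iterations`, `converged`.
#' @export
fit_sinusoid <- function(recording, initial_frequency = NULL, max_iter = 200) {
  stopifnot(inherits(recording, "flow_recording"))
  t <- recording$times
  y <- recording$values
  n <- length(y)
  if (sd(y) == 0)
    stop_fit("constant recording: amplitude is zero, phase undefined")

  f0 <- initial_frequency
  if (is.null(f0)) {
    # Hann window: without it, spectral leakage on non-bin-aligned periods
    # can let a bin-aligned harmonic overtake the fundamental
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    spec <- Mod(fft((y - mean(y)) * w))[2:floor(n / 2)]
    k <- which.max(spec)  # first bin after DC
    f0 <- k * recording$sample_rate / n
  }
  if (f0 <= 0) stop_fit("non-positive initial frequency %g", f0)
  duration <- t[n] - t[1]
  if (duration < 2 / f0)
    stop_input("recording spans %.2f s < 2 estimated periods (%.2f s)",
               duration, 2 / f0)

  A0 <- sqrt(2) * sd(y)
  b0 <- mean(y)
  best <- NULL
  for (phi0 in c(0, pi / 2, pi, 3 * pi / 2)) {
    fit <- lm_sinusoid(t, y, c(A0, f0, phi0, b0), max_iter)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  if (!best$converged)
    stop_fit("sinusoid fit did not converge in %d iterations", max_iter,
             data = best)

  p <- best$par  # (A, f, phi, b) -> canonical A >= 0, phi in [0, 2*pi)
  if (p[1] < 0) { p[1] <- -p[1]; p[3] <- p[3] + pi }
  if (p[2] < 0) { p[2] <- -p[2]; p[3] <- pi - p[3] }
  p[3] <- p[3] %% (2 * pi)
  if (p[3] >= 2 * pi - 1e-10) p[3] <- 0  # fp wrap: 2*pi and 0 are the same phase
  structure(
    list(amplitude = p[1], frequency = p[2], phase = p[3], offset = p[4],
         residual_norm = sqrt(best$sse), iterations = best$iterations,
         converged = best$converged),
    class = "sinusoid_model"
  )
}

#' @export
print.sinusoid_model <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_model> A=%.4g, f=%.6g Hz, phi=%.4g rad, b=%.4g (resid %.3g, %d iter)\n",
    x$amplitude, x$frequency, x$phase, x$offset, x$residual_norm,
    x$iterations))
  invisible(x)
}

# One Levenberg-Marquardt run on par = (A, f, phi, b).
lm_sinusoid <- function(t, y, par, max_iter) {
  model <- function(p) p[1] * sin(2 * pi * p[2] * t + p[3]) + p[4]
  r <- y - model(par)
  sse <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    w <- 2 * pi * par[2] * t + par[3]
    cw <- cos(w)
    J <- cbind(sin(w), par[1] * cw * 2 * pi * t, par[1] * cw, 1)
    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)
    accepted <- FALSE
    for (k in 1:30) {
      H <- JtJ + lambda * diag(diag(JtJ) + 1e-12)
      delta <- tryCatch(solve(H, Jtr), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- par + as.numeric(delta)
        r_new <- y - model(cand)
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new <= sse) {
          rel <- (sse - sse_new) / max(sse, .Machine$double.eps)
          step <- max(abs(delta) / pmax(abs(par), 1e-8))
          par <- cand; r <- r_new; sse <- sse_new
          lambda <- max(lambda / 3, 1e-12)
          accepted <- TRUE
          if (rel < 1e-14 || step < 1e-12) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 3
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  list(par = par, sse = sse, iterations = iter, converged = converged)
}

#' Condense a recording onto a single cardiac cycle
#'
#' Uses the fitted sinusoid's extrema to slice the recording: cycles are
#' anchored at the sinusoid's minima (the flow minimum, near end-diastole; a
#' fixed package-wide convention) and every sample is mapped to its phase
#' `tau = (t - t0) mod T` with `T = 1/f` and `t0` the first fitted minimum.
#' No samples are dropped: partial leading/trailing cycles wrap correctly
#' under the modulus.
#'
#' @param recording A [flow_recording()].
#' @param fit A `sinusoid_model` from [fit_sinusoid()].
#' @return A `condensed_cycle` with fields `tau` (in `[0, T)`), `flow`,
#'   `period`, `heart_rate` (beats/min), `anchor_time`.
#' @export
condense <- function(recording, fit) {
  stopifnot(inherits(recording, "flow_recording"),
            inherits(fit, "sinusoid_model"))
  T <- 1 / fit$frequency
  t <- recording$times
  if (t[length(t)] - t[1] < 2 * T)
    stop_input("recording shorter than 2 fitted periods (%.3f s)", 2 * T)
  # sin minimal where 2*pi*f*t + phi = 3*pi/2 (mod 2*pi); first such t >= t[1]
  t0 <- t[1] + ((3 * pi / 2 - fit$phase) / (2 * pi) - t[1] * fit$frequency) %%
    1 / fit$frequency
  tau <- (t - t0) %% T
  tau[tau >= T] <- 0  # guard against T itself from fp rounding
  structure(
    list(tau = tau, flow = recording$values, period = T,
         heart_rate = 60 / T, anchor_time = t0),
    class = "condensed_cycle"
  )
}

#' Standardize a condensed cycle into a feature matrix
#'
#' Applies the z-score transform `Z = (X - mean(X)) / sd(X)` per feature
#' axis: `Z1` the phase `tau`, `Z2` the instantaneous flow and optionally
#' `Z3` the heart rate. The SVM downstream is not scale invariant, so all
#' axes are brought onto a common scale. By default each recording is
#' standardized by its own statistics; a scaler from another recording (or a
#' pooled baseline) can be supplied instead, and the scaler actually used is
#' recorded in the result.
#'
#' `Z3` is constant within a single recording, so it is kept raw here and
#' standardized across recordings by [pool_features()].
#'
#' @param cycle A `condensed_cycle` from [condense()].
#' @param scaler Optional list with `center` and `scale` vectors to apply
#'   instead of the cycle's own statistics.
#' @param features 2 for (Z1, Z2), 3 to append the heart-rate axis.
#' @return A `feature_matrix`: matrix `Z` with columns `Z1`, `Z2` (and `Z3`),
#'   plus the `scaler` used, `heart_rate` and `period`.
#' @export
standardize <- function(cycle, scaler = NULL, features = 2) {
  stopifnot(inherits(cycle, "condensed_cycle"))
  if (!features %in% c(2, 3))
    stop_input("features must be 2 or 3, got %s", features)
  X <- cbind(Z1 = cycle$tau, Z2 = cycle$flow)
  if (features == 3) X <- cbind(X, Z3 = rep(cycle$heart_rate, nrow(X)))
  axes <- colnames(X)
  std_axes <- axes[axes != "Z3"]  # Z3 standardized across recordings later

  if (is.null(scaler)) {
    center <- colMeans(X)
    # population sigma: the common standardization convention, and the one
    # under which two equally frequent values map exactly to -1 / +1
    scale <- sqrt(colMeans(sweep(X, 2, center)^2))
    bad <- std_axes[scale[std_axes] == 0]
    if (length(bad))
      stop_flowmci("flowmci_standardize_error",
                   "zero variance on axis %s: cannot standardize",
                   paste(bad, collapse = ", "))
    if ("Z3" %in% axes) { center["Z3"] <- 0; scale["Z3"] <- 1 }  # raw
    scaler <- list(center = center, scale = scale, own = TRUE)
  } else {
    if (is.null(scaler$center) || is.null(scaler$scale))
      stop_input("scaler must supply center and scale for each axis")
    if (!is.null(names(scaler$center))) {
      if (!all(axes %in% names(scaler$center)))
        stop_input("scaler lacks entries for axes %s",
                   paste(setdiff(axes, names(scaler$center)), collapse = ", "))
      scaler$center <- scaler$center[axes]
      scaler$scale <- scaler$scale[axes]
    } else if (length(scaler$center) != length(axes)) {
      stop_input("scaler length %d does not match %d feature axes",
                 length(scaler$center), length(axes))
    }
    scaler$own <- FALSE
    if (any(scaler$scale == 0))
      stop_flowmci("flowmci_standardize_error",
                   "external scaler has a zero scale entry")
  }
  Z <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
  structure(
    list(Z = Z, scaler = scaler, n = nrow(Z),
         heart_rate = cycle$heart_rate, period = cycle$period,
         anchor = "sinusoid minimum"),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s), heart rate %.2f bpm\n",
              nrow(x$Z), ncol(x$Z), paste(colnames(x$Z), collapse = ", "),
              x$heart_rate))
  invisible(x)
}

#' Preprocess a recording end to end
#'
#' Chains [fit_sinusoid()], [condense()] and [standardize()].
#'
#' @inheritParams fit_sinusoid
#' @inheritParams standardize
#' @return A `feature_matrix`.
#' @export
preprocess_recording <- function(recording, features = 2, scaler = NULL,
                                 initial_frequency = NULL) {
  fit <- fit_sinusoid(recording, initial_frequency = initial_frequency)
  cyc <- condense(recording, fit)
  fm <- standardize(cyc, scaler = scaler, features = features)
  fm$fit <- fit
  fm
}

#' Pool feature matrices from several recordings
#'
#' Row-binds per-recording feature matrices into one training set. If the
#' heart-rate axis `Z3` is present it is standardized here, across the pooled
#' recordings (it is constant within any one recording).
#'
#' @param fms List of `feature_matrix` objects with identical columns.
#' @return A `feature_matrix` covering all rows.
#' @export
pool_features <- function(fms) {
  stopifnot(length(fms) >= 1, all(vapply(fms, inherits, TRUE, "feature_matrix")))
  cols <- lapply(fms, function(f) colnames(f$Z))
  if (length(unique(vapply(cols, paste, "", collapse = ","))) != 1)
    stop_input("feature matrices have differing columns; cannot pool")
  Z <- do.call(rbind, lapply(fms, `[[`, "Z"))
  if ("Z3" %in% colnames(Z)) {
    s <- sqrt(mean((Z[, "Z3"] - mean(Z[, "Z3"]))^2))
    if (s == 0)
      stop_flowmci("flowmci_standardize_error",
                   paste("zero variance on axis Z3 across recordings",
                         "(constant pump rate); use features = 2"))
    Z[, "Z3"] <- (Z[, "Z3"] - mean(Z[, "Z3"])) / s
  }
  structure(
    list(Z = Z, scaler = list(own = TRUE, pooled = TRUE), n = nrow(Z),
         heart_rate = mean(vapply(fms, `[[`, 0, "heart_rate")),
         period = mean(vapply(fms, `[[`, 0, "period")),
         anchor = "sinusoid minimum"),
    class = "feature_matrix"
  )
}
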