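# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# Small, fast simulator config for unit tests (5 cycles at 60 Hz).
test_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 300L, noise_sd = 0, closure_reflux_volume = 0,
         seed = 123L),
    list(...))
  do.call(simulation_config, args)
}

# Deterministic 2-D blob training sets for SVM tests.
random_blob <- function(l, seed, spread = 1) {
  set.seed(seed)
  cbind(rnorm(l, 0, spread), rnorm(l, 0, spread))
}

# --- Independent oracle: dense grid search over frequency with per-frequency
# linear least squares for (A, phi, b). a*sin + c*cos + b is linear given f.
grid_fit_sinusoid <- function(t, y, f_grid) {
  best <- list(sse = Inf)
  for (f in f_grid) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
    beta <- qr.coef(qr(X), y)
    r <- y - X %*% beta
    sse <- sum(r^2)
    if (sse < best$sse)
      best <- list(f = f, sse = sse, A = sqrt(beta[1]^2 + beta[2]^2),
                   phi = atan2(beta[2], beta[1]) %% (2 * pi), b = beta[3])
  }
  best
}

# --- Independent oracle: exact one-sided rank-sum p-value by complete
# enumeration of all rank assignments (no ties assumed).
enumerate_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n)])
  all_sets <- utils::combn(n + m, n)
  w_all <- colSums(matrix(seq_len(n + m)[all_sets], nrow = n))
  mean(w_all >= w_obs)
}

# --- Independent oracle: generic QP solver (scipy trust-constr) on the
# one-class dual. problems: list of list(K = matrix, C = scalar).
solve_qp_oracle <- function(problems) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  jsonlite::write_json(
    lapply(problems, function(p)
      list(K = p$K, C = jsonlite::unbox(p$C))),
    infile, digits = NA)
  status <- system2("python",
                    c(test_path("qp_oracle.py"), infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("qp_oracle.py failed with status ", status)
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

dual_objective <- function(alpha, K) 0.5 * sum(alpha * (K %*% alpha))

kernel_matrix <- function(X, gamma) {
  d2 <- as.matrix(dist(X))^2
  exp(-gamma * d2)
}
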