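test_that("RBF kernel basics", {
  set.seed(1)
  x <- rnorm(3); y <- rnorm(3)
  expect_equal(rbf_kernel(x, x, gamma = 7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 7), exp(-7))
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(rbf_kernel(a, b, 2.3), rbf_kernel(b, a, 2.3))
    expect_gt(rbf_kernel(a, b, 2.3), 0)
    expect_lte(rbf_kernel(a, b, 2.3), 1)
  }
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1),
               class = "flowmci_input_error")
  expect_error(rbf_kernel(x, x, gamma = 0), class = "flowmci_input_error")
})

test_that("unit-square training matches the generic QP oracle", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  m <- ocsvm_train(X, nu = 0.5, gamma = 1)
  oracle <- solve_qp_oracle(list(list(K = kernel_matrix(X, 1),
                                      C = 1 / (0.5 * 4))))[[1]]
  expect_equal(m$dual_objective, oracle$objective, tolerance = 1e-6)
  # all four corners are equivalent by symmetry: alpha = 1/4 each
  expect_equal(m$alpha, unlist(oracle$alpha), tolerance = 1e-6)
  expect_equal(m$alpha, rep(0.25, 4), tolerance = 1e-6)
})

test_that("dual constraints hold after any successful training run", {
  for (seed in 1:4) {
    l <- 40
    nu <- c(0.1, 0.25, 0.5, 0.9)[seed]
    m <- ocsvm_train(random_blob(l, seed), nu = nu, gamma = 2)
    C <- 1 / (nu * l)
    expect_lt(abs(sum(m$alpha) - 1), 1e-8)
    expect_true(all(m$alpha >= -1e-12 & m$alpha <= C + 1e-12))
    # support vectors are exactly the rows retained in the model
    expect_true(all(m$alpha > 0))
  }
})

test_that("decision function vanishes on margin SVs and decays to -rho", {
  l <- 60
  m <- ocsvm_train(random_blob(l, 7), nu = 0.2, gamma = 1)
  C <- 1 / (0.2 * l)
  margin <- which(m$alpha > C * 1e-4 & m$alpha < C * (1 - 1e-4))
  expect_gt(length(margin), 0)
  d <- ocsvm_decision(m, m$support_vectors[margin, , drop = FALSE])
  expect_true(all(abs(d) < 1e-5))
  # far probe: all kernel terms vanish, decision -> -rho < 0
  far <- ocsvm_decision(m, c(1e6, 1e6))
  expect_equal(far, -m$rho, tolerance = 1e-12)
  expect_gt(m$rho, 0)
  expect_lt(far, 0)
  # batch evaluation equals per-row evaluation
  probes <- random_blob(10, 99)
  batch <- ocsvm_decision(m, probes)
  single <- vapply(seq_len(10), function(i) ocsvm_decision(m, probes[i, ]), 0)
  expect_equal(batch, single, tolerance = 1e-12)
  expect_error(ocsvm_decision(m, c(1, 2, 3)), class = "flowmci_input_error")
})

test_that("predict applies the zero-as-inlier tie rule", {
  m <- ocsvm_train(random_blob(50, 3), nu = 0.2, gamma = 1)
  m2 <- m
  m2$rho <- 0  # force decision(far probe) == 0 exactly
  expect_identical(ocsvm_predict(m2, c(1e6, 1e6)), "inlier")
  expect_identical(ocsvm_predict(m, c(1e6, 1e6)), "outlier")
})

test_that("nu-property: outlier and support-vector fractions bracket nu", {
  for (nu in c(0.05, 0.1, 0.2, 0.5)) {
    for (gamma in c(1, 7)) {
      X <- random_blob(200, seed = round(100 * nu + gamma))
      m <- ocsvm_train(X, nu = nu, gamma = gamma)
      out_frac <- mean(ocsvm_predict(m, X) == "outlier")
      sv_frac <- length(m$alpha) / nrow(X)
      expect_lte(out_frac, nu + 2 / nrow(X))
      expect_gte(sv_frac, nu - 2 / nrow(X))
    }
  }
})

test_that("training score on baseline features is about 1 - nu", {
  fm <- preprocess_recording(generate_recording(
    simulation_config(noise_sd = 5, seed = 12L)))
  m <- ocsvm_train(fm, nu = 0.05, gamma = 7)
  expect_equal(m$training_score, 0.95, tolerance = 0.02)
  expect_identical(m$training_score, ocsvm_score(m, fm))
  # an all-distant probe set scores 0
  far <- matrix(1e5, nrow = 5, ncol = 2)
  expect_equal(ocsvm_score(m, far), 0)
  expect_error(ocsvm_score(m, matrix(0, 0, 2)), class = "flowmci_input_error")
})

test_that("predictions are invariant to training-row permutation", {
  X <- random_blob(80, 17)
  m1 <- ocsvm_train(X, nu = 0.15, gamma = 2)
  set.seed(4)
  m2 <- ocsvm_train(X[sample(80), ], nu = 0.15, gamma = 2)
  probes <- as.matrix(expand.grid(seq(-3, 3, length.out = 15),
                                  seq(-3, 3, length.out = 15)))
  expect_equal(ocsvm_decision(m1, probes), ocsvm_decision(m2, probes),
               tolerance = 1e-6)
})

test_that("gamma sweeps reproduce the regularization trends", {
  fm <- preprocess_recording(generate_recording(
    simulation_config(noise_sd = 5, seed = 5L, n_samples = 480L)))
  gammas <- c(0.1, 1, 7, 50)
  n_grid <- 30
  grid_1d <- seq(-3, 3, length.out = n_grid)
  probes <- as.matrix(expand.grid(grid_1d, grid_1d))
  scores <- numeric(length(gammas))
  areas <- numeric(length(gammas))
  rough <- numeric(length(gammas))
  for (i in seq_along(gammas)) {
    m <- ocsvm_train(fm, nu = 0.1, gamma = gammas[i])
    scores[i] <- m$training_score
    d <- ocsvm_decision(m, probes)
    areas[i] <- mean(ocsvm_predict(m, probes) == "inlier")
    # surface roughness: variation between adjacent grid points relative to
    # the overall variation; a smooth (regularized) surface scores low
    dm <- matrix(d, n_grid, n_grid)
    rough[i] <- sd(diff(dm)) / sd(dm)
  }
  expect_gte(scores[4], scores[1])          # large gamma drives score up
  expect_lt(areas[4], areas[1])             # probe-grid inlier area shrinks
  expect_lt(rough[1], rough[4])             # small gamma = smoother surface
  expect_true(all(diff(rough) > 0))
})

test_that("infeasible parameters raise parameter errors", {
  X <- random_blob(10, 1)
  expect_error(ocsvm_train(X, nu = 0, gamma = 1),
               class = "flowmci_input_error")
  expect_error(ocsvm_train(X, nu = 1.2, gamma = 1),
               class = "flowmci_input_error")
  expect_error(ocsvm_train(X, nu = 0.05, gamma = 1),  # l < 1/nu
               class = "flowmci_input_error")
  expect_error(ocsvm_train(X, nu = 0.5, gamma = -1),
               class = "flowmci_input_error")
})

test_that("SMO agrees with the QP oracle on random problems", {
  # smaller sibling of the acceptance sweep: 6 random sets
  set.seed(2024)
  cases <- data.frame(l = sample(10:60, 6, replace = TRUE),
                      nu = sample(c(0.1, 0.5), 6, replace = TRUE),
                      gamma = sample(c(0.5, 5), 6, replace = TRUE))
  problems <- list()
  models <- list()
  for (i in seq_len(nrow(cases))) {
    X <- random_blob(cases$l[i], seed = 300 + i)
    models[[i]] <- ocsvm_train(X, nu = cases$nu[i], gamma = cases$gamma[i])
    problems[[i]] <- list(K = kernel_matrix(X, cases$gamma[i]),
                          C = 1 / (cases$nu[i] * cases$l[i]))
  }
  oracle <- solve_qp_oracle(problems)
  for (i in seq_len(nrow(cases)))
    expect_lt(abs(models[[i]]$dual_objective - oracle[[i]]$objective), 1e-6)
})
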