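test_that("gaussian_rbf peaks at the center, is symmetric and rejects bad spreads", {
  expect_identical(gaussian_rbf(5, 5, 3), 1)
  for (sig in c(0.5, 2, 7)) {
    expect_equal(gaussian_rbf(10 + sig, 10, sig), exp(-0.5))
    d <- 1:5
    expect_equal(gaussian_rbf(10 + d, 10, sig), gaussian_rbf(10 - d, 10, sig))
  }
  expect_error(gaussian_rbf(1, 1, 0), class = "aiqp_invalid_parameter")
  expect_error(gaussian_rbf(1, 1, -2), class = "aiqp_invalid_parameter")
})

test_that("design_matrix evaluates RBF columns on the sample grid", {
  phi <- design_matrix(3, 2, 1)
  expect_equal(as.vector(phi), c(exp(-0.5), 1, exp(-0.5)))

  # rank-deficient limit: very wide RBFs flatten to all-ones columns
  phi2 <- design_matrix(4, c(1, 4), 1e8)
  expect_true(all(abs(phi2 - 1) < 1e-12))

  phi3 <- design_matrix(200, c(50, 100, 150), 10)
  expect_equal(apply(phi3, 2, which.max), c(50, 100, 150))
  expect_equal(unname(phi3[cbind(c(50, 100, 150), 1:3)]), rep(1, 3))

  expect_error(design_matrix(10, 11, 2), class = "aiqp_invalid_parameter")
  expect_error(design_matrix(10, 0, 2), class = "aiqp_invalid_parameter")
})

test_that("solve_weights minimizes SSE with residual orthogonal to the design", {
  p <- 32
  phi1 <- design_matrix(p, 10, 3)
  w <- solve_weights(phi1, 3 * phi1[, 1])
  expect_equal(w, 3, tolerance = 1e-12)

  expect_equal(solve_weights(phi1, rep(0, p)), 0)

  # normal-equations oracle on a well-conditioned random instance
  set.seed(41)
  phi <- design_matrix(p, c(5, 12, 20, 28), 4)
  y <- rnorm(p)
  w4 <- solve_weights(phi, y)
  w_oracle <- solve(crossprod(phi), crossprod(phi, y))
  expect_equal(w4, as.vector(w_oracle), tolerance = 1e-8)
  resid <- y - phi %*% w4
  for (j in 1:4)
    expect_lt(abs(sum(phi[, j] * resid)),
              1e-8 * sqrt(sum(y^2)) * sqrt(sum(phi[, j]^2)))

  expect_error(solve_weights(phi, rnorm(p + 1)), class = "aiqp_invalid_input")
})

test_that("OLS picks the generating center first when y is a single RBF column", {
  p <- 40
  y <- design_matrix(p, 17, 3)[, 1]
  sel <- ols_select_centers(y, 3, 1)
  expect_identical(sel$model$centers, 17L)
  expect_equal(sel$trace$err_ratios[1], 1, tolerance = 1e-9)
  fit <- fit_rbfnn(y, 1, 3)
  expect_lt(fit$aqr, 1e-9)
})

test_that("OLS selection matches the exhaustive refit-per-candidate greedy oracle", {
  # triangular ramp, the hand-sized deterministic instance
  p <- 16
  y <- c(1:8, 8:1)
  sel <- ols_select_centers(y, 2, 3)
  expect_identical(sel$model$centers, oracle_greedy_centers(y, 2, 3))

  # random instances across sizes and spreads
  set.seed(7)
  for (i in 1:25) {
    p <- sample(8:32, 1)
    sigma <- sample(c(1, 2, 4), 1)
    M <- sample(1:min(6, p), 1)
    y <- rnorm(p)
    sel <- ols_select_centers(y, sigma, M)
    expect_identical(sel$model$centers, oracle_greedy_centers(y, sigma, M),
                     info = sprintf("p=%d sigma=%g M=%d i=%d", p, sigma, M, i))
  }
})

test_that("error reduction ratios are energy fractions and scale invariant", {
  set.seed(11)
  y <- rnorm(24)
  sel <- ols_select_centers(y, 2, 5)
  expect_true(all(sel$trace$err_ratios >= 0 & sel$trace$err_ratios <= 1))
  expect_lte(sum(sel$trace$err_ratios), 1 + 1e-12)

  for (alpha in c(0.5, 3, -2)) {
    sel_a <- ols_select_centers(alpha * y, 2, 5)
    expect_identical(sel_a$model$centers, sel$model$centers)
    expect_equal(sel_a$trace$err_ratios, sel$trace$err_ratios, tolerance = 1e-9)
  }
})

test_that("orthogonal decomposition conserves signal energy", {
  set.seed(13)
  for (i in 1:10) {
    p <- sample(16:64, 1)
    y <- rnorm(p)
    fit <- fit_rbfnn(y, sample(2:8, 1), sample(c(1, 2, 4), 1))
    expect_lt(energy_relerr(fit, y), 1e-9)
  }
  qrs <- simulate_qrs()
  fit <- fit_rbfnn(qrs, 20, 10)
  expect_lt(energy_relerr(fit, qrs), 1e-9)
})

test_that("SSE is non-increasing along the nested OLS center sequence", {
  qrs <- simulate_qrs(qrs_spec(p = 64, lobes = cbind(
    amplitude = c(-200, 1500, -400), center = c(22, 32, 44), width = c(3, 4, 3))))
  y <- qrs$samples
  sses <- vapply(1:12, function(m) fit_rbfnn(y, m, 3)$sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-9 * sses[1]))
})

test_that("fit_rbfnn recovers exact RBF mixtures and interpolates at M = p", {
  p <- 64
  phi <- design_matrix(p, c(15, 30, 50), 4)
  y <- phi %*% c(2, -1, 0.5)
  fit <- fit_rbfnn(as.vector(y), 3, 4)
  expect_lt(fit$aqr, 1e-6)

  # one neuron per sample: Gaussian interpolation on distinct centers.
  # Narrow RBFs interpolate even rough signals; wider ones need the signal
  # to be as smooth as the basis for the system to stay well conditioned.
  set.seed(5)
  fit2 <- fit_rbfnn(rnorm(p) + 5, p, 2)
  expect_identical(fit2$model$M, as.integer(p))
  expect_lt(fit2$aqr, 1e-4)
  smooth <- as.vector(y) + 3
  fit3 <- fit_rbfnn(smooth, p, 5)
  expect_lt(fit3$aqr, 1e-4)
})

test_that("residuals scale linearly with the signal while AQR and centers are invariant", {
  qrs <- simulate_qrs()
  f1 <- fit_rbfnn(qrs, 20, 10)
  f2 <- fit_rbfnn(2 * qrs$samples, 20, 10)
  expect_identical(f2$model$centers, f1$model$centers)
  expect_equal(f2$residual, 2 * f1$residual, tolerance = 1e-9)
  expect_equal(f2$aiqp, 2 * f1$aiqp, tolerance = 1e-9)   # error RMS doubles
  expect_equal(f2$aqr, f1$aqr, tolerance = 1e-9)
})

test_that("residual after fitting is orthogonal to every design column", {
  set.seed(19)
  y <- rnorm(48)
  fit <- fit_rbfnn(y, 6, 2)
  phi <- design_matrix(48, fit$model$centers, 2)
  rel <- abs(crossprod(phi, fit$residual)) /
    (sqrt(colSums(phi^2)) * sqrt(sum(y^2)))
  expect_true(all(rel < 1e-8))
})

test_that("degenerate inputs raise classed errors", {
  expect_error(ols_select_centers(rep(0, 10), 2, 2),
               class = "aiqp_degenerate_signal")
  expect_error(ols_select_centers(rnorm(10), 2, 11),
               class = "aiqp_invalid_parameter")
  # huge spread: all columns identical, selection cannot proceed past step 1
  err <- tryCatch(ols_select_centers(rnorm(16), 1e9, 3),
                  aiqp_partial_selection = function(e) e)
  expect_s3_class(err, "aiqp_partial_selection")
  expect_equal(err$n_placed, 1L)
  expect_length(err$partial$model$centers, 1)
})
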