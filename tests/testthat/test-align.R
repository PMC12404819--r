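aligned_default <- function(seed, n_families = 40, mod = NULL) {
  pars <- small_sim_params(seed = seed, n_families = n_families, n_extra = 0)
  if (!is.null(mod)) { pars <- modifyList(pars, mod); class(pars) <- "sim_params" }
  sim <- simulate_landmarks(pars)
  list(fit = align_to_reference(gpa(sim$configs), sim$truth$mean_shape),
       sim = sim)
}

test_that("a null latitudinal effect yields a near-zero shape vector", {
  null <- aligned_default(seed = 61, n_families = 200,
                          mod = list(beta_latitude = rep(0, 16)))
  bl_null <- fit_shape_regression(null$fit, null$sim$design, "latitude")
  real <- aligned_default(seed = 61, n_families = 200)
  bl_real <- fit_shape_regression(real$fit, real$sim$design, "latitude")
  # under the null the estimate is pure sampling noise, well below the
  # signal recovered from the same design with the effect present
  expect_lt(bl_null$norm, 0.5 * bl_real$norm)
})

test_that("the thermal shape vector is recovered in direction and scale", {
  d <- aligned_default(seed = 62, n_families = 100)
  bt <- fit_shape_regression(d$fit, d$sim$design, "temperature")
  truth <- d$sim$truth$params$beta_temperature
  expect_gte(vector_correlation(bt$beta, truth), 0.95)
  expect_lt(abs(bt$norm / sqrt(sum(truth^2)) - 1), 0.25)
})

test_that("shape regressions are invariant to shifting the covariate origin", {
  d <- aligned_default(seed = 63, n_families = 40)
  b1 <- fit_shape_regression(d$fit, d$sim$design, "latitude")
  design2 <- d$sim$design
  design2$latitude <- design2$latitude + 100
  coords2 <- d$fit$coords
  coords2$latitude <- NULL
  b2 <- fit_shape_regression(coords2, design2, "latitude")
  expect_equal(b2$beta, b1$beta, tolerance = 1e-8)
})

test_that("constant covariates are a rank error, not a silent zero", {
  d <- aligned_default(seed = 64, n_families = 10)
  design2 <- d$sim$design
  design2$latitude <- 42
  coords2 <- d$fit$coords; coords2$latitude <- NULL
  expect_error(fit_shape_regression(coords2, design2, "latitude"),
               "does not vary")
})

test_that("e_beta is the Rayleigh quotient of the trace-scaled matrix", {
  M <- random_psd(6, seed = 65)
  e <- eigen(M / sum(diag(M)), symmetric = TRUE)
  expect_equal(e_beta(e$vectors[, 1], M), e$values[1], tolerance = 1e-12)
  # isotropy: any direction captures 1/p
  b <- rnorm(6)
  expect_equal(e_beta(b, diag(6)), 1 / 6, tolerance = 1e-12)
  # hand computation
  expect_equal(e_beta(c(1, 1), diag(c(3, 1)) / 4), 0.5)
  # scale invariance and spectral bounds
  expect_equal(e_beta(3.2 * b, M), e_beta(b, M))
  vals <- vapply(1:50, function(i) e_beta(rnorm(6), M), numeric(1))
  expect_true(all(vals >= min(e$values) - 1e-12 &
                    vals <= max(e$values) + 1e-12))
})

test_that("e_beta sums to one over any orthonormal basis", {
  M <- random_psd(7, seed = 66)
  Q <- qr.Q(qr(matrix(rnorm(49), 7, 7)))
  expect_equal(sum(vapply(1:7, function(j) e_beta(Q[, j], M), numeric(1))),
               1, tolerance = 1e-12)
})

test_that("e_beta_test flags alignment with dmax and respects the null", {
  M <- random_psd(16, seed = 67, eigenvalues = c(8, 4, 2, rep(0.5, 13)))
  dmax <- reference_basis(M, 1)[, 1]
  hit <- e_beta_test(dmax, M, n_resamples = 9999, seed = 1)
  expect_lte(hit$p_value, 0.01)
  expect_equal(hit$observed, e_beta(dmax, M))
  # an observed value below the null median must give p > 0.5
  vmin <- eigen(M, symmetric = TRUE)$vectors[, 16]
  low <- e_beta_test(vmin, M, n_resamples = 1999, seed = 2)
  expect_gt(low$p_value, 0.5)
})

test_that("e_beta_test p-values are uniform under an isotropic null", {
  M <- random_psd(16, seed = 68)
  ps <- withr::with_seed(69, vapply(1:200, function(i) {
    b <- rnorm(16)
    e_beta_test(b, M, n_resamples = 999, seed = i,
                null = "isotropic")$p_value
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("angle_test recognizes identity and closed-form angles", {
  b <- rnorm(8)
  self <- angle_test(b, b, n_resamples = 999, seed = 3)
  expect_equal(self$observed, 0)
  # minimal up to chance collisions where both permutations coincide
  expect_lte(self$p_value, 3 / 1000)
  t45 <- angle_test(c(1, 0), c(1, 1), n_resamples = 999, seed = 4)
  expect_equal(t45$observed, 45, tolerance = 1e-9)
})

test_that("the isotropic null angle distribution matches its expectation", {
  b <- rnorm(16); v <- rnorm(16)
  at <- angle_test(b, v, n_resamples = 20000, seed = 5, null = "isotropic")
  # oracle for the mean angle between random directions in 16 dimensions
  oracle <- withr::with_seed(990, {
    mean(vapply(1:20000, function(i) {
      u1 <- rnorm(16); u2 <- rnorm(16)
      acos(abs(sum(u1 * u2)) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
    }, numeric(1)))
  })
  expect_lt(abs(mean(at$null_samples) - oracle), 1)
})
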