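test_that("reference_basis returns leading eigenvectors with fixed signs", {
  M <- diag(c(3, 2, 1))
  K <- reference_basis(M, 2)
  expect_equal(abs(K), cbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-12)
  expect_equal(crossprod(K), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  # sign convention survives an eigenvector sign flip in the input
  A <- random_psd(5, seed = 41)
  e <- eigen(A, symmetric = TRUE)
  A2 <- (-e$vectors) %*% (e$values * t(-e$vectors))
  expect_equal(reference_basis(A, 3), reference_basis(A2, 3),
               tolerance = 1e-9)
  expect_error(reference_basis(random_psd(6, eigenvalues = c(3, 2, 1, 0, 0, 0)),
                               5), "rank")
})

test_that("subspace comparison identities hold exactly", {
  A <- random_psd(8, seed = 42)
  K <- reference_basis(A, 6)
  self <- krzanowski_compare(A, A, K)
  expect_equal(self$r, 1)
  expect_equal(self$b, 1)
  # shared eigenvectors, squared eigenvalues: log-variances double exactly
  e <- eigen(A, symmetric = TRUE)
  A2 <- e$vectors %*% (e$values^2 * t(e$vectors))
  cmp <- krzanowski_compare(A, A2, e$vectors[, 1:6])
  expect_equal(cmp$r, 1, tolerance = 1e-9)
  expect_equal(cmp$b, 2, tolerance = 1e-9)
})

test_that("degenerate and invalid projections are handled explicitly", {
  A <- diag(c(4, 2, 1))
  B <- diag(c(2, 2, 2))
  cmp <- krzanowski_compare(A, B, diag(3))
  expect_true(cmp$degenerate)
  expect_equal(cmp$r, 0)
  # non-positive projected variance -> error, not NaN
  C <- diag(c(1, 1, 0))
  expect_error(krzanowski_compare(A, C, diag(3)), "Non-positive")
  expect_error(krzanowski_compare(A, B, matrix(1, 3, 2)), "orthonormal")
})

test_that("vector correlation and angle obey their closed forms", {
  expect_equal(vector_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(vector_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(vector_correlation(c(1, 0), c(1, 1)), sqrt(0.5),
               tolerance = 1e-9)
  expect_equal(vector_angle(c(1, 0), c(1, 1)), 45, tolerance = 1e-9)
  # scale invariance, including sign flips
  v1 <- rnorm(10); v2 <- rnorm(10)
  expect_equal(vector_correlation(v1, v2),
               vector_correlation(-3.7 * v1, 0.01 * v2))
  expect_error(vector_correlation(v1, rep(0, 10)), "zero vector")
})

test_that("random skewers is exact on identical matrices and symmetric", {
  A <- random_psd(6, seed = 43)
  expect_equal(random_skewers(A, A, 500, seed = 1)$mean_response_correlation,
               1, tolerance = 1e-12)
  expect_equal(random_skewers(diag(6), diag(6), 200,
                              seed = 2)$mean_response_correlation, 1)
  B <- random_psd(6, seed = 44)
  ab <- random_skewers(A, B, 2000, seed = 3)
  ba <- random_skewers(B, A, 2000, seed = 3)
  expect_equal(ab$mean_response_correlation, ba$mean_response_correlation)
})

test_that("skewers mean matches an independent Monte-Carlo oracle", {
  p <- 16
  A <- diag(p)
  B <- diag(c(10, rep(1, p - 1)))
  got <- random_skewers(A, B, 10000, seed = 5)$mean_response_correlation
  # oracle: direct per-vector loop, different RNG stream, same sampling
  # convention (components uniform on [-1, 1], normalized)
  oracle <- withr::with_seed(987, {
    mean(vapply(seq_len(20000), function(i) {
      b <- runif(p, -1, 1); b <- b / sqrt(sum(b^2))
      ra <- A %*% b; rb <- B %*% b
      abs(sum(ra * rb)) / sqrt(sum(ra^2) * sum(rb^2))
    }, numeric(1)))
  })
  expect_lt(abs(got - oracle), 0.01)

  # the Gaussian-sphere option against its own oracle
  got_g <- random_skewers(A, B, 10000, seed = 5,
                          method = "gaussian")$mean_response_correlation
  oracle_g <- withr::with_seed(988, {
    mean(vapply(seq_len(20000), function(i) {
      b <- rnorm(p); b <- b / sqrt(sum(b^2))
      ra <- A %*% b; rb <- B %*% b
      abs(sum(ra * rb)) / sqrt(sum(ra^2) * sum(rb^2))
    }, numeric(1)))
  })
  expect_lt(abs(got_g - oracle_g), 0.01)
})

test_that("skewers similarity is monotone along matrix interpolation", {
  A <- random_psd(8, seed = 45)
  B <- random_psd(8, seed = 46)
  rs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(t) {
    M <- (1 - t) * B + t * A
    random_skewers(A, M, 4000, seed = 7)$mean_response_correlation
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_equal(rs[5], 1, tolerance = 1e-12)
})

test_that("REML-MVN draws are centered on the estimate", {
  sim <- simulate_landmarks(small_sim_params(seed = 47, n_families = 40,
                                             n_extra = 0))
  fit <- align_to_reference(gpa(sim$configs), sim$truth$mean_shape)
  D <- estimate_D(fit, sim$design)
  # D's null directions hover at zero, so most draws are clipped (warned)
  draws <- suppressWarnings(reml_mvn_resample(D, n_samples = 4000, seed = 8))
  avg <- Reduce(`+`, draws) / length(draws)
  # clipping adds a small positive bias; compare against the clipped scale
  expect_lt(norm(avg - D$values, "F") / norm(D$values, "F"), 0.1)
  expect_true(attr(draws, "n_clipped") >= 0)
})

test_that("zero sampling covariance returns the estimate unchanged", {
  Y <- withr::with_seed(48, matrix(rnorm(2000 * 3), 2000, 3) %*%
                          diag(c(2, 1, 0.5)))
  fm <- fit_factor_model(Y, 1, n_starts = 1)
  fm$param_sampling_cov <- fm$param_sampling_cov * 0
  draws <- reml_mvn_resample(fm, n_samples = 50, seed = 9)
  for (d in draws[1:5]) {
    expect_equal(d, devomatrix:::factor_model_target(fm), tolerance = 1e-12)
  }
})

test_that("BCa reduces to the percentile interval when z0 = a = 0", {
  x <- withr::with_seed(50, rnorm(4001))
  obs <- median(x)
  got <- bca_interval(x, obs, jackknife_values = NULL, level = 0.95)
  expect_equal(attr(got, "z0"), 0, tolerance = 0.002)
  plain <- quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  expect_equal(as.numeric(got), plain, tolerance = 2e-3)
})

test_that("BCa matches the textbook formula on skewed samples", {
  x <- withr::with_seed(51, rexp(2000))
  obs <- 0.8
  jack <- withr::with_seed(52, rexp(60))
  got <- bca_interval(x, obs, jackknife_values = jack, level = 0.9)
  # independent reference implementation
  B <- length(x)
  z0 <- qnorm(sum(x < obs) / B)
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  al <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  ref <- quantile(x, c(al(qnorm(0.05)), al(qnorm(0.95))), type = 7,
                  names = FALSE)
  expect_equal(as.numeric(got), as.numeric(ref), tolerance = 1e-12)
})

test_that("degenerate BCa inputs collapse to the observed value", {
  got <- bca_interval(rep(0.4, 500), 0.4)
  expect_equal(as.numeric(got), c(0.4, 0.4))
})

test_that("subspace confidence intervals cover the point estimate", {
  sim <- simulate_landmarks(small_sim_params(seed = 53, n_families = 40,
                                             n_extra = 0))
  fit <- align_to_reference(gpa(sim$configs), sim$truth$mean_shape)
  D <- estimate_D(fit, sim$design)
  G <- estimate_G(fit, sim$design)
  K <- reference_basis(estimate_P(fit, sim$design), 6)
  cmp <- suppressWarnings(
    krzanowski_compare_ci(D, G, K, n_samples = 400, seed = 10))
  expect_true(cmp$ci_r[1] <= cmp$r && cmp$r <= cmp$ci_r[2])
  expect_true(cmp$ci_b[1] <= cmp$b && cmp$b <= cmp$ci_b[2])
  expect_true(all(abs(cmp$samples$r) <= 1, na.rm = TRUE))
})
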