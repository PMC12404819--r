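# plain-matrix responses from an exact low-rank-plus-noise covariance;
# pass `L` to keep the true loadings fixed across replicates
factor_responses <- function(n, p, m, seed = 1, noise = 0.1, L = NULL) {
  withr::with_seed(seed, {
    if (is.null(L)) L <- matrix(rnorm(p * m), p, m)
    Z <- matrix(rnorm(n * m), n, m)
    Z %*% t(L) + matrix(rnorm(n * p, 0, noise), n, p)
  })
}

test_that("the restricted likelihood is monotone in the number of factors", {
  Y <- factor_responses(400, 8, 2, seed = 31)
  fits <- lapply(1:4, function(m)
    fit_factor_model(Y, m, n_starts = 2, compute_sampling_cov = FALSE))
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-4))
  for (f in fits) expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params)
})

test_that("the full-rank factor model reproduces the unstructured estimate", {
  Y <- factor_responses(500, 6, 6, seed = 32, noise = 0.3)
  S <- cov(Y)
  fm <- fit_factor_model(Y, 6, n_starts = 2, compute_sampling_cov = FALSE)
  C <- reconstruct_cov(fm)
  expect_lt(norm(C$values - S, "F") / norm(S, "F"), 5e-3)
})

test_that("reconstruction round-trips an exact low-rank decomposition", {
  M <- random_psd(7, eigenvalues = c(5, 2, 1, 0, 0, 0, 0), seed = 33)
  e <- eigen(M, symmetric = TRUE)
  L <- e$vectors[, 1:3] %*% diag(sqrt(e$values[1:3]))
  model <- structure(list(loadings_reduced = L, loadings = L,
                          specific_variances = rep(0, 7), p = 7L, m = 3L,
                          basis = NULL, label = "other",
                          n_units = NA_integer_),
                     class = "factor_model")
  C <- reconstruct_cov(model, include_specific = FALSE)
  expect_equal(C$values, M, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(C$selected_rank, 3L)
  # reconstructed matrices are symmetric PSD by construction
  expect_gte(min(eigen(C$values, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("sequential AIC rank selection finds a planted rank-2 structure", {
  hits <- vapply(1:20, function(s) {
    Y <- factor_responses(1500, 8, 2, seed = s, noise = 0.15)
    rs <- select_rank(Y, m_max = 5, n_starts = 2, seed = s)
    rs$m_star
  }, numeric(1))
  expect_gte(mean(hits == 2), 0.9)
})

test_that("rank selection is trivially bounded by m_max", {
  Y <- factor_responses(200, 6, 3, seed = 34)
  rs <- select_rank(Y, m_max = 1, n_starts = 1)
  expect_equal(rs$m_star, 1L)
  expect_equal(nrow(rs$table), 1L)
})

test_that("factor models on asymmetry strata match the moment estimate", {
  pars <- small_sim_params(seed = 35, n_families = 60, n_extra = 0)
  sim <- simulate_landmarks(pars)
  fit <- align_to_reference(gpa(sim$configs), sim$truth$mean_shape)
  st <- asymmetry_strata(fit, sim$design)
  fm <- fit_factor_model(st, m = st$p, n_starts = 1,
                         compute_sampling_cov = FALSE)
  Dfa <- reconstruct_cov(fm)
  Dm <- estimate_D(fit, sim$design)
  expect_lt(norm(Dfa$values - Dm$values, "F") / norm(Dm$values, "F"), 0.05)
})

test_that("the reported sampling covariance matches replicate scatter", {
  # many replicates of a small factor problem with a fixed truth: the
  # empirical variance of the reconstructed covariance entries should match
  # the REML-MVN spread within a factor of two on the diagonal
  p <- 4L
  reps <- 150L
  L_true <- matrix(c(1, 0.8, 0.6, 0.4), p, 1)
  ests <- matrix(NA_real_, reps, p)
  fit1 <- NULL
  for (i in seq_len(reps)) {
    Y <- factor_responses(300, p, 1, seed = 500 + i, noise = 0.5, L = L_true)
    fm <- fit_factor_model(Y, 1, n_starts = 1,
                           compute_sampling_cov = i == 1L)
    if (i == 1L) fit1 <- fm
    ests[i, ] <- diag(reconstruct_cov(fm)$values)
  }
  draws <- reml_mvn_resample(fit1, n_samples = 2000, seed = 1)
  mvn_var <- apply(vapply(draws, diag, numeric(p)), 1, var)
  emp_var <- apply(ests, 2, var)
  ratio <- mvn_var / emp_var
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("non-convergence is flagged, never silent", {
  Y <- factor_responses(50, 6, 2, seed = 36)
  fm <- fit_factor_model(Y, 2, n_starts = 1, compute_sampling_cov = FALSE,
                         control = list(maxit = 2))
  expect_false(fm$converged)
})
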