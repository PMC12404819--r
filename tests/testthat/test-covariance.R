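aligned_small <- function(seed = 1, n_families = 20, n_extra = 0, mod = NULL) {
  pars <- small_sim_params(seed = seed, n_families = n_families,
                           n_extra = n_extra)
  if (!is.null(mod)) pars <- modifyList(pars, mod)
  class(pars) <- "sim_params"
  sim <- simulate_landmarks(pars)
  fit <- align_to_reference(gpa(sim$configs), sim$truth$mean_shape)
  list(fit = fit, sim = sim)
}

rel_frob <- function(A, B) norm(A - B, "F") / norm(B, "F")

test_that("moment and REML estimators agree on balanced designs", {
  d <- aligned_small(seed = 21, n_families = 50)
  Dm <- estimate_D(d$fit, d$sim$design, method = "moment")
  Dr <- estimate_D(d$fit, d$sim$design, method = "reml")
  expect_lt(rel_frob(Dr$values, Dm$values), 1e-6)
  Gm <- estimate_G(d$fit, d$sim$design, method = "moment")
  Gr <- estimate_G(d$fit, d$sim$design, method = "reml")
  expect_lt(rel_frob(Gr$values, Gm$values), 1e-6)
})

test_that("cov_matrix results satisfy their structural invariants", {
  d <- aligned_small(seed = 22, n_families = 25, n_extra = 10)
  for (est in list(estimate_D(d$fit, d$sim$design),
                   estimate_P(d$fit, d$sim$design),
                   estimate_G(d$fit, d$sim$design))) {
    M <- est$values
    expect_lt(max(abs(M - t(M))), 1e-12)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * est$trace)
    expect_lte(est$selected_rank, 2 * 8 - 4)
    expect_equal(est$trace, sum(diag(M)))
  }
})

test_that("a null developmental component is recovered as (near) zero", {
  d <- aligned_small(seed = 23, n_families = 250, mod = list(
    D_true = matrix(0, 16, 16)))
  Dh <- estimate_D(d$fit, d$sim$design)
  # compare against the scale of the true D in the standard design
  ref <- sum(diag(small_sim_params()$D_true))
  expect_lt(Dh$trace, 0.1 * ref)
})

test_that("a null genetic component is recovered as (near) zero", {
  d <- aligned_small(seed = 24, n_families = 100, mod = list(
    G_true = matrix(0, 16, 16)))
  Gh <- estimate_G(d$fit, d$sim$design)
  ref <- sum(diag(small_sim_params()$G_true))
  expect_lt(Gh$trace, 0.35 * ref)
})

test_that("P estimates the among-individual covariance G + E", {
  d <- aligned_small(seed = 25, n_families = 500)   # 2000 individuals
  Ph <- estimate_P(d$fit, d$sim$design)
  P_true <- d$sim$truth$P_true
  expect_lt(rel_frob(Ph$values, P_true), 0.25)
})

test_that("P is insensitive to the size of the adjusted fixed effects", {
  base <- aligned_small(seed = 26, n_families = 120)
  strong <- aligned_small(seed = 26, n_families = 120, mod = list(
    beta_temperature = 2 * small_sim_params()$beta_temperature))
  P1 <- estimate_P(base$fit, base$sim$design)
  P2 <- estimate_P(strong$fit, strong$sim$design)
  expect_lt(rel_frob(P2$values, P1$values), 0.05)
})

test_that("estimates are invariant to population relabeling and temperature recoding", {
  d <- aligned_small(seed = 27, n_families = 40)
  G1 <- estimate_G(d$fit, d$sim$design)
  design2 <- d$sim$design
  design2$population_id <- paste0("relabel_", design2$population_id)
  design2$temperature <- ifelse(design2$temperature == 19, 0, 1)
  coords2 <- d$fit$coords
  coords2$population_id <- NULL; coords2$temperature <- NULL
  G2 <- estimate_G(coords2, design2)
  expect_lt(rel_frob(G2$values, G1$values), 1e-10)
})

test_that("D and G recover the simulated truth at study scale", {
  errs <- sapply(1:5, function(s) {
    sim <- simulate_landmarks(default_sim_params(seed = 200 + s))
    fit <- align_to_reference(gpa(sim$configs), sim$truth$mean_shape)
    c(D = rel_frob(estimate_D(fit, sim$design)$values, sim$truth$params$D_true),
      G = rel_frob(estimate_G(fit, sim$design)$values, sim$truth$params$G_true))
  })
  expect_lt(median(errs["D", ]), 0.25)
  expect_lt(median(errs["G", ]), 0.35)
})

test_that("gmax is recovered from a hundred families of six", {
  pars <- small_sim_params(seed = 28, n_families = 100, n_extra = 0)
  pars$offspring_per_family <- 6L
  sim <- simulate_landmarks(pars)
  fit <- align_to_reference(gpa(sim$configs), sim$truth$mean_shape)
  Gh <- estimate_G(fit, sim$design)
  gmax_hat <- reference_basis(Gh, 1)[, 1]
  gmax_true <- sim$truth$eigen_G$vectors[, 1]
  expect_gte(vector_correlation(gmax_hat, gmax_true), 0.9)
})

test_that("measurement-error variances are estimated per variable", {
  d <- aligned_small(seed = 29, n_families = 60)
  err <- estimate_meas_error(d$fit)
  sigma_true <- d$sim$truth$params$sigma_meas^2
  ratio <- err$sigma2 / sigma_true
  expect_lt(max(abs(log(ratio))), log(2.5))
})

test_that("single-replicate data cannot separate measurement error", {
  d <- aligned_small(seed = 30, n_families = 10)
  once <- d$fit$coords[d$fit$coords$replicate == 1, ]
  expect_error(estimate_D(once, d$sim$design), "inestimable")
})
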