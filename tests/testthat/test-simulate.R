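test_that("default design reproduces the study dimensions", {
  pars <- default_sim_params(seed = 1)
  expect_equal(pars$k_landmarks, 8L)
  expect_equal(ncol(pars$G_true), 16L)
  ranks <- function(M) sum(eigen(M, symmetric = TRUE, only.values = TRUE)$values >
                             1e-8 * sum(diag(M)))
  expect_equal(ranks(pars$D_true), 7L)
  expect_equal(ranks(pars$G_true), 6L)

  sim <- simulate_landmarks(pars)
  expect_equal(nrow(sim$configs), 1736L)
  expect_equal(nrow(sim$design), 434L)
  expect_equal(validate_design(sim$configs)$n_records, 1736L)
})

test_that("broods are split evenly across the two rearing temperatures", {
  sim <- simulate_landmarks(small_sim_params(seed = 2))
  cg <- sim$design[sim$design$cohort == "common_garden", ]
  counts <- table(cg$family_id, cg$temperature)
  expect_true(all(counts == counts[1, 1]))
  expect_equal(sort(unique(cg$temperature)), c(19, 27))
})

test_that("the generator is a pure function of its seed", {
  pars <- small_sim_params(seed = 9)
  a <- simulate_landmarks(pars)
  b <- simulate_landmarks(pars)
  expect_identical(a$configs, b$configs)
  pars2 <- small_sim_params(seed = 10)
  c <- simulate_landmarks(pars2)
  expect_false(isTRUE(all.equal(cm(a$configs), cm(c$configs))))
})

test_that("invalid covariance inputs are rejected", {
  pars <- small_sim_params()
  bad <- pars$G_true
  bad[1, 2] <- bad[1, 2] + 1e-3   # asymmetric
  expect_error(do.call(sim_params, modifyList(unclass(pars), list(G_true = bad))),
               "symmetric")
  neg <- -diag(16)
  expect_error(do.call(sim_params, modifyList(unclass(pars), list(D_true = neg))),
               "positive semi-definite")
  expect_error(do.call(sim_params,
                       modifyList(unclass(pars), list(sigma_meas = rep(0, 4)))),
               "length p")
})

test_that("without developmental noise and measurement error the two sides agree", {
  pars <- small_sim_params(seed = 3, n_families = 10, n_extra = 0)
  pars$D_true <- matrix(0, 16, 16)
  pars$sigma_meas <- rep(0, 16)
  pars$DA_vector <- rep(0, 16)
  pars$nuisance <- list(rotate = FALSE, translate = 0, scale_jitter_sd = 0)
  sim <- simulate_landmarks(pars)
  m <- cm(reflect_configs(sim$configs, side = "left"))
  left <- m[sim$configs$side == "left" & sim$configs$replicate == 1, ]
  right <- m[sim$configs$side == "right" & sim$configs$replicate == 1, ]
  expect_equal(left, right, tolerance = 1e-12)

  fit <- gpa(sim$configs)
  an <- symmetry_anova(fit, n_permutations = 0)
  fa_prop <- an$table$proportion[an$table$term == "individual:side"]
  expect_lt(fa_prop, 1e-10)
})

test_that("realized family effects have the prescribed covariance", {
  pars <- small_sim_params(seed = 4, n_families = 2000, n_extra = 0)
  pars$offspring_per_family <- 2L
  sim <- simulate_landmarks(pars)
  emp <- cov(sim$truth$family_deviations)
  err <- norm(emp - pars$G_true, "F") / norm(pars$G_true, "F")
  expect_lt(err, 0.15)
})

test_that("side contrasts recover D and the directional asymmetry vector", {
  pars <- small_sim_params(seed = 5, n_families = 500, n_extra = 0)
  pars$sigma_meas <- rep(0, 16)
  pars$nuisance <- list(rotate = FALSE, translate = 0, scale_jitter_sd = 0)
  pars$size_distribution$sdlog <- 0   # fixed unit so raw coords are tangent
  sim <- simulate_landmarks(pars)
  m <- cm(reflect_configs(sim$configs, side = "left"))
  sizes <- exp(pars$size_distribution$meanlog)
  left <- m[sim$configs$side == "left" & sim$configs$replicate == 1, ] / sizes
  right <- m[sim$configs$side == "right" & sim$configs$replicate == 1, ] / sizes
  diffs <- right - left
  # mean difference estimates the DA vector
  expect_lt(sqrt(sum((colMeans(diffs) - pars$DA_vector)^2)) /
              sqrt(sum(pars$DA_vector^2)), 0.35)
  # covariance of (right - left)/sqrt(2) converges to D
  Demp <- cov(diffs) / 2
  expect_lt(norm(Demp - pars$D_true, "F") / norm(pars$D_true, "F"), 0.15)
})
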