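signed_area <- function(cfg) {
  x <- cfg[, 1L]; y <- cfg[, 2L]
  i2 <- c(seq_len(nrow(cfg))[-1L], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

test_that("reflection is an involution that flips chirality, not size", {
  configs <- tiny_configs(n = 2, reps = 1)
  twice <- reflect_configs(reflect_configs(configs))
  expect_equal(cm(twice), cm(configs))

  cfg0 <- matrix(as.numeric(cm(configs)[1, ]), ncol = 2)
  cfg1 <- matrix(as.numeric(cm(reflect_configs(configs))[1, ]), ncol = 2)
  expect_equal(signed_area(cfg1), -signed_area(cfg0))
  expect_equal(centroid_size(reflect_configs(configs)),
               centroid_size(configs))
})

test_that("GPA is invariant to nuisance rotation, translation and scale", {
  base <- matrix(c(0, 2, 1.1, 0.2, 0, 0.1, 1.5, 0.9), ncol = 2)
  rows <- withr::with_seed(11, lapply(1:40, function(i) {
    th <- runif(1, -pi, pi); s <- exp(rnorm(1, 0, 0.5))
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    cfg <- s * base %*% R + matrix(runif(2, -50, 50), 4, 2, byrow = TRUE)
    c(list(specimen_id = paste0("i", i), side = "right", replicate = 1L),
      setNames(as.list(c(cfg[, 1], cfg[, 2])), c(paste0("x", 1:4), paste0("y", 1:4))))
  }))
  configs <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  fit <- gpa(configs, reflect_side = "none")
  m <- cm(fit$coords)
  expect_lt(max(abs(sweep(m, 2, colMeans(m)))), 1e-8)
  # aligned records are centered with unit centroid size
  expect_lt(max(abs(rowSums(m[, 1:4]))), 1e-9)
  expect_lt(max(abs(rowSums(m^2) - 1)), 1e-9)
  # consensus equals the mean of aligned coordinates
  expect_equal(as.numeric(fit$consensus),
               as.numeric(colMeans(m)), tolerance = 1e-8)
})

test_that("GPA is idempotent on already-aligned coordinates", {
  sim <- simulate_landmarks(small_sim_params(seed = 6, n_families = 5,
                                             n_extra = 0))
  fit <- gpa(sim$configs)
  fit2 <- gpa(fit$coords, reflect_side = "none")
  expect_equal(cm(fit2$coords), cm(fit$coords), tolerance = 1e-6)
})

test_that("degenerate configurations are reported by record", {
  configs <- tiny_configs(n = 2, reps = 1)
  configs[3, grep("^[xy]", names(configs))] <- 0.7   # coincident landmarks
  expect_error(gpa(configs), "zero centroid size")
})

test_that("Procrustes distance matches a rotation-grid brute force", {
  a <- matrix(c(0, 1, 0.4, 0, 0, 1.2), ncol = 2)
  b <- matrix(c(0.1, 1.05, 0.5, -0.1, 0.15, 0.95), ncol = 2)
  cs <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  grid <- seq(0, 2 * pi, length.out = 200001)[-200001]
  an <- cs(a); bn <- cs(b)
  dd <- vapply(grid, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sqrt(sum((bn %*% R - an)^2))
  }, numeric(1))
  expect_equal(procrustes_distance(a, b), min(dd), tolerance = 1e-6)
})

test_that("aligned covariance loses the four similarity dimensions", {
  sim <- simulate_landmarks(small_sim_params(seed = 7, n_families = 30,
                                             n_extra = 0))
  fit <- gpa(sim$configs)
  ev <- eigen(cov(cm(fit$coords)), symmetric = TRUE, only.values = TRUE)$values
  # the unit-size constraint is quadratic, so a curvature remnant of order
  # (deviation scale)^2 can survive; count directions above 1e-3 of the top
  expect_lte(sum(ev > 1e-3 * max(ev)), 2 * fit$k - 4)
})

test_that("symmetry ANOVA has textbook df and additive SS on balanced data", {
  sim <- simulate_landmarks(small_sim_params(seed = 8, n_families = 10,
                                             n_extra = 4))
  n <- nrow(sim$design)
  fit <- gpa(sim$configs)
  an <- symmetry_anova(fit, n_permutations = 49, seed = 1)
  tab <- an$table
  expect_equal(tab$df[tab$term == "individual"], n - 1)
  expect_equal(tab$df[tab$term == "side"], 1)
  expect_equal(tab$df[tab$term == "individual:side"], n - 1)
  expect_equal(tab$df[tab$term == "error"], n * 2 * (2 - 1))
  expect_equal(sum(tab$SS), an$total_SS, tolerance = 1e-12)
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-12)
})

test_that("fluctuating asymmetry is detected when present and only then", {
  # with developmental noise present, F >> 1 and the permutation p is small
  sim <- simulate_landmarks(small_sim_params(seed = 9, n_families = 25,
                                             n_extra = 0))
  an <- symmetry_anova(gpa(sim$configs), n_permutations = 199, seed = 2)
  fa <- an$table[an$table$term == "individual:side", ]
  expect_gt(fa$F, 1.5)
  expect_lt(fa$p_perm, 0.05)
  expect_gt(fa$Z, 2)

  # with D = 0 and tiny measurement error the FA share collapses
  pars <- small_sim_params(seed = 10, n_families = 25, n_extra = 0)
  pars$D_true <- matrix(0, 16, 16)
  pars$sigma_meas <- pars$sigma_meas / 30
  sim0 <- simulate_landmarks(pars)
  an0 <- symmetry_anova(gpa(sim0$configs), n_permutations = 199, seed = 2)
  fa0 <- an0$table[an0$table$term == "individual:side", ]
  expect_lt(fa0$proportion, 0.02)
  expect_gt(fa0$p_perm, 0.05)
})

test_that("permutation p-values are calibrated under the FA null", {
  # D = 0: repeated simulations give roughly uniform permutation p
  ps <- vapply(1:12, function(s) {
    pars <- small_sim_params(seed = 100 + s, n_families = 6, n_extra = 0)
    pars$D_true <- matrix(0, 16, 16)
    sim <- simulate_landmarks(pars)
    an <- symmetry_anova(gpa(sim$configs), n_permutations = 99, seed = s)
    an$table$p_perm[an$table$term == "individual:side"]
  }, numeric(1))
  expect_gt(mean(ps), 0.2)   # far from systematic rejection
  expect_gt(min(ps), 0.01)
})
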