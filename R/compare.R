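# Covariance-matrix comparison: Krzanowski-style common-subspace analysis,
# random skewers, leading-eigenvector correlations, REML-MVN resampling and
# BCa confidence intervals.

#' Reference basis from the leading eigenvectors of a covariance matrix
#'
#' First `q` unit eigenvectors in descending eigenvalue order, with a
#' deterministic sign convention (largest-magnitude element positive, ties
#' broken by first index). Typically applied to an independently estimated
#' phenotypic matrix so that two focal matrices are compared along the same
#' orthonormal directions.
#'
#' @param M A [cov_matrix()] or plain symmetric matrix.
#' @param q Number of leading eigenvectors (must not exceed the numerical
#'   rank; shape data lose 4 dimensions to the similarity transformations,
#'   so q is typically well below p).
#' @return p x q matrix with orthonormal columns.
#' @export
reference_basis <- function(M, q = 6L) {
  V <- as_cov_values(M)
  r <- psd_rank(V)
  if (q > r) {
    abort(paste0("q = ", q, " exceeds the numerical rank (", r,
                 ") of the matrix; restrict the comparison to the shared ",
                 "rank of the matrices involved."))
  }
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  fix_eigen_signs(e$vectors[, seq_len(q), drop = FALSE])
}

#' Krzanowski-style common-subspace comparison of two covariance matrices
#'
#' Projects both matrices on a shared orthonormal basis `K`, takes the
#' variances along each axis (`diag(K' M K)`), and relates the logarithms:
#' Pearson's r between `log v_A` and `log v_B`, and the OLS slope `b` of
#' `log v_B` on `log v_A` (A is the predictor; with A = D and B = G the
#' slope answers how developmental variance predicts genetic variance).
#'
#' @param A,B [cov_matrix()] objects or plain matrices (A plays the role
#'   of the predictor).
#' @param K p x q orthonormal basis, e.g. from [reference_basis()].
#' @return Object of class `subspace_comparison`: list with `r`, `b`,
#'   `intercept`, per-axis `log_variances` tibble, `q_used`, `degenerate`
#'   flag.
#' @export
krzanowski_compare <- function(A, B, K) {
  A <- as_cov_values(A); B <- as_cov_values(B)
  K <- as.matrix(K)
  if (max(abs(crossprod(K) - diag(ncol(K)))) > 1e-10) {
    abort("Columns of `K` must be orthonormal.")
  }
  q <- ncol(K)
  if (q < 3L) warn("Fewer than 3 reference axes: the correlation is unstable.")
  vA <- diag(t(K) %*% A %*% K)
  vB <- diag(t(K) %*% B %*% K)
  if (any(vA <= 0) || any(vB <= 0)) {
    abort("Non-positive projected variance: log-variances undefined along some axis; reduce q or check the matrices.")
  }
  lA <- log(vA); lB <- log(vB)
  degenerate <- sd(lA) == 0 || sd(lB) == 0
  if (degenerate) {
    r <- 0
    b <- if (sd(lA) == 0) NA_real_ else 0
    intercept <- mean(lB)
  } else {
    r <- stats::cor(lA, lB)
    b <- stats::cov(lA, lB) / stats::var(lA)
    intercept <- mean(lB) - b * mean(lA)
  }
  structure(list(
    r = r, b = b, intercept = intercept,
    log_variances = tibble(axis = seq_len(q), log_var_A = lA, log_var_B = lB),
    q_used = q, degenerate = degenerate,
    ci_r = NULL, ci_b = NULL
  ), class = "subspace_comparison")
}

#' @export
print.subspace_comparison <- function(x, ...) {
  cat(sprintf("Common-subspace comparison over %d axes\n", x$q_used))
  cat(sprintf("  r = %.3f%s\n", x$r,
              if (!is.null(x$ci_r)) sprintf(" [%.3f, %.3f]", x$ci_r[1], x$ci_r[2]) else ""))
  cat(sprintf("  b = %.3f%s\n", x$b,
              if (!is.null(x$ci_b)) sprintf(" [%.3f, %.3f]", x$ci_b[1], x$ci_b[2]) else ""))
  if (x$degenerate) cat("  (degenerate: zero spread in log-variances)\n")
  invisible(x)
}

#' Vector correlation (absolute cosine similarity)
#'
#' `r = |v1 . v2| / (|v1| |v2|)`, invariant to rescaling of either vector.
#'
#' @param v1,v2 Nonzero numeric vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @seealso [vector_angle()]
#' @export
vector_correlation <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) abort("Vector correlation of a zero vector is undefined.")
  min(abs(sum(v1 * v2)) / (n1 * n2), 1)
}

#' Angle between two vectors in degrees
#'
#' `theta = acos(vector_correlation(v1, v2))`, in \[0, 90\] degrees.
#'
#' @inheritParams vector_correlation
#' @return Angle in degrees.
#' @export
vector_angle <- function(v1, v2) {
  acos(vector_correlation(v1, v2)) * 180 / pi
}

# random unit vectors: components uniform(-1, 1) normalized (the classic
# skewers convention) or Gaussian-sphere
random_unit_vectors <- function(n, p, method = c("uniform", "gaussian")) {
  method <- match.arg(method)
  M <- if (method == "uniform") matrix(runif(n * p, -1, 1), n, p)
       else matrix(rnorm(n * p), n, p)
  M / sqrt(rowSums(M^2))
}

#' Random skewers comparison of two covariance matrices
#'
#' Applies the same random unit "selection" vectors to both matrices and
#' averages the vector correlation between the paired responses `A b` and
#' `B b`. The p-value is the probability that the correlation between two
#' independent random unit vectors in p dimensions exceeds the observed
#' mean (analytic null from the |cos| distribution on the sphere;
#' `null = "montecarlo"` draws it instead).
#'
#' @param A,B [cov_matrix()] objects or plain matrices of equal dimension.
#' @param n_vectors Number of skewer vectors.
#' @param seed Seed for the vector stream.
#' @param method Skewer sampling: `"uniform"` components (default, the
#'   convention of the classic implementation) or `"gaussian"` sphere.
#' @param null `"analytic"` (default) or `"montecarlo"`.
#' @return Object of class `skewers_result`: `mean_response_correlation`,
#'   `p_value`, `n_vectors`, `seed`.
#' @export
random_skewers <- function(A, B, n_vectors = 10000L, seed = 1L,
                           method = c("uniform", "gaussian"),
                           null = c("analytic", "montecarlo")) {
  method <- match.arg(method); null <- match.arg(null)
  A <- as_cov_values(A); B <- as_cov_values(B)
  if (!all(dim(A) == dim(B))) abort("A and B must have the same dimension.")
  p <- nrow(A)
  Bv <- with_seed(seed, random_unit_vectors(n_vectors, p, method))
  RA <- Bv %*% A
  RB <- Bv %*% B
  num <- abs(rowSums(RA * RB))
  den <- sqrt(rowSums(RA^2) * rowSums(RB^2))
  rs <- ifelse(den == 0, 0, pmin(num / den, 1))
  r_mean <- mean(rs)
  p_value <- if (null == "analytic") {
    # |cos| of two independent uniform directions: cos^2 ~ Beta(1/2, (p-1)/2)
    1 - pbeta(r_mean^2, 1 / 2, (p - 1) / 2)
  } else {
    u <- with_seed(child_seed(seed, 7L), {
      u1 <- random_unit_vectors(n_vectors, p, "gaussian")
      u2 <- random_unit_vectors(n_vectors, p, "gaussian")
      abs(rowSums(u1 * u2))
    })
    (1 + sum(u >= r_mean)) / (1 + n_vectors)
  }
  structure(list(mean_response_correlation = r_mean, p_value = p_value,
                 n_vectors = n_vectors, seed = seed, method = method,
                 null = null),
            class = "skewers_result")
}

#' @export
print.skewers_result <- function(x, ...) {
  cat(sprintf("Random skewers (%d vectors): mean response correlation %.3f, p = %.4g\n",
              x$n_vectors, x$mean_response_correlation, x$p_value))
  invisible(x)
}

#' REML-MVN resampling of a covariance matrix estimate
#'
#' Propagates estimation uncertainty by drawing parameter vectors from the
#' multivariate normal centered at the estimates with the fit's sampling
#' covariance and rebuilding a covariance matrix per draw ("G-scale"
#' sampling: draws are taken for the variance parameters themselves). For
#' a [fit_factor_model()] result the factor parameters are resampled; for
#' a moment/REML [cov_matrix()] the half-vectorized matrix is resampled
#' with its Wishart-type sampling covariance. Non-PSD draws are projected
#' to the nearest PSD matrix (eigenvalue clipping at zero) and counted.
#'
#' @param fit A `factor_model` or a `cov_matrix` carrying sampling
#'   information.
#' @param n_samples Number of draws.
#' @param seed Seed.
#' @param clip Project non-PSD draws to the nearest PSD matrix (default).
#'   Statistic streams that only use leading-axis projections (e.g.
#'   [krzanowski_compare_ci()]) use the raw draws, since clipping biases
#'   the resampling distribution.
#' @return List of p x p matrices with attributes `n_clipped` (draws that
#'   needed, or would have needed, clipping) and `seed`. Warns when more
#'   than half the draws were clipped.
#' @export
reml_mvn_resample <- function(fit, n_samples = 1000L, seed = 1L,
                              clip = TRUE) {
  draws <- if (inherits(fit, "factor_model")) {
    if (is.null(fit$param_sampling_cov)) {
      abort("Factor model carries no sampling covariance; refit with compute_sampling_cov = TRUE.")
    }
    V <- psd_project(fit$param_sampling_cov)
    pars <- with_seed(seed, MASS::mvrnorm(n_samples, mu = fit$par, Sigma = V,
                                          tol = 1e-6))
    lapply(seq_len(n_samples), function(i) factor_model_target(fit, pars[i, ]))
  } else if (inherits(fit, "cov_matrix")) {
    s <- fit$sampling
    if (is.null(s)) abort("cov_matrix carries no sampling information.")
    back <- function(Mr) {
      if (is.null(s$basis)) Mr else s$basis %*% Mr %*% t(s$basis)
    }
    if (s$type == "wishart_contrast") {
      r <- nrow(s$Sigma_r)
      V <- wishart_vech_cov(s$Sigma_r, s$df) * s$scale^2
      V <- psd_project(V)
      d <- with_seed(seed, MASS::mvrnorm(n_samples, mu = rep(0, nrow(V)),
                                         Sigma = V, tol = 1e-6))
      lapply(seq_len(n_samples),
             function(i) back(s$center_r + unvech(d[i, ], r)))
    } else if (s$type == "wishart_family") {
      r <- nrow(s$S_between_r)
      Vb <- psd_project(wishart_vech_cov(s$S_between_r, s$df_between))
      Vw <- psd_project(wishart_vech_cov(s$S_within_r, s$df_within) / s$n0^2)
      d <- with_seed(seed, {
        db <- MASS::mvrnorm(n_samples, mu = rep(0, nrow(Vb)), Sigma = Vb,
                            tol = 1e-6)
        dw <- MASS::mvrnorm(n_samples, mu = rep(0, nrow(Vw)), Sigma = Vw,
                            tol = 1e-6)
        db - dw
      })
      lapply(seq_len(n_samples),
             function(i) back(s$center_r + unvech(d[i, ], r)))
    } else {
      abort(paste0("Unknown sampling type: ", s$type))
    }
  } else {
    abort("`fit` must be a factor_model or a cov_matrix.")
  }
  n_clipped <- 0L
  out <- lapply(draws, function(M) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev))) {
      n_clipped <<- n_clipped + 1L
      if (clip) return(psd_project(M))
    }
    (M + t(M)) / 2
  })
  if (n_clipped > n_samples / 2) {
    warn(sprintf("REML-MVN: %d of %d draws required PSD clipping; asymptotic sampling covariance may be unreliable.",
                 n_clipped, n_samples))
  }
  attr(out, "n_clipped") <- n_clipped
  attr(out, "seed") <- seed
  out
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa: the bias correction `z0` comes from the fraction of
#' resampled statistics below the observed value, the acceleration `a`
#' from the jackknife skewness; the interval is the correspondingly
#' adjusted pair of percentiles of the resampled statistics. With `z0 = a
#' = 0` this is the plain percentile interval.
#'
#' @param statistic_samples Numeric vector of resampled statistic values
#'   (>= 100 recommended).
#' @param observed Observed statistic.
#' @param jackknife_values Optional leave-one-unit-out statistics (units:
#'   families for G, individuals for D/P); `NULL` sets a = 0.
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `c(lo, hi)` with attributes `z0` and `a`.
#' @export
bca_interval <- function(statistic_samples, observed,
                         jackknife_values = NULL, level = 0.95) {
  x <- statistic_samples[is.finite(statistic_samples)]
  B <- length(x)
  if (B < 2L || all(x == x[1L])) {
    out <- c(observed, observed)
    attr(out, "z0") <- 0; attr(out, "a") <- 0
    return(out)
  }
  prop <- sum(x < observed) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(prop)
  a <- 0
  if (!is.null(jackknife_values)) {
    jk <- jackknife_values[is.finite(jackknife_values)]
    d <- mean(jk) - jk
    denom <- sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / (6 * denom)
  }
  alpha <- (1 - level) / 2
  zlo <- qnorm(alpha); zhi <- qnorm(1 - alpha)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  out <- as.numeric(quantile(x, probs = c(adj(zlo), adj(zhi)), type = 7,
                             names = FALSE))
  attr(out, "z0") <- z0
  attr(out, "a") <- a
  out
}

#' Common-subspace comparison with REML-MVN confidence intervals
#'
#' Convenience wrapper: computes [krzanowski_compare()] for the point
#' estimates, resamples both matrices with [reml_mvn_resample()],
#' recomputes r and b per draw, and attaches BCa intervals.
#'
#' @param A,B `cov_matrix` or `factor_model` objects (resampled
#'   independently).
#' @param K Shared orthonormal basis.
#' @param n_samples MVN draws per matrix.
#' @param seed Seed.
#' @param level Confidence level.
#' @param jackknife_r,jackknife_b Optional jackknife statistic vectors for
#'   the acceleration constant.
#' @return A `subspace_comparison` with `ci_r`, `ci_b` and the resampled
#'   statistic streams in `samples`.
#' @export
krzanowski_compare_ci <- function(A, B, K, n_samples = 1000L, seed = 1L,
                                  level = 0.95, jackknife_r = NULL,
                                  jackknife_b = NULL) {
  point_A <- if (inherits(A, "factor_model")) reconstruct_cov(A) else A
  point_B <- if (inherits(B, "factor_model")) reconstruct_cov(B) else B
  obs <- krzanowski_compare(point_A, point_B, K)
  # raw (unclipped) draws: the statistic only uses leading-axis projected
  # variances, and PSD clipping would bias the resampling distribution
  dA <- reml_mvn_resample(A, n_samples, seed = child_seed(seed, 1L),
                          clip = FALSE)
  dB <- reml_mvn_resample(B, n_samples, seed = child_seed(seed, 2L),
                          clip = FALSE)
  stats <- vapply(seq_len(n_samples), function(i) {
    vA <- diag(t(K) %*% dA[[i]] %*% K)
    vB <- diag(t(K) %*% dB[[i]] %*% K)
    if (any(vA <= 0) || any(vB <= 0)) return(c(NA_real_, NA_real_))
    lA <- log(vA); lB <- log(vB)
    if (sd(lA) == 0 || sd(lB) == 0) return(c(0, NA_real_))
    c(stats::cor(lA, lB), stats::cov(lA, lB) / stats::var(lA))
  }, numeric(2))
  obs$samples <- tibble(r = stats[1L, ], b = stats[2L, ])
  obs$ci_r <- as.numeric(bca_interval(stats[1L, ], obs$r, jackknife_r, level))
  obs$ci_b <- as.numeric(bca_interval(stats[2L, ], obs$b, jackknife_b, level))
  obs$n_samples <- n_samples
  obs$seed <- seed
  obs
}
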