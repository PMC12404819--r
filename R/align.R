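# Shape-change vectors from multivariate regression and their alignment
# with covariance matrices: the e_beta statistic (fraction of a
# trace-scaled matrix's variance captured by a direction) and angle tests,
# both with resampling nulls.

#' Estimate a shape-change vector by multivariate regression
#'
#' Latitudinal vector: family-mean shapes (averaged across temperatures)
#' regressed on mean log centroid size and latitude; the latitude
#' coefficient vector (per degree) is returned. Thermal vector:
#' individual-mean shapes regressed on log centroid size, rearing
#' temperature (two-level factor, cold-to-warm contrast) and population;
#' the temperature contrast vector is returned.
#'
#' @param aligned A `gpa_fit` or aligned coords tibble.
#' @param design Optional design table.
#' @param covariate `"latitude"` or `"temperature"`.
#' @param aggregation `"by_family"` or `"by_individual"`; defaults to the
#'   covariate's natural unit (family for latitude, individual for
#'   temperature).
#' @return Object of class `shape_vector`: list with `beta` (length-p,
#'   Procrustes units per covariate unit), `covariate`, `norm`,
#'   `model_terms`, `n_units`.
#' @export
fit_shape_regression <- function(aligned, design = NULL,
                                 covariate = c("latitude", "temperature"),
                                 aggregation = NULL) {
  covariate <- match.arg(covariate)
  aggregation <- aggregation %||%
    if (covariate == "latitude") "by_family" else "by_individual"
  im <- individual_means(aligned, design)
  info <- im$info
  Y <- im$Y

  if (covariate == "latitude") {
    keep <- !is.na(col_or(info, "family_id")) &
      !is.na(col_or(info, "latitude"))
    if (!any(keep)) abort("No individuals with family and latitude metadata.")
    Y <- Y[keep, , drop = FALSE]; info <- info[keep, , drop = FALSE]
    if (aggregation == "by_family") {
      fam <- factor(info$family_id)
      cnt <- as.integer(table(fam))
      Y <- rowsum(Y, fam) / cnt
      info <- tibble(
        logcs = as.numeric(tapply(info$logcs, fam, mean)),
        latitude = as.numeric(tapply(info$latitude, fam, function(z) z[1L]))
      )
    }
    if (length(unique(info$latitude)) < 2L) {
      abort("Latitude does not vary across units: regression is rank-deficient.")
    }
    X <- stats::model.matrix(~ logcs + latitude, data = info)
    focal <- "latitude"
    terms <- c("intercept", "log centroid size", "latitude")
  } else {
    keep <- !is.na(col_or(info, "temperature")) &
      !is.na(col_or(info, "population_id"))
    if (!any(keep)) abort("No individuals with temperature and population metadata.")
    Y <- Y[keep, , drop = FALSE]; info <- info[keep, , drop = FALSE]
    if (length(unique(info$temperature)) < 2L) {
      abort("Temperature does not vary across units: regression is rank-deficient.")
    }
    info$temp_f <- factor(info$temperature)   # cold is the reference level
    X <- stats::model.matrix(~ logcs + temp_f + factor(population_id),
                             data = info)
    focal <- grep("^temp_f", colnames(X), value = TRUE)[1L]
    terms <- c("intercept", "log centroid size", "temperature", "population")
  }
  q <- qr(X)
  if (q$rank < ncol(X)) abort("Collinear design: shape regression is rank-deficient.")
  B <- qr.coef(q, Y)
  beta <- as.numeric(B[focal, ])
  structure(list(beta = beta, covariate = covariate,
                 norm = sqrt(sum(beta^2)), model_terms = terms,
                 aggregation = aggregation, n_units = nrow(Y)),
            class = "shape_vector")
}

#' @export
print.shape_vector <- function(x, ...) {
  cat(sprintf("Shape-change vector (%s, %s): |beta| = %.4g over %d units\n",
              x$covariate, x$aggregation, x$norm, x$n_units))
  invisible(x)
}

beta_of <- function(beta) {
  if (inherits(beta, "shape_vector")) beta$beta else as.numeric(beta)
}

#' Variance of a trace-scaled covariance matrix along a direction
#'
#' `e_beta = (b' M b) / |b|^2` with `M` scaled to unit trace: the fraction
#' of the matrix's total variance captured by the direction `b`. Bounded
#' by the smallest and largest eigenvalues of the trace-scaled matrix, and
#' maximal (`= lambda_1`) when `b` is the leading eigenvector.
#'
#' @param beta A `shape_vector` or nonzero numeric vector.
#' @param M A [cov_matrix()] or PSD matrix.
#' @return Scalar in \[0, 1\].
#' @export
e_beta <- function(beta, M) {
  b <- beta_of(beta)
  if (sum(b^2) == 0) abort("e_beta of a zero vector is undefined.")
  V <- as_cov_values(M)
  tr <- sum(diag(V))
  if (tr <= 0) abort("Matrix has non-positive trace.")
  as.numeric(b %*% (V / tr) %*% b) / sum(b^2)
}

alignment_result <- function(statistic_name, observed, null_samples,
                             p_value, reference, n_resamples, seed, null) {
  structure(list(statistic_name = statistic_name, observed = observed,
                 null_samples = null_samples, p_value = p_value,
                 reference = reference, n_resamples = n_resamples,
                 seed = seed, null = null),
            class = "alignment_test")
}

#' @export
print.alignment_test <- function(x, ...) {
  cat(sprintf("Alignment test (%s vs %s): observed %.4g, p = %.4g (%d resamples, %s null)\n",
              x$statistic_name, x$reference, x$observed, x$p_value,
              x$n_resamples, x$null))
  invisible(x)
}

#' Resampling test of e_beta against a null of unstructured directions
#'
#' Compares the observed [e_beta()] to a null distribution of directions
#' with no landmark structure: by default random element permutations of
#' the observed vector (preserving its norm and marginal distribution), or
#' isotropic random unit vectors. One-sided: large `e_beta` means the
#' direction runs along the matrix's main axes;
#' `p = (1 + #\{null >= observed\}) / (1 + n_resamples)`.
#'
#' @inheritParams e_beta
#' @param n_resamples Number of null draws (>= 999).
#' @param seed Seed.
#' @param null `"permute"` (default) or `"isotropic"`.
#' @param reference Label of the matrix compared against (for reporting).
#' @return An `alignment_test` with the null samples attached.
#' @export
e_beta_test <- function(beta, M, n_resamples = 10000L, seed = 1L,
                        null = c("permute", "isotropic"),
                        reference = "D") {
  null <- match.arg(null)
  if (n_resamples < 999L) abort("Use at least 999 resamples.")
  b <- beta_of(beta)
  V <- as_cov_values(M)
  V <- V / sum(diag(V))
  p <- length(b)
  obs <- as.numeric(b %*% V %*% b) / sum(b^2)
  draws <- with_seed(seed, {
    if (null == "permute") {
      t(vapply(seq_len(n_resamples), function(i) sample(b), numeric(p)))
    } else {
      random_unit_vectors(n_resamples, p, "gaussian")
    }
  })
  nulls <- rowSums((draws %*% V) * draws) / rowSums(draws^2)
  p_value <- (1 + sum(nulls >= obs)) / (1 + n_resamples)
  alignment_result("e_beta", obs, nulls, p_value, reference,
                   n_resamples, seed, null)
}

#' Resampling test of the angle between two shape vectors
#'
#' Observed angle via [vector_angle()]; the null randomizes both vectors
#' (independent element permutations by default, or isotropic unit
#' vectors) and the one-sided p-value is the fraction of null angles at
#' least as small as observed (small angle = alignment).
#'
#' @param beta A `shape_vector` or numeric vector.
#' @param v Reference vector (e.g. `dmax` or `gmax`).
#' @inheritParams e_beta_test
#' @return An `alignment_test` (statistic in degrees).
#' @export
angle_test <- function(beta, v, n_resamples = 10000L, seed = 1L,
                       null = c("permute", "isotropic"),
                       reference = "dmax") {
  null <- match.arg(null)
  b <- beta_of(beta); v <- beta_of(v)
  obs <- vector_angle(b, v)
  p <- length(b)
  draws <- with_seed(seed, {
    if (null == "permute") {
      b_perm <- t(vapply(seq_len(n_resamples), function(i) sample(b), numeric(p)))
      v_perm <- t(vapply(seq_len(n_resamples), function(i) sample(v), numeric(p)))
      list(b_perm, v_perm)
    } else {
      list(random_unit_vectors(n_resamples, p, "gaussian"),
           random_unit_vectors(n_resamples, p, "gaussian"))
    }
  })
  cosines <- abs(rowSums(draws[[1L]] * draws[[2L]])) /
    sqrt(rowSums(draws[[1L]]^2) * rowSums(draws[[2L]]^2))
  nulls <- acos(pmin(cosines, 1)) * 180 / pi
  p_value <- (1 + sum(nulls <= obs)) / (1 + n_resamples)
  alignment_result("angle", obs, nulls, p_value, reference,
                   n_resamples, seed, null)
}
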