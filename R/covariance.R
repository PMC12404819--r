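# Moment (ANOVA-type) estimators of the developmental (D), phenotypic (P)
# and broad-sense genetic (G) covariance matrices from aligned bilateral
# shape data, and the cov_matrix result class. REML counterparts live in
# factor_model.R and share these stratum builders.
#
# Procrustes alignment removes 4 degrees of freedom (translation x/y,
# rotation, scale), so aligned covariance matrices are singular in the
# p-variable frame. All variance-component fitting happens in the
# (2k-4)-dimensional shape subspace spanned by the orthonormal basis T
# computed at the consensus; estimates are mapped back to the p-variable
# frame as T theta T'. Per-variable digitizing error likewise appears in
# the aligned frame as the projected covariance T' diag(sigma^2) T.

# ---- cov_matrix class -------------------------------------------------

#' Construct a labeled covariance matrix result
#'
#' Symmetrizes the input, clips negative eigenvalues to zero (recording how
#' many were clipped), and stores provenance: the label (D, G, P, other),
#' the fixed effects adjusted for, the number of units the estimate is
#' based on, and optionally a sampling-covariance description used by
#' [reml_mvn_resample()].
#'
#' @param values p x p matrix.
#' @param label One of `"D"`, `"G"`, `"P"`, `"other"`.
#' @param n_units Number of independent units behind the estimate.
#' @param fixed_effects Character vector of adjusted fixed effects.
#' @param sampling Optional list describing the asymptotic sampling
#'   distribution (see [reml_mvn_resample()]).
#' @param clip Clip negative eigenvalues to zero (default TRUE).
#' @return Object of class `cov_matrix`.
#' @export
cov_matrix <- function(values, label = c("other", "D", "G", "P"),
                       n_units = NA_integer_, fixed_effects = character(),
                       sampling = NULL, clip = TRUE) {
  label <- match.arg(label)
  raw <- (values + t(values)) / 2
  vals <- if (clip) psd_project(raw) else raw
  structure(list(
    values = vals,
    values_raw = raw,
    label = label,
    trace = sum(diag(vals)),
    selected_rank = psd_rank(vals),
    n_clipped = attr(vals, "n_clipped") %||% 0L,
    fixed_effects_adjusted_for = fixed_effects,
    n_units = n_units,
    sampling = sampling
  ), class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat(sprintf("%s-matrix (%d x %d): trace %.4g, effective rank %d, n = %s\n",
              x$label, nrow(x$values), ncol(x$values), x$trace,
              x$selected_rank, format(x$n_units)))
  if (length(x$fixed_effects_adjusted_for)) {
    cat("  adjusted for:", paste(x$fixed_effects_adjusted_for, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.matrix.cov_matrix <- function(x, ...) x$values

# accept cov_matrix or plain matrix
as_cov_values <- function(M) {
  if (inherits(M, "cov_matrix")) M$values else as.matrix(M)
}

# vech (column-major lower triangle) helpers
vech <- function(M) M[lower.tri(M, diag = TRUE)]
unvech <- function(v, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M))
}

# asymptotic covariance of vech(S) for S = Wishart(Sigma, df)/df
wishart_vech_cov <- function(Sigma, df) {
  p <- nrow(Sigma)
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  n <- nrow(idx)
  V <- matrix(0, n, n)
  for (a in seq_len(n)) {
    i <- idx[a, 1L]; j <- idx[a, 2L]
    V[a, ] <- (Sigma[i, idx[, 1L]] * Sigma[j, idx[, 2L]] +
               Sigma[i, idx[, 2L]] * Sigma[j, idx[, 1L]]) / df
  }
  (V + t(V)) / 2
}

# ---- shared data preparation ------------------------------------------

coords_of <- function(aligned) {
  if (inherits(aligned, "gpa_fit")) aligned$coords else aligned
}

join_design <- function(coords, design) {
  if (is.null(design)) return(coords)
  add <- setdiff(names(design), names(coords))
  if (length(add) == 0L) return(coords)
  dplyr::left_join(coords, design[, c("specimen_id", add)], by = "specimen_id")
}

# orthonormal basis (p x (p-4)) of the shape subspace at the mean of the
# aligned coordinates
shape_basis <- function(coords, k = n_landmarks(coords)) {
  mu <- colMeans(coord_matrix(coords, k))
  similarity_basis(center_scale(vec_to_config(mu)))$shape
}

# within-(specimen, side) replicate residual covariance: unbiased for the
# aligned (projected) digitizing-error covariance
meas_error_stratum <- function(coords, k = n_landmarks(coords)) {
  m <- coord_matrix(coords, k)
  cell <- interaction(coords$specimen_id, coords$side, drop = TRUE)
  cnt <- as.integer(table(cell))
  df <- nrow(m) - nlevels(cell)
  if (df <= 0L) {
    abort("Measurement error is inestimable: need >= 2 replicates per (specimen, side) for at least some cells.")
  }
  mu <- rowsum(m, cell) / cnt
  resid <- m - mu[as.integer(cell), , drop = FALSE]
  S_full <- crossprod(resid) / df
  list(S_full = S_full, df = df, diag = diag(S_full))
}

#' Per-variable measurement-error variances from replicate residuals
#'
#' Estimates the digitizing-error SD of each raw shape variable from the
#' within-(specimen, side) replicate residuals by restricted maximum
#' likelihood, accounting for the loss of the four similarity dimensions
#' during superimposition (the aligned error covariance is
#' `T' diag(sigma^2) T`).
#'
#' @param aligned A `gpa_fit` or aligned coords tibble.
#' @return List with `sigma2` (length-p variances), `basis` (the shape
#'   subspace basis T), and the stratum (`S_full`, `df`).
#' @export
estimate_meas_error <- function(aligned) {
  coords <- coords_of(aligned)
  k <- n_landmarks(coords)
  Tb <- shape_basis(coords, k)
  err <- meas_error_stratum(coords, k)
  r <- ncol(Tb)
  # moment start: solve diag(T T' s T T') = observed diagonal
  Pi <- Tb %*% t(Tb)
  M <- Pi^2
  s0 <- tryCatch(solve(M, err$diag), error = function(e) err$diag)
  s0 <- pmax(s0, 1e-6 * mean(err$diag))
  comp <- list(list(type = "projdiag", Q = t(Tb), init = s0))
  strata <- list(list(S = t(Tb) %*% err$S_full %*% Tb, df = err$df, w = 1))
  fit <- run_reml(comp, strata, r,
                  unlist(lapply(comp, component_init_par, p = r)))
  s <- exp(fit$par)
  list(sigma2 = s, basis = Tb, S_full = err$S_full, df = err$df,
       loglik = fit$loglik, convergence = fit$convergence)
}

# replicate-mean right-left contrasts per individual, with the fixed-effect
# design (intercept = directional asymmetry, log centroid size, cohort)
asymmetry_responses <- function(aligned, design = NULL) {
  coords <- join_design(coords_of(aligned), design)
  k <- n_landmarks(coords)
  m <- coord_matrix(coords, k)
  cell <- factor(paste(coords$specimen_id, coords$side, sep = "\r"))
  cnt <- as.integer(table(cell))
  mu <- rowsum(m, cell) / cnt
  keys <- do.call(rbind, strsplit(levels(cell), "\r", fixed = TRUE))
  cell_tbl <- tibble(specimen_id = keys[, 1L], side = keys[, 2L],
                     n_rep = cnt, row = seq_len(nrow(mu)))
  wide <- tidyr::pivot_wider(cell_tbl, names_from = "side",
                             values_from = c("n_rep", "row"))
  wide <- wide[!is.na(wide$row_left) & !is.na(wide$row_right), ]
  if (nrow(wide) < 3L) abort("Too few individuals with both sides measured.")
  Y <- mu[wide$row_right, , drop = FALSE] - mu[wide$row_left, , drop = FALSE]
  c_noise <- mean(1 / wide$n_rep_left + 1 / wide$n_rep_right)

  meta <- dplyr::distinct(coords[, intersect(c("specimen_id", "cohort"),
                                             names(coords)), drop = FALSE])
  logcs <- tapply(log(coords$centroid_size), coords$specimen_id, mean)
  ids <- wide$specimen_id
  X <- cbind(`(Intercept)` = rep(1, nrow(wide)),
             logcs = as.numeric(logcs[ids]) - mean(as.numeric(logcs[ids])))
  fixed <- c("side (directional asymmetry)", "log centroid size")
  if ("cohort" %in% names(meta)) {
    coh <- meta$cohort[match(ids, meta$specimen_id)]
    if (length(unique(coh)) > 1L) {
      X <- cbind(X, stats::model.matrix(~cohort,
                                        data.frame(cohort = factor(coh)))[, -1L, drop = FALSE])
      fixed <- c(fixed, "cohort")
    }
  }
  list(Y = Y, X = X, ids = ids, c_noise = c_noise, fixed = fixed, k = k,
       coords = coords)
}

# residualize Y on X; returns residuals and residual df
resid_fixed <- function(Y, X) {
  q <- qr(X)
  list(R = qr.resid(q, Y), df = nrow(Y) - q$rank)
}

# per-individual mean shapes over all records, joined with design covariates
individual_means <- function(aligned, design = NULL) {
  coords <- join_design(coords_of(aligned), design)
  k <- n_landmarks(coords)
  m <- coord_matrix(coords, k)
  ind <- factor(coords$specimen_id)
  cnt <- as.integer(table(ind))
  mu <- rowsum(m, ind) / cnt
  logcs <- as.numeric(tapply(log(coords$centroid_size), ind, mean))
  meta_cols <- intersect(c("family_id", "population_id", "latitude",
                           "temperature", "cohort"), names(coords))
  meta <- dplyr::distinct(coords[, c("specimen_id", meta_cols), drop = FALSE])
  meta <- meta[match(levels(ind), meta$specimen_id), , drop = FALSE]
  info <- dplyr::bind_cols(
    tibble(specimen_id = levels(ind), n_records = cnt, logcs = logcs),
    as_tibble(meta[, meta_cols, drop = FALSE])
  )
  list(Y = mu, info = info, k = k, coords = coords)
}

# ---- estimators --------------------------------------------------------

#' Estimate the developmental covariance matrix D
#'
#' D captures the shape (co)variation induced by stochastic developmental
#' noise, estimated from the individual-by-side (fluctuating asymmetry)
#' variance component. Individuals are pooled across populations,
#' temperatures and cohorts; directional asymmetry, allometry (log
#' centroid size) and cohort are adjusted as fixed effects on the signed
#' right-minus-left contrasts. The moment path subtracts the projected
#' measurement-error covariance from the contrast covariance,
#' `D = (Cov(contrasts) - (2/r) T diag(sigma2) T') / 2`, with the
#' per-variable error variances from [estimate_meas_error()]; the REML
#' path maximizes the joint two-stratum restricted likelihood numerically
#' and agrees with the moment path on balanced designs.
#'
#' @param aligned A `gpa_fit` or aligned coords tibble.
#' @param design Optional design table with per-specimen covariates.
#' @param method `"moment"` (closed form given the error variances) or
#'   `"reml"` (iterative).
#' @return A [cov_matrix()] labeled `"D"`, carrying a Wishart-type
#'   sampling description for [reml_mvn_resample()].
#' @export
estimate_D <- function(aligned, design = NULL,
                       method = c("moment", "reml")) {
  method <- match.arg(method)
  resp <- asymmetry_responses(aligned, design)
  rf <- resid_fixed(resp$Y, resp$X)
  S2 <- crossprod(rf$R) / rf$df
  err <- estimate_meas_error(resp$coords)
  Tb <- err$basis
  S2r <- t(Tb) %*% S2 %*% Tb
  noise_r <- t(Tb) %*% (err$sigma2 * Tb)
  if (method == "moment") {
    theta_r <- (S2r - resp$c_noise * noise_r) / 2
  } else {
    fit <- reml_contrast_unstructured(S2r, rf$df, err, resp$c_noise, Tb)
    theta_r <- fit$Theta
  }
  D <- Tb %*% theta_r %*% t(Tb)
  cov_matrix(D, label = "D", n_units = nrow(resp$Y),
             fixed_effects = resp$fixed,
             sampling = list(type = "wishart_contrast", Sigma_r = S2r,
                             df = rf$df, scale = 0.5, basis = Tb,
                             center_r = theta_r,
                             jackknife_units = "individual"))
}

#' Estimate the phenotypic covariance matrix P
#'
#' Among-individual ("static") covariance of side- and replicate-averaged
#' shapes after adjusting log centroid size, rearing temperature, side and
#' population as fixed effects and subtracting the developmental
#' (`D / n_sides`) and measurement-error noise carried by the individual
#' means. Restricted to individuals with complete covariates (the common
#' garden).
#'
#' @inheritParams estimate_D
#' @return A [cov_matrix()] labeled `"P"`.
#' @export
estimate_P <- function(aligned, design = NULL,
                       method = c("moment", "reml")) {
  method <- match.arg(method)
  im <- individual_means(aligned, design)
  info <- im$info
  keep <- !is.na(col_or(info, "temperature")) &
    !is.na(col_or(info, "population_id"))
  if (!any(keep)) abort("No individuals with temperature and population covariates.")
  Y <- im$Y[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  X <- stats::model.matrix(~ logcs + factor(temperature) + factor(population_id),
                           data = info)
  rf <- resid_fixed(Y, X)
  S <- crossprod(rf$R) / rf$df

  D_hat <- estimate_D(aligned, design, method = method)
  err <- estimate_meas_error(im$coords)
  Tb <- err$basis
  Sr <- t(Tb) %*% S %*% Tb
  noise_r <- t(Tb) %*% (err$sigma2 * Tb)
  D_r <- t(Tb) %*% D_hat$values_raw %*% Tb
  theta_r <- Sr - D_r / 2 - noise_r * mean(1 / info$n_records)
  P <- Tb %*% theta_r %*% t(Tb)
  cov_matrix(P, label = "P", n_units = nrow(Y),
             fixed_effects = c("log centroid size", "temperature",
                               "side", "population"),
             sampling = list(type = "wishart_contrast", Sigma_r = Sr,
                             df = rf$df, scale = 1, basis = Tb,
                             center_r = theta_r,
                             jackknife_units = "individual"))
}

#' Estimate the broad-sense genetic covariance matrix G
#'
#' Between-family covariance component of individual mean shapes (full-sib
#' families, so the estimate contains additive and non-additive variance),
#' with log centroid size, rearing temperature and population as fixed
#' effects; the population term makes this the pooled within-population
#' genetic covariance. Moment path: `G = S_between - S_within / n0` with
#' `n0` the mean family size; the REML path refines this numerically and
#' agrees on balanced designs.
#'
#' @inheritParams estimate_D
#' @return A [cov_matrix()] labeled `"G"`.
#' @export
estimate_G <- function(aligned, design = NULL,
                       method = c("moment", "reml")) {
  method <- match.arg(method)
  fr <- family_responses(aligned, design)
  Tb <- fr$basis
  if (method == "moment") {
    theta_r <- fr$S_between_r - fr$S_within_r / fr$n0
  } else {
    fit <- reml_family_unstructured(fr)
    theta_r <- fit$Theta
  }
  G <- Tb %*% theta_r %*% t(Tb)
  cov_matrix(G, label = "G", n_units = fr$n_families,
             fixed_effects = c("log centroid size", "temperature",
                               "population"),
             sampling = list(type = "wishart_family",
                             S_between_r = fr$S_between_r,
                             df_between = fr$df_between,
                             S_within_r = fr$S_within_r,
                             df_within = fr$df_within,
                             n0 = fr$n0, basis = Tb, center_r = theta_r,
                             jackknife_units = "family"))
}

# between/within-family strata of individual mean shapes, in the shape
# subspace
family_responses <- function(aligned, design = NULL) {
  im <- individual_means(aligned, design)
  info <- im$info
  if (!"family_id" %in% names(info)) abort("Design has no family_id column.")
  keep <- !is.na(info$family_id)
  Y <- im$Y[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  fam <- factor(info$family_id)
  sizes <- as.integer(table(fam))
  if (all(sizes < 2L)) abort("G is inestimable: all families are singletons.")
  X <- stats::model.matrix(~ logcs + factor(temperature) + factor(population_id),
                           data = info)
  rf <- resid_fixed(Y, X)
  R <- rf$R
  mu_f <- rowsum(R, fam) / sizes
  W_resid <- R - mu_f[as.integer(fam), , drop = FALSE]
  df_within <- nrow(R) - nlevels(fam)
  S_within <- crossprod(W_resid) / df_within
  # family means: the population structure was removed at the individual
  # level; residualize on the family-level design for honest df
  fam_info <- dplyr::distinct(info[, c("family_id", "population_id")])
  fam_info <- fam_info[match(levels(fam), fam_info$family_id), ]
  Xb <- stats::model.matrix(~ factor(population_id), data = fam_info)
  rb <- resid_fixed(mu_f, Xb)
  S_between <- crossprod(rb$R) / rb$df
  n_ind <- nrow(R)
  n0 <- (n_ind - sum(sizes^2) / n_ind) / (nlevels(fam) - 1L)
  Tb <- shape_basis(im$coords)
  list(S_between_r = t(Tb) %*% S_between %*% Tb, df_between = rb$df,
       S_within_r = t(Tb) %*% S_within %*% Tb, df_within = df_within,
       n0 = n0, n_families = nlevels(fam), n_individuals = n_ind,
       basis = Tb, p = ncol(Tb))
}
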