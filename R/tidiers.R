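# broom-style tidiers for every result class.

#' @export
tidy.gpa_fit <- function(x, ...) x$coords

#' @export
glance.gpa_fit <- function(x, ...) {
  tibble(n_records = nrow(x$coords), n_landmarks = x$k,
         n_shape_variables = x$p, iterations = x$iterations,
         rms_change = x$rms_change)
}

#' @export
tidy.symmetry_anova <- function(x, ...) x$table

#' @export
glance.symmetry_anova <- function(x, ...) {
  fa <- x$table[x$table$term == "individual:side", ]
  tibble(n_individuals = x$n_individuals, n_records = x$n_records,
         fa_df = fa$df, error_df = x$table$df[x$table$term == "error"],
         fa_F = fa$F, fa_Z = fa$Z, fa_p = fa$p_perm,
         fa_proportion = fa$proportion)
}

#' @export
tidy.cov_matrix <- function(x, ...) {
  p <- nrow(x$values)
  tibble(row = rep(seq_len(p), times = p),
         col = rep(seq_len(p), each = p),
         value = as.numeric(x$values))
}

#' @export
glance.cov_matrix <- function(x, ...) {
  tibble(label = x$label, trace = x$trace, rank = x$selected_rank,
         n_units = x$n_units, n_clipped = x$n_clipped)
}

#' @export
tidy.factor_model <- function(x, ...) {
  p <- x$p; m <- x$m
  tibble(variable = rep(seq_len(p), times = m),
         factor = rep(seq_len(m), each = p),
         loading = as.numeric(x$loadings))
}

#' @export
glance.factor_model <- function(x, ...) {
  tibble(m = x$m, loglik = x$loglik, n_params = x$n_params, aic = x$aic,
         converged = x$converged, label = x$label)
}

#' @export
tidy.rank_selection <- function(x, ...) x$table

#' @export
glance.rank_selection <- function(x, ...) {
  tibble(m_star = x$m_star, n_fitted = nrow(x$table),
         min_aic = min(x$table$aic[x$table$converged]))
}

#' @export
tidy.subspace_comparison <- function(x, ...) x$log_variances

#' @export
glance.subspace_comparison <- function(x, ...) {
  tibble(r = x$r, b = x$b, intercept = x$intercept, q_used = x$q_used,
         degenerate = x$degenerate,
         ci_r_lo = if (is.null(x$ci_r)) NA_real_ else x$ci_r[1L],
         ci_r_hi = if (is.null(x$ci_r)) NA_real_ else x$ci_r[2L],
         ci_b_lo = if (is.null(x$ci_b)) NA_real_ else x$ci_b[1L],
         ci_b_hi = if (is.null(x$ci_b)) NA_real_ else x$ci_b[2L])
}

#' @export
glance.skewers_result <- function(x, ...) {
  tibble(mean_response_correlation = x$mean_response_correlation,
         p_value = x$p_value, n_vectors = x$n_vectors, seed = x$seed)
}

#' @export
tidy.alignment_test <- function(x, ...) tibble(null_value = x$null_samples)

#' @export
glance.alignment_test <- function(x, ...) {
  tibble(statistic = x$statistic_name, observed = x$observed,
         p_value = x$p_value, reference = x$reference,
         n_resamples = x$n_resamples, null = x$null)
}

#' @export
tidy.shape_vector <- function(x, ...) {
  p <- length(x$beta)
  k <- p / 2L
  tibble(variable = shape_var_names(k), estimate = x$beta)
}

#' @export
glance.shape_vector <- function(x, ...) {
  tibble(covariate = x$covariate, norm = x$norm,
         aggregation = x$aggregation, n_units = x$n_units)
}

#' @export
tidy.validation_report <- function(x, ...) x$imbalance

#' @export
glance.validation_report <- function(x, ...) {
  tibble(n_individuals = x$n_individuals, n_sides = x$n_sides,
         n_replicates = x$n_replicates, n_records = x$n_records,
         n_landmarks = x$n_landmarks,
         n_shape_variables = x$n_shape_variables,
         n_flags = x$n_flags, complete = x$complete)
}
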