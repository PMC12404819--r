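# ggplot2 autoplot methods: quick diagnostic graphics for each result.

#' @export
autoplot.gpa_fit <- function(object, alpha = 0.2, ...) {
  k <- object$k
  coords <- tidy(object)
  long <- tidyr::pivot_longer(
    coords[, shape_var_names(k)],
    cols = dplyr::everything(),
    names_to = c(".value", "landmark"),
    names_pattern = "([xy])([0-9]+)")
  cons <- tibble(landmark = as.character(seq_len(k)),
                 x = object$consensus[, 1L], y = object$consensus[, 2L])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = alpha, size = 0.4,
                        ggplot2::aes(colour = .data$landmark)) +
    ggplot2::geom_point(data = cons, size = 2, shape = 21, fill = "white") +
    ggplot2::geom_text(data = cons, ggplot2::aes(label = .data$landmark),
                       nudge_y = 0.03, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(title = "Aligned landmark configurations",
                  x = NULL, y = NULL)
}

#' @export
autoplot.cov_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(object$label, "-matrix"),
                  x = NULL, y = NULL, fill = "cov")
}

#' @export
autoplot.symmetry_anova <- function(object, ...) {
  d <- object$table
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "Shape variance decomposition",
                  y = "proportion of total SS", x = NULL)
}

#' @export
autoplot.rank_selection <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$m, y = .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::geom_vline(xintercept = object$m_star, linetype = 2) +
    ggplot2::labs(title = "Factor-model rank selection", y = "AIC",
                  x = "dimensions (m)")
}

#' @export
autoplot.subspace_comparison <- function(object, ...) {
  d <- object$log_variances
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_var_A, y = .data$log_var_B)) +
    ggplot2::geom_abline(slope = object$b, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("Common-subspace comparison (r = %.2f, b = %.2f)",
                      object$r, object$b),
      x = "log variance (predictor matrix)",
      y = "log variance (response matrix)")
}

#' @export
autoplot.alignment_test <- function(object, bins = 40, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null_value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      title = sprintf("%s vs %s: observed %.3g (p = %.3g)",
                      object$statistic_name, object$reference,
                      object$observed, object$p_value),
      x = object$statistic_name, y = "null count")
}
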