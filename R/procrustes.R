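# Generalized Procrustes superimposition (partial Procrustes: rotation only,
# unit centroid size) and the bilateral symmetry ANOVA.

#' Reflect landmark configurations about the vertical axis
#'
#' Negates the x-coordinates of the selected records; landmark order is
#' unchanged. Reflection is an involution and leaves centroid size intact.
#'
#' @param configs Tibble of configurations.
#' @param side Which records to reflect: `"left"`, `"right"`, or `"all"`.
#' @return The tibble with reflected coordinates.
#' @export
reflect_configs <- function(configs, side = "all") {
  k <- n_landmarks(configs)
  rows <- if (identical(side, "all")) rep(TRUE, nrow(configs))
          else configs$side == side
  xcols <- paste0("x", seq_len(k))
  configs[rows, xcols] <- -configs[rows, xcols]
  configs
}

#' Centroid size of each configuration
#'
#' Root summed squared distances of the landmarks from their centroid.
#'
#' @param configs Tibble of configurations.
#' @return Numeric vector, one size per row (digitizing units).
#' @export
centroid_size <- function(configs) {
  k <- n_landmarks(configs)
  m <- coord_matrix(configs, k)
  xs <- m[, seq_len(k), drop = FALSE]
  ys <- m[, k + seq_len(k), drop = FALSE]
  xs <- xs - rowMeans(xs)
  ys <- ys - rowMeans(ys)
  sqrt(rowSums(xs^2) + rowSums(ys^2))
}

# rotate each row-configuration (centered, n x 2k) onto consensus (c(x, y)
# vector, centered); returns the rotated matrix. Rotation only (det +1).
rotate_onto <- function(m, cons, k) {
  cx <- cons[seq_len(k)]; cy <- cons[k + seq_len(k)]
  xs <- m[, seq_len(k), drop = FALSE]
  ys <- m[, k + seq_len(k), drop = FALSE]
  a <- xs %*% cx + ys %*% cy
  b <- ys %*% cx - xs %*% cy
  h <- sqrt(a^2 + b^2)
  h[h == 0] <- 1            # coincident-with-origin guard; rotation moot
  co <- as.numeric(a / h); si <- as.numeric(b / h)
  cbind(xs * co + ys * si, -xs * si + ys * co)
}

#' Generalized Procrustes alignment of bilateral configurations
#'
#' Simultaneously superimposes all records: the designated side is mirrored
#' (matching symmetry), every configuration is centered and scaled to unit
#' centroid size, and configurations are iteratively rotated onto the
#' consensus (rotation-only orthogonal Procrustes solution, determinant +1)
#' until the root-mean-square consensus change falls below `tol`.
#'
#' @param configs Tibble of configurations (metadata columns are carried
#'   through).
#' @param reflect_side Side mirrored before alignment (`"left"`, the
#'   default, or `"right"` or `"none"`). The choice only fixes the frame.
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Maximum number of consensus updates.
#' @return An object of class `gpa_fit`: list with `coords` (tibble of
#'   aligned shape variables plus `centroid_size` and all metadata),
#'   `consensus` (k x 2 mean shape), `iterations`, `rms_change`, `k`, `p`.
#' @export
gpa <- function(configs, reflect_side = "left", tol = 1e-10, max_iter = 100L) {
  if (nrow(configs) < 2L) abort("GPA needs at least two configurations.")
  k <- n_landmarks(configs)
  if (!identical(reflect_side, "none")) {
    configs <- reflect_configs(configs, side = reflect_side)
  }
  m <- coord_matrix(configs, k)
  xs <- m[, seq_len(k), drop = FALSE]
  ys <- m[, k + seq_len(k), drop = FALSE]
  xs <- xs - rowMeans(xs)
  ys <- ys - rowMeans(ys)
  cs <- sqrt(rowSums(xs^2) + rowSums(ys^2))
  if (any(cs <= 0)) {
    bad <- which(cs <= 0)[1L]
    abort(paste0("Degenerate configuration (zero centroid size) at record ",
                 bad, if (!is.null(configs$specimen_id))
                   paste0(" (", configs$specimen_id[bad], ")") else ""))
  }
  m <- cbind(xs / cs, ys / cs)

  consensus <- m[1L, ]
  consensus <- consensus / sqrt(sum(consensus^2))
  it <- 0L; change <- Inf
  while (it < max_iter) {
    it <- it + 1L
    m <- rotate_onto(m, consensus, k)
    new_cons <- colMeans(m)
    new_cons[seq_len(k)] <- new_cons[seq_len(k)] - mean(new_cons[seq_len(k)])
    new_cons[k + seq_len(k)] <- new_cons[k + seq_len(k)] -
      mean(new_cons[k + seq_len(k)])
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    change <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (change < tol) break
  }
  m <- rotate_onto(m, consensus, k)

  coords <- as_tibble(m, .name_repair = "minimal")
  names(coords) <- shape_var_names(k)
  keep <- setdiff(names(configs), shape_var_names(k))
  out <- dplyr::bind_cols(configs[, keep, drop = FALSE], coords)
  out$centroid_size <- cs

  structure(list(coords = out, consensus = vec_to_config(consensus),
                 iterations = it, rms_change = change, k = k, p = 2L * k,
                 reflect_side = reflect_side),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("Procrustes superimposition: %d records, %d landmarks\n",
              nrow(x$coords), x$k))
  cat(sprintf("  converged after %d iterations (RMS change %.2e)\n",
              x$iterations, x$rms_change))
  invisible(x)
}

#' Rotate an aligned dataset onto a reference shape
#'
#' Applies the single rotation that best superimposes the consensus on a
#' reference configuration (centered and scaled internally) to every
#' aligned record. Useful for expressing estimates in the same frame as a
#' known truth or a published mean shape.
#'
#' @param fit A `gpa_fit`.
#' @param reference k x 2 reference configuration.
#' @return The `gpa_fit` with rotated coordinates and consensus.
#' @export
align_to_reference <- function(fit, reference) {
  stopifnot(inherits(fit, "gpa_fit"))
  k <- fit$k
  ref <- center_scale(reference)
  m <- coord_matrix(fit$coords, k)
  cons <- config_to_vec(fit$consensus)
  # single rotation taking the consensus onto the reference, applied to all
  cx <- ref[, 1L]; cy <- ref[, 2L]
  a <- sum(cons[seq_len(k)] * cx + cons[k + seq_len(k)] * cy)
  b <- sum(cons[k + seq_len(k)] * cx - cons[seq_len(k)] * cy)
  h <- sqrt(a^2 + b^2)
  co <- a / h; si <- b / h
  xs <- m[, seq_len(k), drop = FALSE]; ys <- m[, k + seq_len(k), drop = FALSE]
  m_rot <- cbind(xs * co + ys * si, -xs * si + ys * co)
  fit$coords[, shape_var_names(k)] <- as_tibble(m_rot, .name_repair = "minimal")
  cons_rot <- c(cons[seq_len(k)] * co + cons[k + seq_len(k)] * si,
                -cons[seq_len(k)] * si + cons[k + seq_len(k)] * co)
  fit$consensus <- vec_to_config(cons_rot)
  fit
}

#' Procrustes distance between two configurations
#'
#' Root summed squared difference after centering, scaling to unit centroid
#' size and optimal rotation (no reflection) of `b` onto `a`.
#'
#' @param a,b k x 2 landmark matrices.
#' @return Non-negative scalar (partial Procrustes distance).
#' @export
procrustes_distance <- function(a, b) {
  a <- center_scale(a); b <- center_scale(b)
  k <- nrow(a)
  rb <- rotate_onto(matrix(config_to_vec(b), 1L), config_to_vec(a), k)
  sqrt(sum((as.numeric(rb) - config_to_vec(a))^2))
}

#' Bilateral symmetry Procrustes ANOVA
#'
#' Goodall-style decomposition of the summed squared Procrustes deviations
#' across all shape variables into individual, side (directional
#' asymmetry), individual-by-side (fluctuating asymmetry, FA) and
#' measurement-error terms. The FA term is tested against the error mean
#' square; side and individual are tested against the interaction. A
#' permutation test shuffles side labels within individuals and reports the
#' permutation p-value and a Z-score (standardized position of the observed
#' F within the permutation distribution).
#'
#' @param aligned A `gpa_fit` or its `coords` tibble (must contain
#'   `specimen_id`, `side`, `replicate` and the shape variables).
#' @param n_permutations Number of side-label permutations (0 to skip).
#' @param seed Seed for the permutation stream.
#' @return Object of class `symmetry_anova`: list with `table` (tibble:
#'   term, df, SS, MS, proportion, F, Z, p_perm), counts and settings.
#' @export
symmetry_anova <- function(aligned, n_permutations = 999L, seed = 1L) {
  coords <- if (inherits(aligned, "gpa_fit")) aligned$coords else aligned
  k <- n_landmarks(coords)
  m <- coord_matrix(coords, k)
  ind <- factor(coords$specimen_id)
  side <- factor(coords$side)
  n <- nlevels(ind)
  s <- nlevels(side)
  if (n < 2L || s != 2L) {
    abort("Symmetry ANOVA needs >= 2 individuals measured on both sides.")
  }
  N <- nrow(m)
  reps_per_cell <- N / (n * s)

  grand <- colMeans(m)
  ss_tot <- sum(sweep(m, 2L, grand)^2)

  ss_between <- function(g) {
    cnt <- as.numeric(table(g))
    mu <- rowsum(m, g) / cnt
    sum(cnt * rowSums(sweep(mu, 2L, grand)^2))
  }
  ss_ind <- ss_between(ind)
  ss_side <- ss_between(side)
  cells <- interaction(ind, side, drop = TRUE)
  ss_cells <- ss_between(cells)
  ss_ia <- ss_cells - ss_ind - ss_side
  ss_err <- ss_tot - ss_cells

  df_ind <- n - 1L
  df_side <- s - 1L
  df_ia <- (n - 1L) * (s - 1L)
  df_err <- N - n * s

  ms_ind <- ss_ind / df_ind
  ms_side <- ss_side / df_side
  ms_ia <- ss_ia / df_ia
  ms_err <- if (df_err > 0L) ss_err / df_err else NA_real_

  f_ind <- ms_ind / ms_ia
  f_side <- ms_side / ms_ia
  f_ia <- if (df_err > 0L) ms_ia / ms_err else NA_real_
  if (df_err == 0L && n_permutations == 0L) {
    warn("Single replicate: FA cannot be tested against measurement error; provide permutations or replicates.")
  }

  # permutation: shuffle side labels within individual, FA statistic
  z_ia <- p_ia <- NA_real_
  if (n_permutations > 0L) {
    ord <- order(ind)
    m_o <- m[ord, , drop = FALSE]
    ind_o <- ind[ord]
    side_o <- side[ord]
    stat_obs <- if (df_err > 0L) f_ia else ms_ia
    stats_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        perm <- order(as.integer(ind_o), runif(N))
        side_p <- side_o[perm]
        cells_p <- interaction(ind_o, side_p, drop = TRUE)
        cnt <- as.numeric(table(cells_p))
        mu <- rowsum(m_o, cells_p) / cnt
        ss_cells_p <- sum(cnt * rowSums(sweep(mu, 2L, grand)^2))
        ss_side_p <- {
          cnt_s <- as.numeric(table(side_p))
          mu_s <- rowsum(m_o, side_p) / cnt_s
          sum(cnt_s * rowSums(sweep(mu_s, 2L, grand)^2))
        }
        ss_ia_p <- ss_cells_p - ss_ind - ss_side_p
        ss_err_p <- ss_tot - ss_cells_p
        if (df_err > 0L) (ss_ia_p / df_ia) / (ss_err_p / df_err)
        else ss_ia_p / df_ia
      }, numeric(1))
    })
    p_ia <- (1 + sum(stats_perm >= stat_obs)) / (1 + n_permutations)
    z_ia <- (stat_obs - mean(stats_perm)) / sd(stats_perm)
  }

  table <- tibble(
    term = c("individual", "side", "individual:side", "error"),
    df = c(df_ind, df_side, df_ia, df_err),
    SS = c(ss_ind, ss_side, ss_ia, ss_err),
    MS = c(ms_ind, ms_side, ms_ia, ms_err),
    proportion = c(ss_ind, ss_side, ss_ia, ss_err) / ss_tot,
    F = c(f_ind, f_side, f_ia, NA_real_),
    Z = c(NA_real_, NA_real_, z_ia, NA_real_),
    p_perm = c(NA_real_, NA_real_, p_ia, NA_real_)
  )

  structure(list(table = table, n_individuals = n, n_sides = s,
                 n_replicates = reps_per_cell, n_records = N,
                 total_SS = ss_tot, n_permutations = n_permutations,
                 seed = seed),
            class = "symmetry_anova")
}

#' @export
print.symmetry_anova <- function(x, ...) {
  cat("Bilateral symmetry Procrustes ANOVA\n")
  cat(sprintf("  %d individuals x %d sides x %g replicates (%d records)\n",
              x$n_individuals, x$n_sides, x$n_replicates, x$n_records))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}
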