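# Internal helpers shared across modules. Shape variables are stored in
# "grouped" order: x1..xk then y1..yk, so a configuration vector of length
# p = 2k reshapes to a k x 2 matrix column-wise.

shape_var_names <- function(k) c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))

# number of landmarks implied by a configs tibble
n_landmarks <- function(configs) {
  xs <- grep("^x[0-9]+$", names(configs), value = TRUE)
  ys <- grep("^y[0-9]+$", names(configs), value = TRUE)
  if (length(xs) == 0L || length(xs) != length(ys)) {
    abort("`configs` must contain matched coordinate columns x1..xk, y1..yk.")
  }
  length(xs)
}

# n x p coordinate matrix in grouped order
coord_matrix <- function(configs, k = n_landmarks(configs)) {
  as.matrix(configs[, shape_var_names(k), drop = FALSE])
}

# p-vector <-> k x 2 configuration matrix
vec_to_config <- function(v) matrix(v, ncol = 2L)
config_to_vec <- function(m) as.numeric(m)

record_keys <- function(configs) {
  paste(configs$specimen_id, configs$side, configs$replicate, sep = "\r")
}

check_coord_finite <- function(configs) {
  m <- coord_matrix(configs)
  bad <- which(!stats::complete.cases(m) | rowSums(!is.finite(m)) > 0L)
  if (length(bad)) {
    abort(paste0(
      "Missing or non-finite landmark coordinates in rows: ",
      paste(head(bad, 10L), collapse = ", "),
      if (length(bad) > 10L) " ..." else ""
    ))
  }
  invisible(configs)
}

check_unique_records <- function(configs) {
  dup <- duplicated(record_keys(configs))
  if (any(dup)) {
    d <- configs[dup, c("specimen_id", "side", "replicate")]
    abort(paste0(
      "Duplicate (specimen_id, side, replicate) records: ",
      paste(head(paste(d$specimen_id, d$side, d$replicate, sep = "/"), 5L),
            collapse = ", ")
    ))
  }
  invisible(configs)
}

# symmetrize and clip eigenvalues below `floor` (relative to trace) to zero
psd_project <- function(M, floor = 0) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  n_clipped <- sum(e$values < floor)
  out <- e$vectors %*% (lam * t(e$vectors))
  attr(out, "n_clipped") <- n_clipped
  (out + t(out)) / 2
}

# numerical rank of a symmetric PSD matrix
psd_rank <- function(M, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(ev, 0, na.rm = TRUE))
}

# eigenvectors with deterministic sign: largest-magnitude element positive,
# ties broken by first index
fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# column lookup that tolerates absent columns (tibbles warn on `$` misses)
col_or <- function(df, nm) {
  if (nm %in% names(df)) df[[nm]] else rep(NA, nrow(df))
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
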