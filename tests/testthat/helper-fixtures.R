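# Shared fixtures: all synthetic, built in code at test time.

# minimal hand-built configuration tibble: n individuals x 2 sides x r reps
# of a fixed triangle-plus-noise design (k = 3), wide coordinate format
tiny_configs <- function(n = 2L, reps = 2L, k = 3L, seed = 1L,
                         noise = 0.01) {
  withr::with_seed(seed, {
    base <- matrix(c(0, 1, 0.5, 0, 0, 1), ncol = 2L) # triangle
    rows <- list()
    for (i in seq_len(n)) for (s in c("left", "right")) for (r in seq_len(reps)) {
      cfg <- base + matrix(rnorm(2 * k, 0, noise), k, 2L)
      rows[[length(rows) + 1L]] <- c(
        list(specimen_id = paste0("ind", i), side = s, replicate = r),
        setNames(as.list(c(cfg[, 1L], cfg[, 2L])),
                 c(paste0("x", 1:k), paste0("y", 1:k)))
      )
    }
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  })
}

# reduced-size simulation: same structure as the default design but fewer
# families, for cheap end-to-end tests
small_sim_params <- function(seed = 1L, n_families = 20L, n_extra = 10L) {
  pars <- default_sim_params(seed = seed)
  pars$n_families <- as.integer(n_families)
  pars$n_extra <- as.integer(n_extra)
  pars
}

# random PSD matrix with given eigenvalues (or dimension)
random_psd <- function(p, eigenvalues = NULL, seed = 1L) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
    lam <- eigenvalues %||% sort(rexp(p), decreasing = TRUE)
    Q %*% (lam * t(Q))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coordinate block of a configs tibble as a matrix (column order as stored)
cm <- function(configs) {
  as.matrix(configs[, grep("^[xy][0-9]+$", names(configs)), drop = FALSE])
}

# write a TPS file for the given configs, return its path
write_tmp_tps <- function(configs) {
  path <- withr::local_tempfile(fileext = ".tps",
                                .local_envir = parent.frame())
  write_tps(configs, path)
  path
}
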