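# End-to-end orchestration: simulate or load -> align -> symmetry ANOVA ->
# D/G/P estimation -> rank selection -> matrix comparison -> alignment
# tests, with deterministic seeding and a reproducible run manifest.

#' Build a pipeline configuration
#'
#' All analysis switches in one validated list. Numeric defaults follow
#' the study design the package emulates (q = 6 reference axes, 10 000
#' resamples and skewers); reduce them for quick runs.
#'
#' @param input Either `list(type = "simulate_default")` (the default;
#'   uses [default_sim_params()] with the pipeline seed),
#'   `list(type = "simulate", params = <sim_params>)`,
#'   `list(type = "csv", path = ...)` or `list(type = "tps", path = ...)`.
#' @param q Number of reference axes for the common-subspace comparison.
#' @param n_resamples REML-MVN draws for confidence intervals.
#' @param n_skewers Random skewer vectors.
#' @param n_permutations Side-label permutations in the symmetry ANOVA.
#' @param n_null Resamples for e_beta and angle nulls.
#' @param m_max Largest factor-model rank scanned.
#' @param method `"moment"` or `"reml"` covariance estimation.
#' @param select_ranks Run AIC rank selection (the slowest stage).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param output_dir Optional directory for JSON/CSV artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "simulate_default"),
                            q = 6L, n_resamples = 10000L,
                            n_skewers = 10000L, n_permutations = 999L,
                            n_null = 10000L, m_max = 8L,
                            method = c("moment", "reml"),
                            select_ranks = TRUE,
                            seed = 1L, output_dir = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(input), !is.null(input$type))
  if (!input$type %in% c("simulate_default", "simulate", "csv", "tps")) {
    abort("input$type must be simulate_default, simulate, csv or tps.")
  }
  structure(list(input = input, q = as.integer(q),
                 n_resamples = as.integer(n_resamples),
                 n_skewers = as.integer(n_skewers),
                 n_permutations = as.integer(n_permutations),
                 n_null = as.integer(n_null),
                 m_max = as.integer(m_max), method = method,
                 select_ranks = isTRUE(select_ranks),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Only scalar settings and file-based inputs round-trip; a configuration
#' holding an in-memory `sim_params` object cannot be serialized this way.
#'
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @return `path` / the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  if (identical(config$input$type, "simulate")) {
    abort("In-memory simulation parameters cannot be serialized; use input type 'simulate_default' or a file input.")
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage <- function(name, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
  inform(sprintf("[%s] done in %.1fs", name,
                 proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured input and returns all results;
#' identical configuration and seed give identical numeric outputs. When
#' `output_dir` is set, JSON/CSV artifacts and a manifest (input hashes,
#' seeds, package version, output checksums) are written as stages
#' complete, so partial output survives a failing stage.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_run`: list with `validation`, `gpa`,
#'   `anova`, `D`, `G`, `P`, `rank_D`, `rank_G`, `subspace`, `skewers`,
#'   `eigvec_alignment`, `shape_vectors`, `alignment_tests`, `truth` (for
#'   simulated input), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  emit_csv <- function(d, name) {
    if (!is.null(out_dir)) {
      readr::write_csv(d, file.path(out_dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
  }

  truth <- NULL
  input_hash <- NULL
  loaded <- stage("input", {
    inp <- config$input
    if (inp$type == "simulate_default") {
      sim <- simulate_landmarks(default_sim_params(seed = child_seed(seed, 1L)))
      truth <<- sim$truth
      list(configs = sim$configs, design = sim$design)
    } else if (inp$type == "simulate") {
      sim <- simulate_landmarks(inp$params)
      truth <<- sim$truth
      list(configs = sim$configs, design = sim$design)
    } else if (inp$type == "csv") {
      input_hash <<- unname(tools::md5sum(inp$path))
      read_landmark_table(inp$path)
    } else {
      input_hash <<- unname(tools::md5sum(inp$path))
      cfgs <- read_tps(inp$path)
      list(configs = cfgs, design = design_table(cfgs))
    }
  })
  configs <- loaded$configs
  design <- loaded$design

  if (config$q > 2L * n_landmarks(configs) - 4L) {
    abort(sprintf(
      "Pipeline stage 'configure' failed: q = %d exceeds the maximum shape-space rank %d (2k - 4).",
      config$q, 2L * n_landmarks(configs) - 4L))
  }

  validation <- stage("validate", validate_design(configs, design))
  if (!is.null(out_dir)) {
    write_validation_report(validation, file.path(out_dir, "validation.json"))
  }

  fit <- stage("gpa", gpa(configs))
  if (!is.null(truth)) fit <- align_to_reference(fit, truth$mean_shape)

  anova <- stage("symmetry_anova",
                 symmetry_anova(fit, n_permutations = config$n_permutations,
                                seed = child_seed(seed, 2L)))
  emit_csv(tidy(anova), "symmetry_anova")

  D <- stage("estimate_D", estimate_D(fit, design, method = config$method))
  P <- stage("estimate_P", estimate_P(fit, design, method = config$method))
  G <- stage("estimate_G", estimate_G(fit, design, method = config$method))
  for (nm in c("D", "P", "G")) {
    emit_csv(tidy(get(nm)), paste0("matrix_", nm))
  }

  rank_D <- rank_G <- NULL
  if (config$select_ranks) {
    rank_D <- stage("select_rank_D",
                    select_rank(asymmetry_strata(fit, design), config$m_max,
                                seed = child_seed(seed, 3L)))
    rank_G <- stage("select_rank_G",
                    select_rank(family_strata(fit, design), config$m_max,
                                seed = child_seed(seed, 4L)))
    emit_csv(tidy(rank_D), "rank_selection_D")
    emit_csv(tidy(rank_G), "rank_selection_G")
  }

  K <- stage("reference_basis", reference_basis(P, config$q))
  subspace <- stage("krzanowski", {
    krzanowski_compare_ci(D, G, K, n_samples = config$n_resamples,
                          seed = child_seed(seed, 5L))
  })
  skewers <- stage("random_skewers",
                   random_skewers(D, G, n_vectors = config$n_skewers,
                                  seed = child_seed(seed, 6L)))

  dmax <- reference_basis(D, 1L)[, 1L]
  gmax <- reference_basis(G, 1L)[, 1L]
  eigvec_alignment <- list(
    r = vector_correlation(dmax, gmax),
    theta = vector_angle(dmax, gmax)
  )

  beta_lat <- stage("latitude_vector",
                    fit_shape_regression(fit, design, "latitude"))
  beta_temp <- stage("temperature_vector",
                     fit_shape_regression(fit, design, "temperature"))

  tests <- stage("alignment_tests", {
    list(
      e_beta_latitude_D = e_beta_test(beta_lat, D, config$n_null,
                                      seed = child_seed(seed, 7L)),
      e_beta_temperature_D = e_beta_test(beta_temp, D, config$n_null,
                                         seed = child_seed(seed, 8L)),
      angle_latitude_dmax = angle_test(beta_lat, dmax, config$n_null,
                                       seed = child_seed(seed, 9L)),
      angle_temperature_dmax = angle_test(beta_temp, dmax, config$n_null,
                                          seed = child_seed(seed, 10L)),
      angle_latitude_gmax = angle_test(beta_lat, gmax, config$n_null,
                                       seed = child_seed(seed, 11L),
                                       reference = "gmax"),
      angle_temperature_gmax = angle_test(beta_temp, gmax, config$n_null,
                                          seed = child_seed(seed, 12L),
                                          reference = "gmax")
    )
  })

  results <- list(
    design = glance(validation),
    anova = glance(anova),
    matrices = dplyr::bind_rows(lapply(list(D, G, P), glance)),
    rank_D = if (!is.null(rank_D)) glance(rank_D),
    rank_G = if (!is.null(rank_G)) glance(rank_G),
    subspace = glance(subspace),
    skewers = glance(skewers),
    eigvec_alignment = eigvec_alignment,
    shape_vectors = dplyr::bind_rows(glance(beta_lat), glance(beta_temp)),
    alignment_tests = dplyr::bind_rows(lapply(tests, glance))
  )
  emit_json(results, "results")

  manifest <- list(
    package_version = as.character(utils::packageVersion("devomatrix")),
    seed = seed,
    method = config$method,
    input_type = config$input$type,
    input_md5 = input_hash,
    settings = list(q = config$q, n_resamples = config$n_resamples,
                    n_skewers = config$n_skewers,
                    n_permutations = config$n_permutations,
                    n_null = config$n_null, m_max = config$m_max)
  )
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$output_md5 <- as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(config = config, validation = validation, gpa = fit,
                 anova = anova, D = D, G = G, P = P,
                 rank_D = rank_D, rank_G = rank_G,
                 K = K, subspace = subspace, skewers = skewers,
                 eigvec_alignment = eigvec_alignment,
                 beta_latitude = beta_lat, beta_temperature = beta_temp,
                 alignment_tests = tests, truth = truth,
                 results = results, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("devomatrix pipeline run\n")
  cat(sprintf("  records: %d | FA proportion: %.3f (F = %.2f)\n",
              x$validation$n_records,
              x$results$anova$fa_proportion, x$results$anova$fa_F))
  cat(sprintf("  subspace r = %.3f, b = %.3f | skewers r = %.3f (p = %.3g)\n",
              x$subspace$r, x$subspace$b,
              x$skewers$mean_response_correlation, x$skewers$p_value))
  invisible(x)
}
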