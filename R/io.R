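#' Read landmark configurations from a TPS file
#'
#' Parses the minimal TpsDig-compatible dialect: `LM=` starts a record and
#' gives the landmark count, followed by that many whitespace-separated
#' coordinate lines; `ID=` carries the record identifier; `IMAGE=` is stored
#' as metadata; `SCALE=` is applied multiplicatively to the coordinates;
#' curve blocks (`CURVES=`/`POINTS=`) are ignored. Record identifiers are
#' expected to follow the `"<specimen>_<L|R>_<replicate>"` convention, since
#' TPS has no dedicated metadata slots; use the CSV interface
#' ([read_landmark_table()]) for richer designs.
#'
#' @param path Path to a TPS file.
#' @return A tibble with one row per configuration: `specimen_id`, `side`
#'   (`"left"`/`"right"`), `replicate` (integer), coordinate columns
#'   `x1..xk, y1..yk` (scaled when `SCALE=` is present), and `image`.
#' @seealso [write_tps()], [read_landmark_table()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(paste0("TPS file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) abort("No LM= records found in TPS file.")
  ends <- c(starts[-1L] - 1L, length(lines))

  records <- vector("list", length(starts))
  for (rec in seq_along(starts)) {
    block <- lines[starts[rec]:ends[rec]]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L) {
      abort(paste0("Record ", rec, ": invalid LM= count."))
    }
    body <- block[-1L]
    is_key <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_key & nzchar(body)]
    if (length(coord_lines) != k) {
      abort(paste0("Record ", rec, ": LM=", k, " but found ",
                   length(coord_lines), " coordinate lines (parse error)."))
    }
    coords <- t(vapply(strsplit(coord_lines, "\\s+"), function(z) {
      v <- suppressWarnings(as.numeric(z[1:2]))
      if (anyNA(v)) abort(paste0("Record ", rec, ": malformed coordinate line."))
      v
    }, numeric(2)))

    keyval <- function(key) {
      m <- grep(paste0("^", key, "\\s*="), body, ignore.case = TRUE, value = TRUE)
      if (length(m) == 0L) return(NA_character_)
      sub(paste0("^", key, "\\s*=\\s*"), "", m[1L], ignore.case = TRUE)
    }
    id <- keyval("ID")
    if (is.na(id)) abort(paste0("Record ", rec, ": missing ID= line."))
    scale <- suppressWarnings(as.numeric(keyval("SCALE")))
    if (!is.na(scale)) coords <- coords * scale

    parts <- strsplit(id, "_")[[1L]]
    if (length(parts) < 3L || !toupper(parts[length(parts) - 1L]) %in% c("L", "R")) {
      abort(paste0("Record ", rec, ": ID '", id,
                   "' does not follow '<specimen>_<L|R>_<replicate>'."))
    }
    n_parts <- length(parts)
    side <- if (toupper(parts[n_parts - 1L]) == "L") "left" else "right"
    replicate <- suppressWarnings(as.integer(parts[n_parts]))
    if (is.na(replicate) || replicate < 1L) {
      abort(paste0("Record ", rec, ": replicate index in ID '", id,
                   "' is not a positive integer."))
    }
    records[[rec]] <- c(
      list(specimen_id = paste(parts[seq_len(n_parts - 2L)], collapse = "_"),
           side = side, replicate = replicate,
           image = keyval("IMAGE")),
      setNames(as.list(c(coords[, 1L], coords[, 2L])), shape_var_names(k))
    )
  }

  ks <- vapply(records, function(r) (length(r) - 4L) / 2L, numeric(1))
  if (length(unique(ks)) > 1L) {
    abort("All TPS records must have the same number of landmarks.")
  }
  configs <- dplyr::bind_rows(lapply(records, as_tibble))
  configs <- configs[, c("specimen_id", "side", "replicate",
                         shape_var_names(ks[1L]), "image")]
  check_coord_finite(configs)
  check_unique_records(configs)
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: emits one `LM=` record per row with the
#' `"<specimen>_<L|R>_<replicate>"` identifier convention. Coordinates are
#' written unscaled (no `SCALE=` line).
#'
#' @param configs Tibble of configurations as produced by [read_tps()],
#'   [read_landmark_table()] or [simulate_landmarks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  k <- n_landmarks(configs)
  m <- coord_matrix(configs, k)
  out <- character(0)
  for (i in seq_len(nrow(configs))) {
    cfg <- vec_to_config(m[i, ])
    id <- paste(configs$specimen_id[i],
                if (configs$side[i] == "left") "L" else "R",
                configs$replicate[i], sep = "_")
    rec <- c(paste0("LM=", k),
             sprintf("%.10g %.10g", cfg[, 1L], cfg[, 2L]),
             if ("image" %in% names(configs) && !is.na(configs$image[i]))
               paste0("IMAGE=", configs$image[i]),
             paste0("ID=", id))
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

normalize_side <- function(side) {
  s <- tolower(as.character(side))
  s[s %in% c("l", "left")] <- "left"
  s[s %in% c("r", "right")] <- "right"
  bad <- !s %in% c("left", "right")
  if (any(bad)) {
    abort(paste0("Unrecognized side labels: ",
                 paste(unique(side[bad]), collapse = ", ")))
  }
  s
}

design_metadata_cols <- c("family_id", "population_id", "latitude",
                          "temperature", "cohort", "species")

#' Read landmark configurations and design metadata from a CSV table
#'
#' The canonical rich input format: one row per digitization with columns
#' `specimen_id`, `side`, `replicate`, `x1..xk`, `y1..yk` plus optional
#' metadata columns (`family_id`, `population_id`, `latitude`,
#' `temperature`, `cohort`, `species`). Metadata are split off into a
#' per-specimen design table.
#'
#' @param path Path to a CSV file (RFC-4180).
#' @return A list with elements `configs` (tibble of configurations) and
#'   `design` (tibble with one row per specimen, see [design_table()]).
#' @export
read_landmark_table <- function(path) {
  if (!file.exists(path)) abort(paste0("CSV file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("specimen_id", "side", "replicate")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    abort(paste0("Schema error: missing mandatory column(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  k <- n_landmarks(raw)
  raw$side <- normalize_side(raw$side)
  raw$replicate <- as.integer(raw$replicate)
  configs <- raw[, c(mandatory, shape_var_names(k),
                     intersect(design_metadata_cols, names(raw)))]
  check_coord_finite(configs)
  check_unique_records(configs)
  list(configs = configs, design = design_table(configs))
}

#' Write landmark configurations (with metadata) to CSV
#'
#' @inheritParams write_tps
#' @param design Optional design table to join onto the configurations
#'   before writing.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(configs, path, design = NULL) {
  out <- configs
  if (!is.null(design)) {
    out <- dplyr::left_join(
      out[, setdiff(names(out), setdiff(design_metadata_cols, "specimen_id"))],
      design, by = "specimen_id")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract the per-specimen design table from a configuration tibble
#'
#' One row per specimen carrying whichever of `family_id`, `population_id`,
#' `latitude`, `temperature`, `cohort`, `species` are present. Checks that
#' metadata are constant within specimen and that each family maps to a
#' single population and latitude.
#'
#' @param configs Tibble of configurations with metadata columns.
#' @return A tibble with one row per `specimen_id`.
#' @export
design_table <- function(configs) {
  meta <- intersect(design_metadata_cols, names(configs))
  design <- dplyr::distinct(configs[, c("specimen_id", meta), drop = FALSE])
  if (anyDuplicated(design$specimen_id)) {
    dup <- unique(design$specimen_id[duplicated(design$specimen_id)])
    abort(paste0("Metadata differ across records of specimen(s): ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  if (all(c("family_id", "population_id") %in% meta)) {
    fam <- dplyr::distinct(design[!is.na(design$family_id),
                                  c("family_id", "population_id")])
    if (anyDuplicated(fam$family_id)) {
      abort("Each family_id must map to exactly one population_id.")
    }
  }
  if (all(c("family_id", "latitude") %in% meta)) {
    fam <- dplyr::distinct(design[!is.na(design$family_id),
                                  c("family_id", "latitude")])
    if (anyDuplicated(fam$family_id)) {
      abort("Each family_id must map to exactly one latitude.")
    }
  }
  design
}

#' Validate completeness of a bilateral measurement design
#'
#' Reports, without erroring, how many individuals, sides and replicates the
#' dataset contains and which (specimen, side, replicate) cells are missing
#' relative to the full crossed design.
#'
#' @param configs Tibble of configurations.
#' @param design Optional design table (only used for the specimen count
#'   cross-check).
#' @return An object of class `validation_report`: a list with counts
#'   (`n_individuals`, `n_sides`, `n_replicates`, `n_records`,
#'   `n_landmarks`, `n_shape_variables`), a tibble `imbalance` of incomplete
#'   specimens, `n_flags`, and `complete`.
#' @export
validate_design <- function(configs, design = NULL) {
  if (nrow(configs) == 0L) {
    rep <- list(n_individuals = 0L, n_sides = 0L, n_replicates = 0L,
                n_records = 0L, n_landmarks = 0L, n_shape_variables = 0L,
                imbalance = tibble(specimen_id = character(),
                                   n_records = integer()),
                n_flags = 0L, complete = TRUE)
    class(rep) <- "validation_report"
    return(rep)
  }
  k <- n_landmarks(configs)
  sides <- sort(unique(configs$side))
  reps <- sort(unique(configs$replicate))
  counts <- dplyr::count(configs, .data$specimen_id, name = "n_records")
  expected <- length(sides) * length(reps)
  imbalance <- counts[counts$n_records != expected, , drop = FALSE]
  rep <- list(
    n_individuals = nrow(counts),
    n_sides = length(sides),
    n_replicates = length(reps),
    n_records = nrow(configs),
    n_landmarks = k,
    n_shape_variables = 2L * k,
    imbalance = as_tibble(imbalance),
    n_flags = nrow(imbalance),
    complete = nrow(imbalance) == 0L
  )
  if (!is.null(design)) {
    rep$n_design_specimens <- nrow(design)
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Bilateral design validation\n")
  cat(sprintf("  individuals: %d | sides: %d | replicates: %d\n",
              x$n_individuals, x$n_sides, x$n_replicates))
  cat(sprintf("  records: %d | landmarks: %d | shape variables: %d\n",
              x$n_records, x$n_landmarks, x$n_shape_variables))
  if (x$complete) cat("  design complete: no flagged cells\n")
  else cat(sprintf("  %d specimen(s) with incomplete cells\n", x$n_flags))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A `validation_report` from [validate_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
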