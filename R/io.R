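#' Read a dense connectivity matrix from a text file
#'
#' Accepts whitespace- or comma-delimited square numeric tables with no
#' header; the delimiter is auto-detected from the first non-empty line.
#'
#' @param path File path.
#' @param kind `"structural"`, `"functional"`, or `NULL` to return the
#'   bare numeric matrix without kind validation.
#' @return A [connectivity_matrix()] (or plain matrix if `kind = NULL`).
#' @export
read_matrix <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path, call. = FALSE)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "[[:space:]]+"
  rows <- lapply(seq_along(lines), function(r) {
    cells <- strsplit(trimws(lines[[r]]), sep)[[1]]
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("non-numeric cell at row %d, column %d of %s: '%s'",
                   r, bad, path, cells[bad]), call. = FALSE)
    }
    vals
  })
  len <- lengths(rows)
  if (length(unique(len)) > 1) {
    bad <- which(len != len[1])[1]
    stop(sprintf("ragged table in %s: row %d has %d columns, expected %d",
                 path, bad, len[bad], len[1]), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in %s is not square: %d rows x %d columns",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  if (is.null(kind)) m else connectivity_matrix(m, kind)
}

#' @rdname read_matrix
#' @param m Matrix to write.
#' @param digits Significant digits preserved (17 round-trips doubles).
#' @export
write_matrix <- function(m, path, digits = 17) {
  m <- if (is_connectivity_matrix(m)) unclass_matrix(m) else m
  lines <- apply(m, 1, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Write or read a cohort directory
#'
#' The on-disk layout is one `sub-<k>_sc.txt` and `sub-<k>_fc.txt` dense
#' matrix file per subject plus a `manifest.json` recording the schema
#' version, subject ids and split labels (and, for synthetic cohorts, the
#' generating spec).
#'
#' @param cohort An `aghn_cohort`.
#' @param dir Directory path (created if missing).
#' @param spec Optional [synthetic_spec()] echoed into the manifest.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns an `aghn_cohort`.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(cohort$pairs)) {
    p <- cohort$pairs[[k]]
    write_matrix(p$sc, file.path(dir, sprintf("sub-%03d_sc.txt", k)))
    write_matrix(p$fc, file.path(dir, sprintf("sub-%03d_fc.txt", k)))
  }
  manifest <- list(
    schema_version = 1L,
    n_regions = cohort$n_regions,
    n_subjects = length(cohort$pairs),
    ids = vapply(cohort$pairs, function(p) p$id %||% NA_character_,
                 character(1)),
    split = cohort$split)
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop("no manifest.json in cohort directory: ", dir, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(mpath)
  pairs <- lapply(seq_len(manifest$n_subjects), function(k) {
    list(sc = read_matrix(file.path(dir, sprintf("sub-%03d_sc.txt", k)),
                          "structural"),
         fc = read_matrix(file.path(dir, sprintf("sub-%03d_fc.txt", k)),
                          "functional"),
         id = manifest$ids[[k]])
  })
  make_cohort(pairs, manifest$split)
}

# ---- run configuration ----------------------------------------------------

run_config_defaults <- function() {
  list(schema_version = 1L,
       scales = c(0.6, 0.8, 1, 2, 4, 6, 8),
       n_layers = 1L,
       learning_rate = 0.001, weight_decay = 5e-4, dropout_keep = 0.5,
       max_epochs = 100L, patience = 10L, batch_size = 16L,
       exclude_diagonal = FALSE,
       variant = "aghn",
       n_regions = 30L, n_subjects = 100L, edge_density = 0.4,
       powerlaw_exponent = 3, weight_min = 0.01,
       planted_scales = c(0.6, 2, 6), planted_mixture = c(0.5, 0.3, 0.2),
       planted_weight_scale = 2, noise_sigma = 0.05,
       split_sizes = NULL,
       n_replicates = 25L,
       resolution = 1,
       seed = 1L)
}

#' Read and validate a JSON run configuration
#'
#' Fills defaults for missing keys and rejects unknown keys before any
#' computation starts. The resolved configuration can be echoed beside
#' outputs for provenance with [write_run_config()].
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file values.
#' @return Named list with class `aghn_run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- run_config_defaults()
  values <- if (is.null(path)) list() else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  for (nm in names(overrides)) values[[nm]] <- overrides[[nm]]
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, values, keep.null = TRUE)
  if (!identical(as.integer(cfg$schema_version), 1L)) {
    stop("unsupported configuration schema_version: ", cfg$schema_version,
         call. = FALSE)
  }
  if (!cfg$variant %in% c("aghn", "m_ghn", "random_aghn")) {
    stop("unknown variant: ", cfg$variant, call. = FALSE)
  }
  structure(cfg, class = "aghn_run_config")
}

#' @rdname read_run_config
#' @param config An `aghn_run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# Derived objects from a resolved run configuration.
config_scale <- function(cfg) {
  aghn_config(scales = cfg$scales, n_layers = cfg$n_layers,
              n_regions = cfg$n_regions)
}

config_train <- function(cfg) {
  train_config(learning_rate = cfg$learning_rate,
               weight_decay = cfg$weight_decay,
               dropout_keep = cfg$dropout_keep,
               max_epochs = cfg$max_epochs, patience = cfg$patience,
               batch_size = cfg$batch_size, seed = cfg$seed,
               exclude_diagonal = cfg$exclude_diagonal)
}

config_synthetic <- function(cfg) {
  synthetic_spec(n_regions = cfg$n_regions, n_subjects = cfg$n_subjects,
                 edge_density = cfg$edge_density,
                 powerlaw_exponent = cfg$powerlaw_exponent,
                 weight_min = cfg$weight_min,
                 planted_scales = cfg$planted_scales,
                 planted_mixture = cfg$planted_mixture,
                 planted_weight_scale = cfg$planted_weight_scale,
                 noise_sigma = cfg$noise_sigma,
                 split_sizes = cfg$split_sizes,
                 seed = cfg$seed)
}
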