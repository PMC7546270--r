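# Reading/writing digitizer-style point series and rendering parameter
# report tables.
#
# The series file format mirrors two-column graph-digitizer exports: an
# optional block of '#'-prefixed metadata comment lines, an optional header,
# then one (x, y) pair per line, comma- or tab-delimited (auto-detected),
# decimal point '.'. Digitized points carry no error bars, so the schema has
# no uncertainty column.

series_meta_fields <- c("species", "pathway", "predictor_kind",
                        "predictor_name", "co2_partial_pressure_Pa",
                        "x_units", "y_units", "source_ref", "series_id")

#' Write a series to a digitizer-style CSV file
#'
#' Emits the metadata as `# key: value` comment lines, a `x,y` header, and
#' the points at full precision (17 significant digits, so a read round-trip
#' is exact). Output is byte-identical across writes of the same series.
#'
#' @param series A `response_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "response_series"))
  meta <- vapply(series_meta_fields, function(f) {
    v <- series[[f]]
    sprintf("# %s: %s", f, if (is.numeric(v)) sprintf("%.17g", v) else v)
  }, character(1))
  lines <- c(meta, "x,y",
             sprintf("%.17g,%.17g", series$x, series$y))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    edm_stop(sprintf("Cannot open '%s' for writing: %s", path,
                     conditionMessage(e)), "edm_io_error")
  })
  on.exit(close(con))
  # fixed newline so files hash identically across platforms
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

parse_meta_line <- function(line) {
  m <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1]]
  if (length(m) != 3L) return(NULL)
  stats::setNames(list(trimws(m[3])), trimws(m[2]))
}

#' Read a digitizer-style series CSV file
#'
#' Parses a two-column delimited text file (comma or tab, auto-detected) into
#' a [response_series()]. Blank lines and `#` comment lines are skipped;
#' `# key: value` comments are interpreted as series metadata, which explicit
#' arguments in `...` override. A non-numeric cell is rejected with the
#' offending row number; a nonpositive response is rejected citing the
#' log-transform requirement.
#'
#' @param path Input file path.
#' @param ... Metadata overrides passed on to [response_series()] (e.g.
#'   `species`, `pathway`, `predictor_kind`).
#' @return A `response_series`.
#' @export
read_series_csv <- function(path, ...) {
  if (!file.exists(path)) {
    edm_stop(sprintf("File not found: '%s'.", path), "edm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  data_rows <- list()
  row_no <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- parse_meta_line(ln)
      if (!is.null(kv)) meta[names(kv)] <- kv
      next
    }
    delim <- if (grepl("\t", ln)) "\t" else ","
    cells <- trimws(strsplit(ln, delim, fixed = TRUE)[[1]])
    if (length(cells) < 2L) {
      edm_stop(sprintf("Line %d of '%s' has fewer than two columns.", i, path),
               "edm_parse_error")
    }
    # skip a header line (first non-comment line with non-numeric cells)
    vals <- suppressWarnings(as.numeric(cells[1:2]))
    if (anyNA(vals)) {
      if (row_no == 0L) next  # header
      edm_stop(sprintf("Non-numeric value on line %d of '%s'.", i, path),
               "edm_parse_error")
    }
    row_no <- row_no + 1L
    data_rows[[row_no]] <- vals
  }
  if (row_no < 3L) {
    edm_stop(sprintf("'%s' holds %d data rows; at least 3 are required.",
                     path, row_no),
             "edm_insufficient_data")
  }
  pts <- do.call(rbind, data_rows)
  if (any(pts[, 2] <= 0)) {
    edm_stop(paste0("Nonpositive response value in '", path,
                    "': responses must be strictly positive because they ",
                    "are log-transformed before the saturation fit."),
             "edm_validation_error")
  }
  args <- meta[intersect(names(meta), series_meta_fields)]
  if (!is.null(args$co2_partial_pressure_Pa)) {
    v <- args$co2_partial_pressure_Pa
    args$co2_partial_pressure_Pa <-
      if (v %in% c("NA", "NaN", "")) NA_real_ else as.numeric(v)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(response_series, c(list(x = pts[, 1], y = pts[, 2]), args))
}

#' Construct a series registry
#'
#' A registry maps series identifiers to file paths plus the metadata needed
#' to interpret each series, with a free-text provenance per entry. Entries
#' whose file is missing at load time are flagged, not fatal, so a partial
#' collection still builds.
#'
#' @param series_id Character vector of unique identifiers.
#' @param path Character vector of file paths.
#' @param species,pathway,predictor_kind,predictor_name Metadata vectors
#'   (recycled).
#' @param co2_partial_pressure_Pa Numeric vector (recycled).
#' @param provenance Free-text citation per entry.
#' @return A `series_registry` (a data frame with one row per entry).
#' @export
series_registry <- function(series_id, path, species = "unspecified",
                            pathway = "C3",
                            predictor_kind = "enzyme_activity",
                            predictor_name = "",
                            co2_partial_pressure_Pa = NA_real_,
                            provenance = "") {
  if (anyDuplicated(series_id)) {
    edm_stop("`series_id` values must be unique.", "edm_validation_error")
  }
  n <- length(series_id)
  species <- rep_len(species, n)
  pathway <- rep_len(pathway, n)
  predictor_kind <- rep_len(predictor_kind, n)
  predictor_name <- rep_len(predictor_name, n)
  co2_partial_pressure_Pa <- rep_len(as.numeric(co2_partial_pressure_Pa), n)
  provenance <- rep_len(provenance, n)
  df <- data.frame(series_id = series_id, path = path, species = species,
                   pathway = pathway, predictor_kind = predictor_kind,
                   predictor_name = predictor_name,
                   co2_partial_pressure_Pa = co2_partial_pressure_Pa,
                   provenance = provenance, stringsAsFactors = FALSE)
  class(df) <- c("series_registry", "data.frame")
  df
}

#' Write / read a registry file
#'
#' The registry is stored as a plain tab-separated text file with a header.
#'
#' @param registry A `series_registry`.
#' @param path Registry file path.
#' @return `write_registry`: `path` invisibly. `read_registry`: a
#'   `series_registry`.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "series_registry"))
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    edm_stop(sprintf("Registry file not found: '%s'.", path), "edm_io_error")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, fill = TRUE,
                          stringsAsFactors = FALSE)
  for (col in c("species", "pathway", "predictor_kind", "predictor_name",
                "provenance")) {
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  }
  do.call(series_registry, as.list(df))
}

#' Load every series referenced by a registry
#'
#' Missing files degrade to flagged entries with a warning (so a collection
#' can be processed before all its files exist); present files are parsed
#' with the registry row's metadata.
#'
#' @param registry A `series_registry`.
#' @param base_dir Optional directory that relative paths resolve against.
#' @return List with `series` (named list of `response_series`) and
#'   `missing` (character vector of series_ids whose file was absent).
#' @export
load_registry_series <- function(registry, base_dir = NULL) {
  stopifnot(inherits(registry, "series_registry"))
  series <- list()
  missing <- character(0)
  for (i in seq_len(nrow(registry))) {
    p <- registry$path[i]
    if (!is.null(base_dir)) p <- file.path(base_dir, p)
    if (!file.exists(p)) {
      warning(sprintf("series '%s': file '%s' is missing; entry skipped",
                      registry$series_id[i], p), call. = FALSE)
      missing <- c(missing, registry$series_id[i])
      next
    }
    series[[registry$series_id[i]]] <- read_series_csv(
      p,
      species = registry$species[i],
      pathway = registry$pathway[i],
      predictor_kind = registry$predictor_kind[i],
      predictor_name = registry$predictor_name[i],
      co2_partial_pressure_Pa = registry$co2_partial_pressure_Pa[i],
      series_id = registry$series_id[i])
  }
  list(series = series, missing = missing)
}

fmt_est_se <- function(est, se) {
  if (is.na(se)) {
    sprintf("%s (NA)", format(signif(est, 4)))
  } else {
    sprintf("%s (%s)", format(signif(est, 4)), format(signif(se, 3)))
  }
}

#' Render a parameter report table
#'
#' Shapes a collection of fits into one of the package's two report layouts:
#' `"table1"` — one row per exponential enzyme fit, with `estimate (SE)`
#' cells for the assimilation scale (alpha) and activity coefficient (b)
#' plus R^2; `"table2"` — nitrogen-response fits as columns (one per
#' species/CO2 condition) with rows ln_P_max, Kp and R^2. Estimates are
#' shown to 4 significant figures, standard errors to 3. Mixing model kinds
#' within one layout is a validation error; an empty input yields the header
#' only.
#'
#' @param results List of `edm_fit` objects (all converged or flagged).
#' @param layout `"table1"` or `"table2"`.
#' @param labels Optional column/row labels; defaults to the fits'
#'   `series_id`.
#' @return A data frame in the requested layout.
#' @export
render_parameter_table <- function(results, layout = c("table1", "table2"),
                                   labels = NULL) {
  layout <- match.arg(layout)
  if (length(results) == 0) {
    return(if (layout == "table1") {
      data.frame(predictor = character(0), P = character(0),
                 vp = character(0), R2 = character(0))
    } else {
      data.frame(parameter = c("ln_P_max", "Kp", "R2"))
    })
  }
  kinds <- vapply(results, `[[`, character(1), "model_kind")
  if (is.null(labels)) {
    labels <- vapply(results, `[[`, character(1), "series_id")
  }
  if (layout == "table1") {
    if (!all(kinds == "exponential")) {
      edm_stop("layout 'table1' accepts exponential fits only.",
               "edm_validation_error")
    }
    data.frame(
      predictor = labels,
      P = vapply(results, function(f)
        fmt_est_se(f$params$alpha, f$se[["alpha"]]), character(1)),
      vp = vapply(results, function(f)
        fmt_est_se(f$params$b, f$se[["b"]]), character(1)),
      R2 = vapply(results, function(f)
        sprintf("%.2f", f$r_squared), character(1)),
      stringsAsFactors = FALSE)
  } else {
    if (!all(startsWith(kinds, "resource_response"))) {
      edm_stop("layout 'table2' accepts resource-response fits only.",
               "edm_validation_error")
    }
    out <- data.frame(parameter = c("ln_P_max", "Kp", "R2"),
                      stringsAsFactors = FALSE)
    for (i in seq_along(results)) {
      f <- results[[i]]
      out[[labels[i]]] <- c(format(signif(f$params$ln_P_max, 4)),
                            format(signif(f$params$Kp, 4)),
                            sprintf("%.2f", f$r_squared))
    }
    out
  }
}

#' Parse an `estimate (SE)` report cell
#'
#' Inverse of the report formatting: recovers the numeric estimate and
#' standard error from a cell such as `"17.37 (0.906)"`.
#'
#' @param cell Character vector of cells.
#' @return Data frame with columns `estimate`, `se`.
#' @export
parse_est_se <- function(cell) {
  m <- regmatches(cell, regexec("^\\s*([-0-9.eE+]+)\\s*\\(([^)]*)\\)", cell))
  est <- vapply(m, function(g) as.numeric(g[2]), numeric(1))
  se <- vapply(m, function(g) suppressWarnings(as.numeric(g[3])), numeric(1))
  data.frame(estimate = est, se = se)
}
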