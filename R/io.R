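# Reading and writing measurement tables (CSV, comma + dot-decimal, header).

#' Read a measurement table from CSV
#'
#' Expects a header with columns `scenario_id`, `observable`, `time_weeks`,
#' `mean`, `sd`, `n` and optionally `holdout`. Malformed rows are reported
#' with their line number in the file (header = line 1). An empty file with
#' a valid header yields an empty table with a warning.
#'
#' @param path CSV file path.
#' @return A validated measurement tibble.
#' @seealso [write_measurements()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop("measurement file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("scenario_id", "observable", "time_weeks", "mean", "sd", "n")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("no measurement rows in ", path, call. = FALSE)
    return(tibble::tibble(scenario_id = character(), observable = character(),
                          time_weeks = numeric(), mean = numeric(),
                          sd = numeric(), n = numeric(), holdout = logical()))
  }

  line <- seq_len(nrow(raw)) + 1L
  problems <- character()
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v)
    if (any(bad)) {
      problems <<- c(problems,
                     paste0("line ", line[bad], ": non-numeric '", col, "' (",
                            ifelse(is.na(raw[[col]][bad]), "missing",
                                   raw[[col]][bad]), ")"))
    }
    v
  }
  out <- tibble::tibble(
    scenario_id = raw$scenario_id,
    observable = raw$observable,
    time_weeks = num("time_weeks"),
    mean = num("mean"),
    sd = num("sd"),
    n = num("n")
  )
  if ("holdout" %in% names(raw)) {
    h <- toupper(trimws(raw$holdout))
    hv <- h %in% c("TRUE", "T", "1")
    bad <- !h %in% c("TRUE", "T", "1", "FALSE", "F", "0")
    if (any(bad)) {
      problems <- c(problems, paste0("line ", line[bad],
                                     ": invalid 'holdout' value"))
    }
    out$holdout <- hv
  } else {
    out$holdout <- FALSE
  }
  badobs <- !out$observable %in% .observable_kinds
  if (any(badobs)) {
    problems <- c(problems,
                  paste0("line ", line[badobs], ": unknown observable '",
                         out$observable[badobs], "'"))
  }
  if (length(problems) > 0) {
    stop("invalid measurement rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  # numeric scenario ids come back as numbers for the built-in designs
  ids <- suppressWarnings(as.numeric(out$scenario_id))
  if (!any(is.na(ids))) out$scenario_id <- ids
  .validate_measurements(out)
}

#' Write a measurement table to CSV
#'
#' @param data A measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  data <- .validate_measurements(data)
  readr::write_csv(data[.measurement_cols], path, progress = FALSE)
  invisible(path)
}
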