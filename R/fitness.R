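# Weighted least-squares (chi-square) fitness over measurement tables.

.measurement_cols <- c("scenario_id", "observable", "time_weeks",
                       "mean", "sd", "n", "holdout")

# effective sigma of a record: the reported group SD, replaced by a floor
# when the SD is unusable (zero, or a single-animal group)
.sigma_effective <- function(mean, sd, n, floor_frac = 0.1, floor_min = 1e-6) {
  use_floor <- !is.finite(sd) | sd <= 0 | n < 2
  out <- sd
  out[use_floor] <- pmax(floor_frac * abs(mean[use_floor]), floor_min)
  out
}

.validate_measurements <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"holdout" %in% names(data)) data$holdout <- FALSE
  missing <- setdiff(.measurement_cols, names(data))
  if (length(missing) > 0) {
    stop("measurement table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(data$observable), .observable_kinds)
  if (length(bad) > 0) {
    stop("unknown observable kind(s): ", paste(bad, collapse = ", "),
         "; use ", paste(.observable_kinds, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(data$time_weeks)) || any(data$time_weeks < 0)) {
    stop("time_weeks must be finite, non-negative ages", call. = FALSE)
  }
  if (any(!is.finite(data$mean))) stop("mean must be finite", call. = FALSE)
  if (any(is.finite(data$sd) & data$sd < 0)) {
    stop("sd must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(data$n) | data$n < 1)) {
    stop("group size n must be >= 1", call. = FALSE)
  }
  data
}

# resolve the scenario object for every id in the table
.scenario_list <- function(ids, scenarios = NULL) {
  out <- list()
  for (id in ids) {
    key <- as.character(id)
    if (!is.null(scenarios) && key %in% names(scenarios)) {
      out[[key]] <- scenarios[[key]]
    } else if (suppressWarnings(!is.na(as.integer(id))) &&
               as.integer(id) %in% 1:13) {
      out[[key]] <- builtin_scenario(as.integer(id))
    } else {
      stop("no scenario definition for id '", id,
           "'; pass it via `scenarios`", call. = FALSE)
    }
  }
  out
}

# lean prediction path used by the optimizer: no tibble/join overhead
.model_at <- function(params, factors, scn, weeks, rtol, atol) {
  din <- build_din(scn, factors)
  days <- sort(unique(weeks)) * 7
  sol <- .integrate_piecewise(params, din, t_end = max(days), out_days = days,
                              rtol = rtol, atol = atol)
  data.frame(
    time_weeks = sol$time / 7,
    LDL_blood = sol$L_B * params$L_B_nor,
    MONO_blood = sol$MONO_B * params$MONO_B_nor,
    lesion_area_pct = 100 * (1 - sol$R^2)
  )
}

# model column for a validated table; identical result to the tidy route
.model_column <- function(params, factors, data, scenarios, rtol, atol) {
  scns <- .scenario_list(unique(data$scenario_id), scenarios)
  model <- numeric(nrow(data))
  for (key in names(scns)) {
    idx <- which(as.character(data$scenario_id) == key)
    sub <- data[idx, ]
    if (any(sub$time_weeks <= 0)) {
      stop("records need a positive age", call. = FALSE)
    }
    pred <- .model_at(params, factors, scns[[key]], sub$time_weeks,
                      rtol, atol)
    row <- match(round(sub$time_weeks * 7, 9), round(pred$time_weeks * 7, 9))
    model[idx] <- vapply(seq_along(idx), function(j) {
      pred[[sub$observable[j]]][row[j]]
    }, numeric(1))
  }
  model
}

#' Model predictions at the times of a measurement table
#'
#' Simulates every scenario present in `data` up to its latest record and
#' returns the table augmented with the model value of each record's
#' observable at its time (column `model`).
#'
#' @param params An [athero_params()] object.
#' @param factors An [athero_factors()] object.
#' @param data A measurement table: columns `scenario_id`, `observable`
#'   (`LDL_blood`, `MONO_blood` or `lesion_area_pct`), `time_weeks`, `mean`,
#'   `sd`, `n` and optionally `holdout`.
#' @param scenarios Optional named list of [scenario()] objects keyed by
#'   `scenario_id`, for ids other than the built-in 1-13.
#' @param rtol,atol Solver tolerances.
#' @return The measurement tibble with an extra `model` column.
#' @export
predict_measurements <- function(params, factors, data, scenarios = NULL,
                                 rtol = 1e-10, atol = 1e-10) {
  data <- .validate_measurements(data)
  if (nrow(data) == 0) return(dplyr::mutate(data, model = numeric(0)))
  data$model <- .model_column(params, factors, data, scenarios, rtol, atol)
  data
}

#' Chi-square fitness of a parameter set against measurements
#'
#' The goal function of parameter estimation: the sum over all (non-holdout)
#' records of the squared standardized residual
#' `((model - mean) / sigma)^2`, where `sigma` is the record's reported
#' group standard deviation. Records flagged `holdout` are excluded (they
#' are reserved for validating predictions). Fitting across several
#' scenarios simply adds their per-scenario sums, so the fitness is
#' invariant to how records are grouped or ordered.
#'
#' Records with an unusable spread (`sd = 0` or a single animal) get a
#' floored sigma of `sigma_floor_frac * |mean|`, at least
#' `sigma_floor_min`.
#'
#' @inheritParams predict_measurements
#' @param include_holdout If `TRUE`, holdout records enter the sum as well
#'   (used for validation summaries, never for fitting).
#' @param sigma_floor_frac,sigma_floor_min Floor rule for unusable SDs.
#' @return A single non-negative number; 0 means the model passes exactly
#'   through every mean.
#' @export
#' @examples
#' # a single record two standard deviations off contributes exactly 4
fitness <- function(params, factors, data, scenarios = NULL,
                    include_holdout = FALSE,
                    sigma_floor_frac = 0.1, sigma_floor_min = 1e-6,
                    rtol = 1e-10, atol = 1e-10) {
  pred <- .validate_measurements(data)
  if (!include_holdout) pred <- pred[!pred$holdout, , drop = FALSE]
  if (nrow(pred) == 0) return(0)
  pred$model <- .model_column(params, factors, pred, scenarios, rtol, atol)
  sig <- .sigma_effective(pred$mean, pred$sd, pred$n,
                          sigma_floor_frac, sigma_floor_min)
  sum(((pred$model - pred$mean) / sig)^2)
}
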