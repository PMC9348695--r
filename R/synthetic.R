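# Synthetic measurement tables with the statistical structure of the study.

#' Define a synthetic measurement design
#'
#' A design is a table of planned measurements: which scenario, which
#' observable, at which age, how many animals per group and which
#' coefficient of variation (CV) the between-animal noise has. The
#' generator simulates the model, draws `n` individual animals per planned
#' point and summarizes them to group mean/SD — the exact data shape the
#' fitting machinery consumes.
#'
#' @param scenario_id Scenario ids (recycled against the other columns).
#' @param observable Observable kinds (`LDL_blood`, `MONO_blood`,
#'   `lesion_area_pct`).
#' @param time_weeks Measurement ages in weeks.
#' @param n Animals per group (>= 2).
#' @param cv Coefficient of variation of individual animals around the
#'   model value (>= 0; 0 gives noise-free data).
#' @param holdout Flag records excluded from fitting.
#' @return A tibble of class `athero_design`.
#' @seealso [study_design()], [generate_measurements()]
#' @export
synth_design <- function(scenario_id, observable, time_weeks, n = 8,
                         cv = 0.1, holdout = FALSE) {
  out <- tibble::tibble(scenario_id = scenario_id, observable = observable,
                        time_weeks = time_weeks, n = n, cv = cv,
                        holdout = holdout)
  bad <- setdiff(unique(out$observable), .observable_kinds)
  if (length(bad) > 0) {
    stop("unknown observable kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(out$n < 2)) stop("group size n must be >= 2", call. = FALSE)
  if (any(out$cv < 0)) stop("cv must be >= 0", call. = FALSE)
  if (any(out$time_weeks <= 0)) {
    stop("time_weeks must be positive ages", call. = FALSE)
  }
  class(out) <- c("athero_design", class(out))
  out
}

#' The sparse thirteen-scenario study design
#'
#' Returns a measurement design emulating the study the model was built on:
#' all thirteen diet/treatment scenarios, blood LDL-C and lesion area as
#' observables, and sparse measurement ages. The in-house scenarios are read
#' out at ages 22 and 28 weeks (6 and 12 weeks on the assigned diet), with
#' the week-28 points of the two untreated scenarios 2 and 4 flagged as
#' holdout — they validate model predictions and never enter the fitness.
#' The literature scenarios contribute two to three points across a longer
#' life span (their exact published ages are not part of this package; the
#' ages used here are stated assumptions of the generator).
#'
#' @param n_experiment,n_literature Animals per group for in-house and
#'   literature scenarios.
#' @param cv_LDL,cv_lesion Coefficients of variation of the two observables.
#' @return An `athero_design` tibble.
#' @export
study_design <- function(n_experiment = 8, n_literature = 4,
                         cv_LDL = 0.10, cv_lesion = 0.15) {
  own <- setdiff(1:13, c(1, 3, 5))
  lit_times <- list(`1` = c(26, 52), `3` = c(26, 52), `5` = c(14, 20, 26))
  rows <- list()
  for (id in 1:13) {
    times <- if (id %in% c(1, 3, 5)) lit_times[[as.character(id)]] else c(22, 28)
    n <- if (id %in% own) n_experiment else n_literature
    for (obs in c("LDL_blood", "lesion_area_pct")) {
      cv <- if (obs == "LDL_blood") cv_LDL else cv_lesion
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario_id = id, observable = obs, time_weeks = times,
        n = n, cv = cv,
        holdout = id %in% c(2, 4) & times == 28
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("athero_design", class(out))
  out
}

#' Generate a synthetic measurement table from known parameters
#'
#' Simulates every scenario of the design under the given ("true")
#' parameters, then draws `n` individual animal values per planned point
#' from a normal law centred on the model observable with standard
#' deviation `cv * value` (truncated at zero by redrawing, since all
#' observables are non-negative), and records the empirical group mean, SD
#' and n. With `cv = 0` the table reproduces the model outputs exactly with
#' zero SDs.
#'
#' The generating truth is attached as attribute `truth`, so recovery
#' studies can close the loop: `fitness(truth, generated data)` is zero for
#' noise-free designs.
#'
#' @param params True [athero_params()].
#' @param factors True [athero_factors()].
#' @param design An [synth_design()] or [study_design()] table.
#' @param seed Integer RNG seed; generation is bit-reproducible given the
#'   seed.
#' @param scenarios Optional named scenario list for non-built-in ids.
#' @return A measurement tibble (columns `scenario_id`, `observable`,
#'   `time_weeks`, `mean`, `sd`, `n`, `holdout`) with attribute `truth`
#'   (list: `params`, `factors`, `design`, `seed`).
#' @export
#' @examples
#' d <- synth_design(1, "lesion_area_pct", c(26, 52), n = 4, cv = 0)
#' generate_measurements(athero_params(), athero_factors(), d, seed = 1)
generate_measurements <- function(params, factors, design, seed = 1L,
                                  scenarios = NULL) {
  stopifnot(inherits(params, "athero_params"),
            inherits(factors, "athero_factors"))
  design <- tibble::as_tibble(design)
  set.seed(seed)
  scns <- .scenario_list(unique(design$scenario_id), scenarios)
  parts <- lapply(split(design, design$scenario_id), function(sub) {
    scn <- scns[[as.character(sub$scenario_id[1])]]
    tr <- tryCatch(
      simulate_model(params, scenario_ = scn, factors = factors,
                     t_end_weeks = max(sub$time_weeks),
                     output_weeks = unique(sub$time_weeks)),
      error = function(e) {
        stop("simulation failed for scenario ", scn$id, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    long <- tidyr::pivot_longer(
      dplyr::select(tibble::as_tibble(tr), "time_weeks", "LDL_blood",
                    "MONO_blood", "lesion_area_pct"),
      cols = -"time_weeks", names_to = "observable", values_to = "model"
    )
    sub <- dplyr::left_join(sub, long, by = c("time_weeks", "observable"))
    sub
  })
  grid <- dplyr::bind_rows(parts)
  grid <- grid[order(grid$scenario_id, grid$observable, grid$time_weeks), ]

  draws <- purrr::pmap(list(grid$model, grid$cv, grid$n), function(m, cv, n) {
    vapply(seq_len(n), function(i) .draw_trunc(m, cv * m), numeric(1))
  })
  out <- tibble::tibble(
    scenario_id = grid$scenario_id,
    observable = grid$observable,
    time_weeks = grid$time_weeks,
    mean = vapply(draws, mean, numeric(1)),
    sd = vapply(draws, stats::sd, numeric(1)),
    n = grid$n,
    holdout = grid$holdout
  )
  attr(out, "truth") <- list(params = params, factors = factors,
                             design = design, seed = seed)
  out
}
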