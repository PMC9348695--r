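# Experimental scenarios and the piecewise-constant LDL-uptake input d_in(t).

.intervention_kinds <- c("HFD", "ABIO", "PA", "IMMOD")
.kind_to_factor <- c(HFD = "d_HFD", ABIO = "d_ABIO", PA = "d_PA",
                     IMMOD = "d_Immod")

#' Define an experimental scenario
#'
#' A scenario is a set of intervention events, each with a kind (`HFD`,
#' `ABIO`, `PA`, `IMMOD`), a start age and an end age in weeks (use `Inf`
#' for "until the end of the observation period"). Time zero is birth; all
#' event times are mouse ages.
#'
#' @param events A data frame with columns `kind`, `start_week`, `end_week`
#'   (`end_week` may be `Inf`), or `NULL` for an intervention-free scenario.
#' @param id Scenario label (integer 1-13 for the built-in designs, or any
#'   user label).
#' @param source Provenance tag, e.g. `"literature"` or `"experiment"`.
#' @return An object of class `athero_scenario`.
#' @seealso [builtin_scenario()], [build_din()]
#' @export
#' @examples
#' # high-fat diet from week 16 to week 56, then nothing
#' sc <- scenario(data.frame(kind = "HFD", start_week = 16, end_week = 56),
#'                id = "hfd_window")
scenario <- function(events = NULL, id = "custom", source = "user") {
  if (is.null(events)) {
    events <- tibble::tibble(kind = character(), start_week = numeric(),
                             end_week = numeric())
  }
  events <- tibble::as_tibble(events)
  need <- c("kind", "start_week", "end_week")
  if (!all(need %in% names(events))) {
    stop("events must have columns kind, start_week, end_week", call. = FALSE)
  }
  events$kind <- as.character(events$kind)
  bad <- setdiff(events$kind, .intervention_kinds)
  if (length(bad) > 0) {
    stop("unknown intervention kind(s): ", paste(unique(bad), collapse = ", "),
         "; use ", paste(.intervention_kinds, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(events$start_week)) || any(events$start_week < 0)) {
    stop("event start_week must be finite and non-negative", call. = FALSE)
  }
  if (any(events$end_week <= events$start_week)) {
    stop("event end_week must exceed start_week", call. = FALSE)
  }
  structure(list(id = id, events = events[need], source = source),
            class = "athero_scenario")
}

#' @export
print.athero_scenario <- function(x, ...) {
  cat("<athero_scenario> id:", format(x$id), " source:", x$source, "\n")
  if (nrow(x$events) == 0) cat("  no interventions (normal diet)\n")
  else print(x$events)
  invisible(x)
}

# Table of the 13 built-in designs: diet/treatment pattern and timing.
# ABIO starts at week 12, HFD at week 16 (weeks 8 in the two literature
# high-fat groups 3 and 5), PA and IL-10 blockage at week 18.
.builtin_events <- list(
  `1` = NULL,
  `2` = NULL,
  `3` = list(c("HFD", 8)),
  `4` = list(c("HFD", 16)),
  `5` = list(c("HFD", 8)),
  `6` = list(c("ABIO", 12), c("HFD", 16)),
  `7` = list(c("HFD", 16), c("PA", 18)),
  `8` = list(c("ABIO", 12), c("HFD", 16), c("PA", 18)),
  `9` = list(c("HFD", 16), c("IMMOD", 18), c("PA", 18)),
  `10` = list(c("HFD", 16), c("IMMOD", 18)),
  `11` = list(c("ABIO", 12)),
  `12` = list(c("PA", 18)),
  `13` = list(c("ABIO", 12), c("PA", 18))
)
.builtin_source <- c(`1` = "literature", `2` = "experiment",
                     `3` = "literature", `4` = "experiment",
                     `5` = "literature", `6` = "experiment",
                     `7` = "experiment", `8` = "experiment",
                     `9` = "experiment", `10` = "experiment",
                     `11` = "experiment", `12` = "experiment",
                     `13` = "experiment")

#' The thirteen built-in experimental scenarios
#'
#' Returns one of the thirteen diet/treatment designs of the study this model
#' was built for: combinations of high-fat diet (from week 16, or week 8 in
#' the two literature high-fat groups), broad-spectrum antibiotics (from week
#' 12), propionate (from week 18) and IL-10 blockage (from week 18). By
#' default every treatment runs until the end of the observation period.
#'
#' The antibiotic course is described in two ways in the source experiments
#' (open-ended vs. a six-week course); the open-ended reading is the default
#' and `abio_weeks` switches to a finite course.
#'
#' @param id Integer scenario id, 1 to 13.
#' @param abio_weeks Duration of antibiotic treatment in weeks (`Inf` for
#'   open-ended, the default; `6` for the six-week-course reading).
#' @return An `athero_scenario` object.
#' @export
#' @examples
#' builtin_scenario(8)  # antibiotics + high-fat diet + propionate
builtin_scenario <- function(id, abio_weeks = Inf) {
  if (length(id) != 1L || !id %in% 1:13) {
    stop("scenario id must be an integer between 1 and 13, got ",
         paste(id, collapse = ","), call. = FALSE)
  }
  key <- as.character(as.integer(id))
  ev <- .builtin_events[[key]]
  if (is.null(ev)) {
    events <- NULL
  } else {
    events <- tibble::tibble(
      kind = vapply(ev, `[[`, character(1), 1L),
      start_week = as.numeric(vapply(ev, `[[`, character(1), 2L)),
      end_week = Inf
    )
    if (is.finite(abio_weeks)) {
      sel <- events$kind == "ABIO"
      events$end_week[sel] <- events$start_week[sel] + abio_weeks
    }
  }
  scenario(events, id = as.integer(id), source = .builtin_source[[key]])
}

#' Piecewise-constant step function
#'
#' Right-continuous step function over age in days: on the interval up to the
#' first breakpoint the function takes `values[1]`, between breakpoints `i`
#' and `i+1` it takes `values[i + 1]`. At a breakpoint the post-change value
#' applies, so an intervention takes effect on its start day.
#'
#' @param breaks_days Strictly increasing numeric vector of breakpoints
#'   (days); may be empty for a constant function.
#' @param values Positive values, one more than `breaks_days`.
#' @return An object of class `athero_step`.
#' @seealso [build_din()], [din_value()]
#' @export
step_function <- function(breaks_days = numeric(), values = 1) {
  breaks_days <- as.numeric(breaks_days)
  values <- as.numeric(values)
  if (length(values) != length(breaks_days) + 1L) {
    stop("need exactly one more value than breakpoints", call. = FALSE)
  }
  if (is.unsorted(breaks_days, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("step-function values must be finite and positive", call. = FALSE)
  }
  structure(list(breaks = breaks_days, values = values), class = "athero_step")
}

#' Evaluate a step function
#'
#' @param fn An [step_function()] object.
#' @param t_days Ages in days (vectorized), `t_days >= 0`.
#' @return Numeric vector of values; right-continuous at breakpoints.
#' @export
din_value <- function(fn, t_days) {
  stopifnot(inherits(fn, "athero_step"))
  if (any(t_days < 0)) stop("t_days must be non-negative", call. = FALSE)
  fn$values[findInterval(t_days, fn$breaks) + 1L]
}

#' @export
print.athero_step <- function(x, ...) {
  cat("<athero_step> ", length(x$breaks), " breakpoint(s)\n", sep = "")
  if (length(x$breaks) == 0) {
    cat("  constant ", format(x$values), "\n", sep = "")
  } else {
    from <- c(0, x$breaks)
    to <- c(x$breaks, Inf)
    for (i in seq_along(x$values)) {
      cat(sprintf("  [%g, %g) d : %g\n", from[i], to[i], x$values[i]))
    }
  }
  invisible(x)
}

#' Build the LDL-uptake input d_in(t) of a scenario
#'
#' Translates a scenario's intervention events into the piecewise-constant
#' LDL-C uptake input `d_in(t)`. On every interval the value is the product
#' of the factors of all active interventions; with none active the value is
#' 1 (normal diet). Event times in weeks are converted to days (1 week = 7
#' days); evaluation is right-continuous, so a factor applies from its start
#' day onward.
#'
#' @param scn An [scenario()] or [builtin_scenario()] object.
#' @param factors An [athero_factors()] object.
#' @return An [step_function()] giving `d_in` over age in days.
#' @export
#' @examples
#' din <- build_din(builtin_scenario(3), athero_factors())
#' din_value(din, c(6, 10) * 7)  # before and after diet start at week 8
build_din <- function(scn, factors) {
  stopifnot(inherits(scn, "athero_scenario"))
  stopifnot(inherits(factors, "athero_factors"))
  ev <- scn$events
  if (nrow(ev) == 0) return(step_function(numeric(), 1))

  # overlapping events of the same kind make the product ambiguous
  for (k in unique(ev$kind)) {
    sub <- ev[ev$kind == k, ]
    if (nrow(sub) > 1) {
      sub <- sub[order(sub$start_week), ]
      if (any(sub$start_week[-1] < sub$end_week[-nrow(sub)])) {
        stop("overlapping '", k, "' events in scenario ", scn$id, call. = FALSE)
      }
    }
  }

  start_d <- ev$start_week * 7
  end_d <- ev$end_week * 7
  breaks <- sort(unique(c(start_d, end_d[is.finite(end_d)])))
  breaks <- breaks[breaks > 0]
  edges <- c(0, breaks)
  vals <- vapply(edges, function(t0) {
    active <- start_d <= t0 & t0 < end_d
    prod(unlist(factors[.kind_to_factor[ev$kind[active]]]), 1)
  }, numeric(1))

  # drop breakpoints that do not change the value (no spurious steps)
  if (length(breaks) > 0) {
    keep <- vals[-1] != vals[-length(vals)]
    breaks <- breaks[keep]
    vals <- c(vals[1], vals[-1][keep])
  }
  step_function(breaks, vals)
}
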