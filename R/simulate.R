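# Numerical integration of the model over a scenario.

#' Simulate the plaque model
#'
#' Integrates the seven-compartment model from birth (`t = 0`) to
#' `t_end_weeks`, starting from the state implied by the parameter set
#' ([initial_state()]). The LDL-uptake input may be a constant, a
#' [step_function()], or be built from a scenario and intervention factors.
#' Integration uses a variable-step multistep solver (`deSolve`'s `lsoda`)
#' at absolute and relative tolerance `1e-10` by default, and is restarted
#' at every breakpoint of `d_in` so the discontinuities are never stepped
#' over. A fixed-step classical Runge-Kutta method is available for
#' cross-validation; steps below 0.1 d give results indistinguishable from
#' the adaptive solver for this system.
#'
#' @param params An [athero_params()] object.
#' @param scenario_ An [scenario()] object (requires `factors`), or `NULL`
#'   when `din` is given directly.
#' @param factors An [athero_factors()] object; required with `scenario_`.
#' @param din A [step_function()] or a single positive constant; overrides
#'   `scenario_`. Default: constant 1 (normal diet).
#' @param t_end_weeks End of simulation, age in weeks.
#' @param output_weeks Ages (weeks) at which to report the solution; defaults
#'   to daily output. Values outside `[0, t_end_weeks]` are an error.
#' @param method `"adaptive"` (lsoda, default) or `"fixed"` (RK4 at `step`).
#' @param rtol,atol Solver tolerances (adaptive method).
#' @param step Step size in days for the fixed-step method.
#' @return A tibble of class `athero_trajectory` with columns `time_weeks`,
#'   `time_days`, the seven states, and the observables `LDL_blood`,
#'   `MONO_blood`, `lesion_area_pct`. The generating parameters and input
#'   are attached as attributes `params` and `din`.
#' @export
#' @examples
#' tr <- simulate_model(athero_params(), t_end_weeks = 10)
#' tail(tr$lesion_area_pct, 1)
simulate_model <- function(params,
                           scenario_ = NULL,
                           factors = NULL,
                           din = NULL,
                           t_end_weeks = 104,
                           output_weeks = NULL,
                           method = c("adaptive", "fixed"),
                           rtol = 1e-10,
                           atol = 1e-10,
                           step = 0.05) {
  stopifnot(inherits(params, "athero_params"))
  method <- match.arg(method)
  if (!is.numeric(t_end_weeks) || t_end_weeks <= 0) {
    stop("t_end_weeks must be positive", call. = FALSE)
  }
  if (is.null(din)) {
    if (is.null(scenario_)) {
      din <- step_function(numeric(), 1)
    } else {
      if (is.null(factors)) {
        stop("factors are required to build d_in from a scenario",
             call. = FALSE)
      }
      din <- build_din(scenario_, factors)
    }
  } else if (is.numeric(din) && length(din) == 1L) {
    din <- step_function(numeric(), din)
  }
  stopifnot(inherits(din, "athero_step"))

  t_end <- t_end_weeks * 7
  if (is.null(output_weeks)) {
    out_days <- seq(0, t_end, by = 1)
    if (out_days[length(out_days)] < t_end) out_days <- c(out_days, t_end)
  } else {
    out_days <- sort(unique(output_weeks)) * 7
    if (any(out_days < 0) || any(out_days > t_end + 1e-9)) {
      stop("output_weeks must lie within [0, t_end_weeks]", call. = FALSE)
    }
  }

  sol <- .integrate_piecewise(params, din, t_end, out_days,
                              method = method, rtol = rtol, atol = atol,
                              step = step)
  obs <- to_observables(sol, params)
  out <- tibble::as_tibble(cbind(
    tibble::tibble(time_weeks = sol$time / 7, time_days = sol$time),
    sol[.state_names], obs
  ))
  attr(out, "params") <- params
  attr(out, "din") <- din
  attr(out, "scenario") <- scenario_
  class(out) <- c("athero_trajectory", class(out))
  out
}

# Integrate over [0, t_end] restarting at every din breakpoint.
# Returns a data.frame with column `time` and the seven states. The
# right-hand side is compiled (src/atherosim.c); divergence (occlusion,
# substantially negative states) is detected on the returned grid.
.integrate_piecewise <- function(params, din, t_end, out_days,
                                 method = "adaptive",
                                 rtol = 1e-10, atol = 1e-10, step = 0.05) {
  clamp <- max(100 * atol, 1e-8)
  base_parms <- c(params$k_MONO, params$d_MONO_B, params$a, params$alpha,
                  params$epsilon, params$c, params$b, params$k_LDL,
                  params$f, params$e, params$d_LDL, params$d_F, params$xi,
                  params$d_L_B, NA_real_, clamp)

  edges <- c(0, din$breaks[din$breaks > 0 & din$breaks < t_end], t_end)
  y <- initial_state(params)
  pieces <- vector("list", length(edges) - 1L)
  for (i in seq_len(length(edges) - 1L)) {
    t0 <- edges[i]; t1 <- edges[i + 1L]
    parms <- base_parms
    parms[15L] <- din_value(din, t0)
    times <- sort(unique(c(t0, out_days[out_days >= t0 & out_days <= t1], t1)))
    if (method == "adaptive") {
      seg <- suppressWarnings(
        deSolve::lsodar(y = y, times = times, func = "atherosim_derivs",
                        dllname = "atherosim", initfunc = "atherosim_init",
                        rootfunc = "atherosim_root", nroot = 1L,
                        parms = parms, rtol = rtol, atol = atol,
                        maxsteps = 10000)
      )
      if (length(attr(seg, "troot")) > 0 || any(seg[, "R"] <= 0.02 + 1e-12)) {
        stop("vessel radius collapsed toward full occlusion at t = ",
             signif(seg[nrow(seg), 1L], 6),
             " d (outside model validity)", call. = FALSE)
      }
    } else {
      grid <- seq(t0, t1, by = step)
      if (grid[length(grid)] < t1) grid <- c(grid, t1)
      grid <- sort(unique(c(grid, times)))
      seg <- deSolve::ode(y = y, times = grid, func = "atherosim_derivs",
                          dllname = "atherosim", initfunc = "atherosim_init",
                          parms = parms, method = "rk4")
    }
    ist <- attr(seg, "istate")
    failed <- (!is.null(ist) && ist[1L] < 0) ||
      abs(seg[nrow(seg), 1L] - t1) > 1e-6 || anyNA(seg)
    if (failed) {
      stop("solver failed in [", signif(t0, 6), ", ", signif(t1, 6),
           "] d; last valid time ", signif(seg[nrow(seg), 1L], 6), " d",
           call. = FALSE)
    }
    if (method == "fixed") {
      seg <- seg[seg[, 1L] %in% times, , drop = FALSE]
    }
    if (any(seg[, "R"] <= 0)) {
      t_bad <- seg[which(seg[, "R"] <= 0)[1L], 1L]
      stop("vessel radius reached zero at t = ", signif(t_bad, 6),
           " d (full occlusion; outside model validity)", call. = FALSE)
    }
    if (any(seg[, -1L] < -clamp)) {
      bad <- which(apply(seg[, -1L, drop = FALSE] < -clamp, 1L, any))[1L]
      stop("state became substantially negative at t = ",
           signif(seg[bad, 1L], 6), " d; the solver is misconfigured",
           call. = FALSE)
    }
    y <- seg[nrow(seg), -1L]
    keep <- seg[, 1L] %in% out_days
    pieces[[i]] <- as.data.frame(seg[keep, , drop = FALSE])
  }
  sol <- do.call(rbind, pieces)
  sol <- sol[!duplicated(sol$time), , drop = FALSE]
  rownames(sol) <- NULL
  # tiny solver-level negatives are numerical noise; report, never return them
  num <- as.matrix(sol[.state_names])
  num[num < 0 & num > -clamp] <- 0
  sol[.state_names] <- num
  sol
}

#' Long-run steady state under a constant LDL-uptake value
#'
#' Simulates from the standard initial state under a constant `d_in` and
#' reports the terminal state together with a convergence diagnostic: the
#' run is flagged converged when the largest instantaneous rate at the
#' horizon falls below `tol` (per day, on the normalized states).
#'
#' @param params An [athero_params()] object.
#' @param din_value Constant LDL-uptake value (e.g. 1 for normal diet, or an
#'   intervention factor).
#' @param horizon_days Simulation horizon in days (default two years).
#' @param tol Convergence tolerance on `max |d state / dt|`.
#' @param ... Passed to [simulate_model()] (e.g. solver tolerances).
#' @return An object of class `athero_steady`: list with elements `state`,
#'   `observables`, `converged`, `residual`, `din_value`, `horizon_days`.
#' @export
#' @examples
#' ss <- steady_state(athero_params(), din_value = 1)
#' ss$observables$lesion_area_pct
steady_state <- function(params, din_value = 1, horizon_days = 730,
                         tol = 1e-8, ...) {
  stopifnot(horizon_days > 0)
  tr <- simulate_model(params, din = din_value,
                       t_end_weeks = horizon_days / 7,
                       output_weeks = c(0, horizon_days / 7), ...)
  fin <- tr[nrow(tr), ]
  state <- unlist(fin[.state_names])
  rate <- athero_derivatives(state, params, din = din_value)
  residual <- max(abs(rate))
  structure(
    list(state = state,
         observables = to_observables(fin, params),
         converged = residual < tol,
         residual = residual,
         din_value = din_value,
         horizon_days = horizon_days,
         tol = tol),
    class = "athero_steady"
  )
}

#' @export
print.athero_steady <- function(x, ...) {
  cat("<athero_steady> d_in =", format(x$din_value),
      " horizon =", x$horizon_days, "d\n")
  cat("  converged:", x$converged,
      " (max |rate| =", format(x$residual, digits = 3), "/d)\n")
  cat("  lesion area:", format(x$observables$lesion_area_pct, digits = 4),
      "%\n")
  invisible(x)
}

#' @export
glance.athero_steady <- function(x, ...) {
  tibble::tibble(
    din_value = x$din_value,
    horizon_days = x$horizon_days,
    converged = x$converged,
    residual = x$residual,
    lesion_area_pct = x$observables$lesion_area_pct,
    LDL_blood = x$observables$LDL_blood,
    MONO_blood = x$observables$MONO_blood
  )
}

#' Predict observables for an arbitrary treatment schedule
#'
#' Runs the model over a (possibly finite-windowed) intervention schedule
#' and reports the observables at the requested readout ages. This is the
#' entry point for in-silico experiments such as stopping all interventions
#' at some age (reversibility) or treating an established lesion with
#' propionate after a high-fat-diet phase.
#'
#' @param params An [athero_params()] object.
#' @param scenario_ An [scenario()] object; events may have finite ends.
#' @param readout_weeks Ages (weeks) at which observables are reported.
#' @param factors An [athero_factors()] object.
#' @param ... Passed to [simulate_model()].
#' @return A tibble with columns `time_weeks`, `LDL_blood`, `MONO_blood`,
#'   `lesion_area_pct`.
#' @export
#' @examples
#' sc <- scenario(data.frame(kind = "HFD", start_week = 16, end_week = 56))
#' predict_experiment(athero_params(), sc, readout_weeks = c(56, 104),
#'                    factors = athero_factors())
predict_experiment <- function(params, scenario_, readout_weeks,
                               factors = athero_factors(), ...) {
  if (length(readout_weeks) == 0 || any(readout_weeks < 0)) {
    stop("readout_weeks must be non-negative ages", call. = FALSE)
  }
  t_end <- max(readout_weeks)
  tr <- simulate_model(params, scenario_ = scenario_, factors = factors,
                       t_end_weeks = t_end,
                       output_weeks = sort(unique(readout_weeks)), ...)
  tibble::tibble(time_weeks = tr$time_weeks, LDL_blood = tr$LDL_blood,
                 MONO_blood = tr$MONO_blood,
                 lesion_area_pct = tr$lesion_area_pct)
}
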