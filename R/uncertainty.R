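# Parametric-bootstrap confidence intervals and +/-1% local sensitivity.

# redraw a record's mean from N(mean, scale), truncated at 0 by redrawing
.draw_trunc <- function(mean, scale) {
  if (scale <= 0) return(mean)
  for (i in 1:100) {
    v <- stats::rnorm(1, mean, scale)
    if (v >= 0) return(v)
  }
  0
}

#' Parametric-bootstrap confidence intervals for fitted parameters
#'
#' For each replicate, every record's group mean is redrawn from a normal
#' law centred on the observed mean; the model is then refitted to the
#' virtual table (starting from the point estimate, with a reduced
#' evolutionary-strategy budget) and the replicate estimates are collected.
#' Percentile intervals at the requested level are computed per parameter
#' across replicates.
#'
#' The spread of the virtual means is `sd / sqrt(n)` (the standard error of
#' the group mean, the default) or the raw group `sd`
#' (`resample = "sd"`). Virtual means of the non-negative observables are
#' truncated at zero by redrawing. Replicate seeds are derived
#' deterministically from `seed`, so the whole computation is reproducible.
#'
#' @param fit An `athero_fit` object (the completed point fit).
#' @param data The measurement table the fit used.
#' @param scenarios Optional named scenario list, as in [fitness()].
#' @param n_reps Number of bootstrap replicates (the full analysis uses
#'   1000; tests and examples use far fewer).
#' @param level Confidence level of the percentile intervals.
#' @param seed Master RNG seed.
#' @param resample `"sem"` (default) or `"sd"`: spread of the virtual means.
#' @param refit_config [fit_config()] for the replicate refits; defaults to
#'   the original config with `max_generations = 300` and
#'   `stagnation = 60`.
#' @param polish_maxit If positive, each replicate refit (and the analysis
#'   as a whole) finishes with a Nelder-Mead refinement of at most this
#'   many iterations ([polish_fit()]); replicate refits must converge to
#'   the same degree as the original fit for percentile intervals to carry
#'   their nominal level.
#' @param max_failure_frac Error out when more than this fraction of
#'   replicate refits fail.
#' @return An object of class `athero_boot`: list with `intervals` (tibble:
#'   parameter, estimate, lower, upper), `replicates` (matrix, one row per
#'   successful replicate), `n_reps`, `n_failed`, `level`, `seed`,
#'   `resample`.
#' @export
bootstrap_ci <- function(fit, data, scenarios = NULL,
                         n_reps = 1000, level = 0.95, seed = 1L,
                         resample = c("sem", "sd"),
                         refit_config = NULL,
                         polish_maxit = 0,
                         max_failure_frac = 0.2) {
  stopifnot(inherits(fit, "athero_fit"))
  resample <- match.arg(resample)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  data <- .validate_measurements(data)
  if (is.null(refit_config)) {
    refit_config <- fit$config
    refit_config$max_generations <- 300
    refit_config$stagnation <- 60
  }

  scale <- .sigma_effective(data$mean, data$sd, data$n,
                            fit$config$sigma_floor_frac,
                            fit$config$sigma_floor_min)
  # records with a literal zero SD are not resampled at all
  scale[is.finite(data$sd) & data$sd == 0] <- 0
  if (resample == "sem") scale <- scale / sqrt(data$n)

  reps <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    set.seed(rep_seed)
    virtual <- data
    virtual$mean <- vapply(seq_len(nrow(data)), function(i) {
      .draw_trunc(data$mean[i], scale[i])
    }, numeric(1))
    res <- tryCatch({
      rf <- fit_evolutionary(virtual, scenarios,
                             init_params = fit$params,
                             init_factors = fit$factors,
                             config = refit_config, seed = rep_seed)
      if (polish_maxit > 0) rf <- polish_fit(rf, virtual, scenarios,
                                             maxit = polish_maxit)
      rf
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else reps[[r]] <- res$estimate
  }
  if (n_failed > max_failure_frac * n_reps) {
    stop(n_failed, " of ", n_reps, " bootstrap refits failed (> ",
         100 * max_failure_frac, "%)", call. = FALSE)
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])

  alpha <- 1 - level
  qs <- apply(mat, 2L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  intervals <- tibble::tibble(
    parameter = colnames(mat),
    estimate = unname(fit$estimate[colnames(mat)]),
    lower = unname(qs[1L, ]),
    upper = unname(qs[2L, ])
  )
  structure(
    list(intervals = intervals, replicates = mat,
         n_reps = n_reps, n_failed = n_failed, level = level,
         seed = seed, resample = resample),
    class = "athero_boot"
  )
}

#' @export
print.athero_boot <- function(x, ...) {
  cat("<athero_boot> ", nrow(x$replicates), " replicate(s) (",
      x$n_failed, " failed), ", 100 * x$level, "% percentile intervals\n",
      sep = "")
  print(x$intervals)
  invisible(x)
}

#' @rdname bootstrap_ci
#' @param x An `athero_boot` object.
#' @param ... Unused.
#' @export
tidy.athero_boot <- function(x, ...) x$intervals

#' Local sensitivity of the fitness to +/- delta parameter changes
#'
#' Perturbs each free parameter by `+delta` and `-delta` (relative, default
#' 1%), leaving all others at their fitted values, and reports the fitness
#' deterioration relative to the optimum. Near a local optimum of a smooth
#' fitness both deteriorations are non-negative up to numerical noise, and
#' their size measures how sharply the data constrain the parameter.
#'
#' @param fit An `athero_fit` object, or a list with `params`/`factors`.
#' @param data The measurement table.
#' @param scenarios Optional named scenario list.
#' @param delta Relative perturbation (default 0.01 = 1%).
#' @param free Parameters to perturb; defaults to the fit's free list.
#' @param rtol,atol Solver tolerances for the evaluations.
#' @return A tibble of class `athero_sensitivity`: `parameter`, `value`,
#'   `fitness_minus`, `fitness_plus`, `deterioration_minus`,
#'   `deterioration_plus` (perturbed minus optimal fitness; `NA` when an
#'   evaluation failed).
#' @export
sensitivity <- function(fit, data, scenarios = NULL, delta = 0.01,
                        free = NULL, rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(fit, "athero_fit"))
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  data <- .validate_measurements(data)
  if (is.null(free)) free <- fit$config$free

  eval_at <- function(theta) {
    asm <- .assemble(theta, fit$params, fit$factors)
    tryCatch(
      fitness(asm$params, asm$factors, data, scenarios,
              sigma_floor_frac = fit$config$sigma_floor_frac,
              sigma_floor_min = fit$config$sigma_floor_min,
              rtol = rtol, atol = atol),
      error = function(e) NA_real_
    )
  }

  theta <- numeric(0)
  for (nm in free) {
    theta[nm] <- if (nm %in% .factor_fields) fit$factors[[nm]]
                 else fit$params[[nm]]
  }
  f0 <- eval_at(theta)
  if (is.na(f0)) stop("fitness evaluation failed at the fitted parameters",
                      call. = FALSE)

  rows <- purrr::map(free, function(nm) {
    up <- theta; up[nm] <- up[nm] * (1 + delta)
    dn <- theta; dn[nm] <- dn[nm] * (1 - delta)
    fp <- eval_at(up); fm <- eval_at(dn)
    tibble::tibble(parameter = nm, value = theta[[nm]],
                   fitness_minus = fm, fitness_plus = fp,
                   deterioration_minus = fm - f0,
                   deterioration_plus = fp - f0)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fitness_optimum") <- f0
  attr(out, "delta") <- delta
  class(out) <- c("athero_sensitivity", class(out))
  out
}
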