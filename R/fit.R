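# (1+3)-evolutionary strategy with self-adaptive mutation step size.

#' Default free-parameter list for fitting
#'
#' The eleven therapy-free kinetic parameters, the initial radius `R0` and
#' the four intervention factors. The normalization-fixed rates (`k_MONO`,
#' `d_MONO_B`, `d_L_B`), the denormalization constants and the initial
#' intimal values are excluded.
#'
#' @return Character vector of parameter names.
#' @export
default_free_parameters <- function() {
  c("a", "alpha", "epsilon", "c", "b", "k_LDL", "f", "e", "d_LDL", "d_F",
    "xi", "R0", .factor_fields)
}

#' Configuration of the evolutionary-strategy fit
#'
#' @param free Names of the parameters to fit; defaults to
#'   [default_free_parameters()]. The normalization-fixed rates may not be
#'   freed.
#' @param bounds Named list of `c(lower, upper)` bounds. Defaults: rates and
#'   factors `[1e-4, 1e4]`, `R0` `[0.9, 1 - 1e-6]`. Offspring are projected
#'   onto the bounds after mutation.
#' @param sigma0 Initial mutation step size (log scale); for the
#'   coordinate scheme every coordinate starts at this value.
#' @param self_adaptation `"coordinate"` (default): every free parameter
#'   carries its own log-normally self-adapted step size, mutated with a
#'   shared global factor plus a per-coordinate factor (Schwefel's rule) —
#'   this handles the strong anisotropy of the chi-square valley;
#'   `"global"`: one shared step size for all coordinates.
#' @param tau Global self-adaptation learning rate; default
#'   `1 / sqrt(2 * d)` with `d` free parameters.
#' @param tau_coord Per-coordinate learning rate of the coordinate scheme;
#'   default `1 / sqrt(2 * sqrt(d))`.
#' @param sigma_min Lower bound on mutated step sizes (never above
#'   `sigma0`), preventing the search from freezing itself.
#' @param contraction Optional multiplicative step-size contraction applied
#'   after a generation without improvement (a 1/5-success-rule-style
#'   safeguard). The default 1 keeps pure success-only self-adaptation;
#'   values just below 1 anneal the step during long stagnations.
#' @param max_generations Generation budget.
#' @param stagnation Stop when the best fitness has not improved by more
#'   than `improvement_tol` over this many generations.
#' @param improvement_tol Minimal improvement counted by the stagnation rule.
#' @param fit_rtol,fit_atol Solver tolerances used for fitness evaluations
#'   during the search (relaxed for speed); the final reported fitness is
#'   recomputed at `final_rtol`/`final_atol`.
#' @param final_rtol,final_atol Tolerances of the final fitness evaluation.
#' @param sigma_floor_frac,sigma_floor_min Sigma floor rule, see [fitness()].
#' @return A list of class `athero_fit_config`.
#' @export
fit_config <- function(free = default_free_parameters(),
                       bounds = NULL,
                       sigma0 = 0.1,
                       self_adaptation = c("coordinate", "global"),
                       tau = NULL,
                       tau_coord = NULL,
                       sigma_min = 1e-6,
                       contraction = 1,
                       max_generations = 2000,
                       stagnation = 200,
                       improvement_tol = 1e-6,
                       fit_rtol = 1e-8, fit_atol = 1e-8,
                       final_rtol = 1e-10, final_atol = 1e-10,
                       sigma_floor_frac = 0.1, sigma_floor_min = 1e-6) {
  fixed <- intersect(free, .fixed_fields)
  if (length(fixed) > 0) {
    stop("parameters fixed by normalization cannot be fitted: ",
         paste(fixed, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(free, c(.param_fields, .factor_fields))
  if (length(unknown) > 0) {
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(free) == 0) stop("need at least one free parameter", call. = FALSE)
  self_adaptation <- match.arg(self_adaptation)
  if (is.null(tau)) tau <- 1 / sqrt(2 * length(free))
  if (is.null(tau_coord)) tau_coord <- 1 / sqrt(2 * sqrt(length(free)))
  b <- list()
  for (nm in free) {
    b[[nm]] <- if (!is.null(bounds[[nm]])) {
      as.numeric(bounds[[nm]])
    } else if (nm == "R0") {
      c(0.9, 1 - 1e-6)
    } else {
      c(1e-4, 1e4)
    }
    if (length(b[[nm]]) != 2L || b[[nm]][1] <= 0 || b[[nm]][1] >= b[[nm]][2]) {
      stop("bounds for '", nm, "' must be positive and increasing",
           call. = FALSE)
    }
  }
  if (contraction <= 0 || contraction > 1) {
    stop("contraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(free = free, bounds = b, sigma0 = sigma0,
                 self_adaptation = self_adaptation, tau = tau,
                 tau_coord = tau_coord, sigma_min = sigma_min,
                 contraction = contraction,
                 max_generations = max_generations, stagnation = stagnation,
                 improvement_tol = improvement_tol,
                 fit_rtol = fit_rtol, fit_atol = fit_atol,
                 final_rtol = final_rtol, final_atol = final_atol,
                 sigma_floor_frac = sigma_floor_frac,
                 sigma_floor_min = sigma_floor_min),
            class = "athero_fit_config")
}

# split a named free-parameter vector back into params/factors objects
.assemble <- function(theta, params, factors) {
  for (nm in names(theta)) {
    if (nm %in% .factor_fields) factors[[nm]] <- theta[[nm]]
    else params[[nm]] <- theta[[nm]]
  }
  list(params = params, factors = factors)
}

#' Fit the model by a (1+3)-evolutionary strategy
#'
#' Minimizes the chi-square [fitness()] over the free parameters. Each
#' generation, three offspring are produced from the incumbent by
#' multiplicative log-normal perturbation: the step sizes are self-adapted
#' first (per coordinate by default,
#' `sigma_i' = sigma_i * exp(tau N_global + tau_c N_i)`), then the
#' parameters are perturbed, `theta_i' = theta_i * exp(sigma_i' * N(0,1))`,
#' and projected onto the bounds. The incumbent is replaced only by a
#' strictly better offspring (elitist selection, so the fitness trace is
#' non-increasing), and the winner's step sizes are inherited.
#' Multiplicative mutation keeps all rates positive and searches on the
#' natural log scale of rate constants; per-coordinate step sizes let the
#' search align with the strongly anisotropic chi-square valley of this
#' model.
#'
#' Fitness evaluations during the search run at relaxed solver tolerances;
#' the returned fitness is recomputed at the strict tolerances. Offspring
#' whose evaluation fails (solver breakdown) are treated as infinitely bad.
#'
#' @inheritParams fitness
#' @param init_params Starting [athero_params()]; defaults to
#'   [athero_params()].
#' @param init_factors Starting [athero_factors()]; defaults to
#'   [athero_factors()].
#' @param config An [fit_config()] object.
#' @param seed Integer RNG seed; the run is bit-reproducible given the seed.
#' @param verbose Print progress every 100 generations.
#' @return An object of class `athero_fit`: list with `params`, `factors`,
#'   `fitness` (at strict tolerances), `trace` (tibble: generation, fitness,
#'   step_size — the median step size for the coordinate scheme), `seed`,
#'   `config`, `n_evaluations`, `converged_by`.
#' @export
fit_evolutionary <- function(data, scenarios = NULL,
                             init_params = athero_params(),
                             init_factors = athero_factors(),
                             config = fit_config(),
                             seed = 1L,
                             verbose = FALSE) {
  stopifnot(inherits(config, "athero_fit_config"))
  data <- .validate_measurements(data)
  set.seed(seed)

  free <- config$free
  lower <- vapply(config$bounds, `[[`, numeric(1), 1L)[free]
  upper <- vapply(config$bounds, `[[`, numeric(1), 2L)[free]

  theta0 <- numeric(length(free)); names(theta0) <- free
  for (nm in free) {
    theta0[[nm]] <- if (nm %in% .factor_fields) init_factors[[nm]]
                    else init_params[[nm]]
  }
  theta0 <- pmin(pmax(theta0, lower), upper)

  n_eval <- 0L
  eval_fitness <- function(theta) {
    n_eval <<- n_eval + 1L
    asm <- .assemble(theta, init_params, init_factors)
    tryCatch(
      fitness(asm$params, asm$factors, data, scenarios,
              sigma_floor_frac = config$sigma_floor_frac,
              sigma_floor_min = config$sigma_floor_min,
              rtol = config$fit_rtol, atol = config$fit_atol),
      error = function(e) Inf
    )
  }

  fit0 <- eval_fitness(theta0)
  if (!is.finite(fit0)) {
    stop("fitness evaluation failed at the initial parameters; ",
         "choose different starting values or bounds", call. = FALSE)
  }

  d <- length(free)
  coord <- config$self_adaptation == "coordinate"
  sig_floor <- min(config$sigma_min, config$sigma0)
  theta <- theta0; best <- fit0
  sigma <- if (coord) rep(config$sigma0, d) else config$sigma0
  trace <- vector("list", config$max_generations + 1L)
  trace[[1L]] <- c(0, best, stats::median(sigma))
  last_improve <- 0L
  converged_by <- "max_generations"

  for (gen in seq_len(config$max_generations)) {
    cand_theta <- theta; cand_fit <- best; cand_sigma <- sigma
    for (k in 1:3) {
      if (coord) {
        sig_k <- sigma * exp(config$tau * stats::rnorm(1) +
                               config$tau_coord * stats::rnorm(d))
      } else {
        sig_k <- sigma * exp(config$tau * stats::rnorm(1))
      }
      sig_k <- pmax(sig_k, sig_floor)
      child <- theta * exp(sig_k * stats::rnorm(d))
      child <- pmin(pmax(child, lower), upper)
      fit_k <- eval_fitness(child)
      if (fit_k < cand_fit) {
        cand_theta <- child; cand_fit <- fit_k; cand_sigma <- sig_k
      }
    }
    if (cand_fit < best - config$improvement_tol) last_improve <- gen
    if (cand_fit < best) {
      theta <- cand_theta; best <- cand_fit; sigma <- cand_sigma
    } else {
      # optional step contraction on failure (1/5-success-rule flavour)
      sigma <- pmax(sigma * config$contraction, sig_floor)
    }
    trace[[gen + 1L]] <- c(gen, best, stats::median(sigma))
    if (verbose && gen %% 100 == 0) {
      message(sprintf("generation %d: fitness %.6g (sigma %.3g)",
                      gen, best, sigma))
    }
    if (gen - last_improve >= config$stagnation) {
      converged_by <- "stagnation"
      trace <- trace[seq_len(gen + 1L)]
      break
    }
  }

  trace <- do.call(rbind, trace)
  trace <- tibble::tibble(generation = trace[, 1L], fitness = trace[, 2L],
                          step_size = trace[, 3L])
  asm <- .assemble(theta, init_params, init_factors)
  final_fit <- tryCatch(
    fitness(asm$params, asm$factors, data, scenarios,
            sigma_floor_frac = config$sigma_floor_frac,
            sigma_floor_min = config$sigma_floor_min,
            rtol = config$final_rtol, atol = config$final_atol),
    error = function(e) best
  )

  structure(
    list(params = asm$params, factors = asm$factors,
         fitness = final_fit, fitness_search = best,
         estimate = theta, trace = trace, seed = seed, config = config,
         n_evaluations = n_eval, converged_by = converged_by),
    class = "athero_fit"
  )
}

#' Local simplex refinement of an evolutionary-strategy fit
#'
#' Runs a Nelder-Mead simplex search on the log scale of the free
#' parameters, starting from a fit's estimate. The evolutionary strategy is
#' good at moving through the rugged large-scale landscape but can stall in
#' the narrow, strongly anisotropic valley around an optimum; the simplex,
#' which adapts its shape to the valley, reliably finishes the descent.
#' Bounds are enforced by penalty. The returned object is a refined
#' `athero_fit` whose final fitness is recomputed at the strict solver
#' tolerances of the fit's configuration.
#'
#' @param fit An `athero_fit` from [fit_evolutionary()].
#' @param data The measurement table the fit used.
#' @param scenarios Optional named scenario list, as in [fitness()].
#' @param maxit Maximal number of simplex iterations.
#' @param reltol Relative convergence tolerance of the simplex.
#' @return The refined `athero_fit` (with `converged_by = "polish"`).
#' @export
polish_fit <- function(fit, data, scenarios = NULL, maxit = 4000,
                       reltol = 1e-10) {
  stopifnot(inherits(fit, "athero_fit"))
  data <- .validate_measurements(data)
  config <- fit$config
  free <- config$free
  lower <- vapply(config$bounds, `[[`, numeric(1), 1L)[free]
  upper <- vapply(config$bounds, `[[`, numeric(1), 2L)[free]

  n_eval <- 0L
  objective <- function(log_theta) {
    n_eval <<- n_eval + 1L
    theta <- exp(log_theta)
    names(theta) <- free
    if (any(theta < lower) || any(theta > upper)) return(1e10)
    asm <- .assemble(theta, fit$params, fit$factors)
    tryCatch(
      fitness(asm$params, asm$factors, data, scenarios,
              sigma_floor_frac = config$sigma_floor_frac,
              sigma_floor_min = config$sigma_floor_min,
              rtol = config$fit_rtol, atol = config$fit_atol),
      error = function(e) 1e10
    )
  }

  opt <- stats::optim(log(fit$estimate), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  theta <- exp(opt$par)
  names(theta) <- free
  asm <- .assemble(theta, fit$params, fit$factors)
  final_fit <- tryCatch(
    fitness(asm$params, asm$factors, data, scenarios,
            sigma_floor_frac = config$sigma_floor_frac,
            sigma_floor_min = config$sigma_floor_min,
            rtol = config$final_rtol, atol = config$final_atol),
    error = function(e) opt$value
  )
  out <- fit
  out$params <- asm$params
  out$factors <- asm$factors
  out$estimate <- theta
  out$fitness <- final_fit
  out$fitness_search <- opt$value
  out$n_evaluations <- fit$n_evaluations + n_eval
  out$converged_by <- "polish"
  out
}

#' @export
print.athero_fit <- function(x, ...) {
  cat("<athero_fit> ", length(x$config$free), " free parameter(s), ",
      max(x$trace$generation), " generation(s)\n", sep = "")
  cat("  fitness:", format(x$fitness, digits = 6),
      " stopped by:", x$converged_by, "\n")
  print(x$estimate)
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x An `athero_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `parameter`,
#'   `estimate`.
#' @export
tidy.athero_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$estimate),
                 estimate = unname(x$estimate))
}

#' One-row summary of a fit
#'
#' @param x An `athero_fit` object.
#' @param ... Unused.
#' @return A tibble with `fitness`, `generations`, `n_evaluations`,
#'   `converged_by`, `seed`.
#' @export
glance.athero_fit <- function(x, ...) {
  tibble::tibble(fitness = x$fitness,
                 generations = max(x$trace$generation),
                 n_evaluations = x$n_evaluations,
                 converged_by = x$converged_by,
                 seed = x$seed)
}
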