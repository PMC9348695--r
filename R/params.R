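# Parameter containers and parameter-file I/O.

# kinetic / structural parameters of the plaque model
.param_fields <- c(
  "k_MONO", "d_MONO_B", "a", "alpha", "epsilon", "c", "b", "k_LDL", "f",
  "e", "d_LDL", "d_F", "xi", "d_L_B", "R0", "MONO_B_nor", "L_B_nor",
  "init_MONO", "init_IM", "init_L", "init_F"
)

# multiplicative LDL-uptake factors of the interventions
.factor_fields <- c("d_HFD", "d_ABIO", "d_Immod", "d_PA")

# parameters excluded from fitting (normalization / identifiability)
.fixed_fields <- c("k_MONO", "d_MONO_B", "d_L_B")

#' Model parameters for the murine atherosclerosis model
#'
#' Construct the full kinetic parameter set of the seven-compartment plaque
#' model. All states are normalized (dimensionless) and time is measured in
#' days, so every rate is per day. The defaults are the package's bundled
#' reference calibration (see `reference_params()`), obtained by fitting the
#' model to published group-level summary values; they are illustrative, not
#' a measured ground truth.
#'
#' The rates `k_MONO` (blood-monocyte production), `d_MONO_B` (blood-monocyte
#' turnover) and `d_L_B` (blood LDL-C removal) are fixed at 1 by the model's
#' normalization and are excluded from fitting by default.
#'
#' A small initial lesion `R0 < 1` together with a non-zero seed in at least
#' one intimal compartment (`init_MONO`, `init_IM`, `init_L`, `init_F`) is
#' required to start plaque growth: the lesion-free state is an equilibrium
#' and the set `MONO = L = 0` is invariant under the dynamics.
#'
#' @param k_MONO Blood-monocyte production rate (fixed at 1 by normalization).
#' @param d_MONO_B Blood-monocyte degradation rate (fixed at 1).
#' @param a Monocyte influx scale into the intima.
#' @param alpha Radius-sensitivity constant of the monocyte influx term
#'   `R^3 / (R^3 + alpha)`.
#' @param epsilon Monocyte efflux rate out of the intima.
#' @param c Monocyte-to-macrophage differentiation rate.
#' @param b Macrophage + lipid to foam-cell conversion rate.
#' @param k_LDL LDL-C influx/oxidation scale into the plaque.
#' @param f Michaelis constant of the monocyte saturation term
#'   `MONO / (f + MONO)`.
#' @param e Consumption rate of plaque LDL-C by macrophages.
#' @param d_LDL Efflux rate of oxidized LDL-C from the plaque.
#' @param d_F Foam-cell efflux rate from the plaque.
#' @param xi Radius-coupling constant linking foam-cell dynamics to radius
#'   reduction.
#' @param d_L_B Blood LDL-C removal rate (fixed at 1).
#' @param R0 Initial normalized vessel radius, `0 < R0 <= 1`; values below 1
#'   encode the small initial lesion needed to start plaque formation.
#' @param MONO_B_nor Denormalization constant for blood monocytes
#'   (observation units, e.g. cells/uL).
#' @param L_B_nor Denormalization constant for blood LDL-C (observation
#'   units, e.g. mg/dL).
#' @param init_MONO,init_IM,init_L,init_F Initial values of the intimal
#'   compartments at `t = 0` (birth).
#'
#' @return An object of class `athero_params`: a validated named list.
#' @seealso [athero_factors()], [read_params()], [reference_params()]
#' @export
#' @examples
#' p <- athero_params()
#' p$R0
athero_params <- function(k_MONO = 1,
                          d_MONO_B = 1,
                          a = 0.590522049,
                          alpha = 0.155300064,
                          epsilon = 0.3667997069,
                          c = 0.1008016358,
                          b = 0.1710619631,
                          k_LDL = 0.1812586163,
                          f = 0.339379935,
                          e = 0.05075306111,
                          d_LDL = 0.1695164082,
                          d_F = 0.007843951994,
                          xi = 1.219821341,
                          d_L_B = 1,
                          R0 = 0.9996,
                          MONO_B_nor = 430,
                          L_B_nor = 430,
                          init_MONO = 1e-4,
                          init_IM = 1e-4,
                          init_L = 1e-4,
                          init_F = 1e-4) {
  p <- list(
    k_MONO = k_MONO, d_MONO_B = d_MONO_B, a = a, alpha = alpha,
    epsilon = epsilon, c = c, b = b, k_LDL = k_LDL, f = f, e = e,
    d_LDL = d_LDL, d_F = d_F, xi = xi, d_L_B = d_L_B, R0 = R0,
    MONO_B_nor = MONO_B_nor, L_B_nor = L_B_nor,
    init_MONO = init_MONO, init_IM = init_IM, init_L = init_L,
    init_F = init_F
  )
  validate_params(p)
  structure(p, class = "athero_params")
}

validate_params <- function(p) {
  for (nm in .param_fields) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  rates <- setdiff(.param_fields, c("R0", "MONO_B_nor", "L_B_nor"))
  neg <- rates[vapply(rates, function(nm) p[[nm]] < 0, logical(1))]
  if (length(neg) > 0) {
    stop("parameters must be non-negative: ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  if (p$R0 <= 0 || p$R0 > 1) {
    stop("R0 must satisfy 0 < R0 <= 1, got ", p$R0, call. = FALSE)
  }
  if (p$MONO_B_nor <= 0 || p$L_B_nor <= 0) {
    stop("normalization constants MONO_B_nor and L_B_nor must be positive",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.athero_params <- function(x, ...) {
  cat("<athero_params>\n")
  vals <- unlist(x[.param_fields])
  print(vals)
  invisible(x)
}

#' Intervention factors on LDL-C uptake
#'
#' The four interventions act on the model exclusively through multiplicative
#' factors on the LDL-C uptake input `d_in(t)`: high-fat diet (`d_HFD`),
#' broad-spectrum antibiotics (`d_ABIO`), IL-10-receptor blockage
#' (`d_Immod`) and the lipid-lowering short-chain fatty acid propionate
#' (`d_PA`). Factors of concurrently applied interventions multiply.
#'
#' Factors above 1 raise LDL-C uptake, factors below 1 lower it. The expected
#' pattern for this disease system is `d_HFD, d_ABIO, d_Immod > 1 > d_PA`,
#' but this is a property of fitted values, not an enforced constraint.
#' Defaults are the bundled reference calibration.
#'
#' @param d_HFD Uptake multiplier of high-fat diet.
#' @param d_ABIO Uptake multiplier of antibiotic treatment.
#' @param d_Immod Uptake multiplier of IL-10 blockage.
#' @param d_PA Uptake multiplier of propionate treatment.
#' @return An object of class `athero_factors`.
#' @seealso [athero_params()], [build_din()]
#' @export
athero_factors <- function(d_HFD = 1.549120344,
                           d_ABIO = 2.605936884,
                           d_Immod = 2.735203843,
                           d_PA = 0.7838942015) {
  fc <- list(d_HFD = d_HFD, d_ABIO = d_ABIO, d_Immod = d_Immod, d_PA = d_PA)
  for (nm in .factor_fields) {
    v <- fc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("intervention factor '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(fc, class = "athero_factors")
}

#' @export
print.athero_factors <- function(x, ...) {
  cat("<athero_factors>\n")
  print(unlist(x[.factor_fields]))
  invisible(x)
}

#' Read a flat parameter file
#'
#' Reads a flat key/value YAML file holding model parameters and, optionally,
#' intervention factors. Unknown keys are rejected. Missing keys fall back to
#' the model's structural defaults where one exists (the normalization-fixed
#' rates `k_MONO`, `d_MONO_B`, `d_L_B` default to 1; initial intimal values
#' default to 0); any other missing kinetic parameter is an error. Factor
#' keys (`d_HFD`, `d_ABIO`, `d_Immod`, `d_PA`) must either all be present or
#' all be absent.
#'
#' @param path Path to a YAML file of `name: value` pairs.
#' @return A list with components `params` ([athero_params()]) and `factors`
#'   ([athero_factors()] or `NULL` when the file carries no factors).
#' @seealso [write_params()], [reference_params()]
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) {
    stop("parameter file must be a flat mapping of name: value pairs",
         call. = FALSE)
  }
  known <- c(.param_fields, .factor_fields)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown parameter keys in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  fnames <- intersect(names(raw), .factor_fields)
  if (length(fnames) > 0 && length(fnames) < length(.factor_fields)) {
    stop("parameter file carries only some intervention factors (",
         paste(fnames, collapse = ", "),
         "); provide all four or none", call. = FALSE)
  }

  defaults <- list(k_MONO = 1, d_MONO_B = 1, d_L_B = 1,
                   init_MONO = 0, init_IM = 0, init_L = 0, init_F = 0)
  pnames <- intersect(names(raw), .param_fields)
  p <- raw[pnames]
  missing <- setdiff(.param_fields, names(p))
  for (nm in intersect(missing, names(defaults))) p[[nm]] <- defaults[[nm]]
  still <- setdiff(.param_fields, names(p))
  if (length(still) > 0) {
    stop("parameter file ", path, " is missing required keys: ",
         paste(still, collapse = ", "), call. = FALSE)
  }
  params <- do.call(athero_params, p)

  factors <- NULL
  if (length(fnames) > 0) {
    factors <- do.call(athero_factors, raw[.factor_fields])
  }
  list(params = params, factors = factors)
}

#' Write parameters (and factors) to a flat YAML file
#'
#' @param params An [athero_params()] object.
#' @param path Output file path.
#' @param factors Optional [athero_factors()] object written into the same
#'   file.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path, factors = NULL) {
  stopifnot(inherits(params, "athero_params"))
  out <- lapply(params[.param_fields], as.numeric)
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "athero_factors"))
    out <- c(out, lapply(factors[.factor_fields], as.numeric))
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Bundled reference parameter set
#'
#' Loads the package's bundled reference calibration
#' (`extdata/parameters_synthetic_reference.yaml`). This set was produced by
#' fitting the model, with the package's own evolutionary-strategy optimizer,
#' to published group-level summary values of lesion area in APOE-deficient
#' mice under the thirteen diet/treatment scenarios; it is a synthetic
#' stand-in for a measured parameter table and is intended for simulation
#' examples and as a realistic scale for synthetic-data studies.
#'
#' @return A list with components `params` and `factors`, as [read_params()].
#' @export
reference_params <- function() {
  path <- system.file("extdata", "parameters_synthetic_reference.yaml",
                      package = "atherosim", mustWork = TRUE)
  read_params(path)
}
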