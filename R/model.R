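# Right-hand side of the plaque model and observable transforms.

.state_names <- c("MONO_B", "MONO", "IM", "L", "F", "L_B", "R")

#' Instantaneous rates of the plaque model
#'
#' Evaluates the right-hand side of the seven-compartment model at one state.
#' The compartments are blood monocytes (`MONO_B`), intimal monocytes
#' (`MONO`), inflammatory macrophages (`IM`), oxidized LDL-C in plaque (`L`),
#' foam cells (`F`), blood LDL-C (`L_B`) and the normalized vessel radius
#' (`R`). The equations are
#' \deqn{MONO_B' = k_{MONO} - d_{MONO_B} MONO_B}
#' \deqn{MONO' = a \frac{R^3}{R^3+\alpha}\frac{L}{1+L} MONO_B - (\epsilon + c) MONO}
#' \deqn{IM' = c\,MONO - b\,IM\,L}
#' \deqn{L_B' = d_{in} - d_{L_B} L_B}
#' \deqn{L' = k_{LDL} L_B \frac{MONO}{f + MONO} - e\,L\,IM - d_{LDL} L}
#' \deqn{F' = b\,IM\,L - d_F F}
#' \deqn{R' = \frac{\xi}{2}(R - 1/R)(b\,IM\,L - d_F F)}
#' Only foam-cell dynamics move the radius; at `R = 1` the factor
#' `(R - 1/R)` vanishes, so the lesion-free vessel never changes.
#'
#' @param state Named numeric vector with elements
#'   `MONO_B, MONO, IM, L, F, L_B, R`; all non-negative, `R > 0`.
#' @param params An [athero_params()] object.
#' @param din Current value of the LDL-C uptake input `d_in(t)` (positive).
#' @return Named numeric vector of rates (per day), same names as `state`.
#' @export
#' @examples
#' p <- athero_params()
#' s <- c(MONO_B = 1, MONO = 0, IM = 0, L = 0, F = 0, L_B = 1, R = 1)
#' athero_derivatives(s, p)  # the lesion-free equilibrium: all rates 0
athero_derivatives <- function(state, params, din = 1) {
  stopifnot(inherits(params, "athero_params"))
  if (!all(.state_names %in% names(state))) {
    stop("state must carry components ", paste(.state_names, collapse = ", "),
         call. = FALSE)
  }
  state <- state[.state_names]
  if (any(!is.finite(state))) stop("state components must be finite", call. = FALSE)
  if (any(state < 0)) {
    stop("state components must be non-negative; got negative ",
         paste(names(state)[state < 0], collapse = ", "), call. = FALSE)
  }
  if (state[["R"]] <= 0) {
    stop("R must be positive (the model is undefined at full occlusion)",
         call. = FALSE)
  }
  if (!is.numeric(din) || length(din) != 1L || din <= 0) {
    stop("din must be a single positive number", call. = FALSE)
  }
  rate <- .athero_rhs(state, params, din)
  names(rate) <- .state_names
  rate
}

# unchecked RHS used inside the integrator; `state` ordered as .state_names
.athero_rhs <- function(state, p, din) {
  MONO_B <- state[[1L]]; MONO <- state[[2L]]; IM <- state[[3L]]
  L <- state[[4L]]; F <- state[[5L]]; L_B <- state[[6L]]; R <- state[[7L]]
  R3 <- R^3
  dF <- p$b * IM * L - p$d_F * F
  # rates ordered as .state_names: MONO_B, MONO, IM, L, F, L_B, R
  c(
    p$k_MONO - p$d_MONO_B * MONO_B,
    p$a * R3 / (R3 + p$alpha) * L / (1 + L) * MONO_B - (p$epsilon + p$c) * MONO,
    p$c * MONO - p$b * IM * L,
    p$k_LDL * L_B * MONO / (p$f + MONO) - p$e * L * IM - p$d_LDL * L,
    dF,
    din - p$d_L_B * L_B,
    p$xi / 2 * (R - 1 / R) * dF
  )
}

#' Lesion area as a fraction of the vessel cross-section
#'
#' The plaque is modelled as a ring deposit on the vessel wall, so the lesion
#' area of a vessel with normalized radius `R` is `pi * (1 - R^2)`. Reported
#' relative to the lesion-free cross-section `pi * 1^2`, the factor `pi`
#' cancels and the lesion fraction is `1 - R^2`.
#'
#' @param R Normalized vessel radius (vectorized), `0 < R <= 1`.
#' @return Lesion area fraction in `[0, 1)`; 0 for a lesion-free vessel.
#' @export
#' @examples
#' lesion_area_fraction(1)       # 0
#' lesion_area_fraction(0.9996)  # the canonical small initial lesion
lesion_area_fraction <- function(R) {
  if (!is.numeric(R) || any(!is.finite(R))) {
    stop("R must be finite numeric", call. = FALSE)
  }
  if (any(R <= 0) || any(R > 1)) {
    stop("R must satisfy 0 < R <= 1", call. = FALSE)
  }
  1 - R^2
}

#' Map model states to observable quantities
#'
#' Converts normalized model states into the three measured observables:
#' blood LDL-C (`L_B * L_B_nor`, data units), blood monocytes
#' (`MONO_B * MONO_B_nor`, data units) and lesion area as a percentage of
#' the vessel cross-section (`100 * (1 - R^2)`).
#'
#' @param state A named numeric state vector, or a data frame with columns
#'   `MONO_B`, `L_B`, `R` (e.g. a trajectory).
#' @param params An [athero_params()] object supplying the denormalization
#'   constants.
#' @return A tibble with columns `LDL_blood`, `MONO_blood`,
#'   `lesion_area_pct`.
#' @export
to_observables <- function(state, params) {
  stopifnot(inherits(params, "athero_params"))
  if (is.data.frame(state)) {
    MONO_B <- state$MONO_B; L_B <- state$L_B; R <- state$R
  } else {
    MONO_B <- state[["MONO_B"]]; L_B <- state[["L_B"]]; R <- state[["R"]]
  }
  tibble::tibble(
    LDL_blood = L_B * params$L_B_nor,
    MONO_blood = MONO_B * params$MONO_B_nor,
    lesion_area_pct = 100 * lesion_area_fraction(R)
  )
}

#' Initial model state implied by a parameter set
#'
#' Assembles the state at `t = 0` (birth): blood compartments at their
#' normalized baseline (`MONO_B = 1`, `L_B = 1`), the radius at `R0`, and
#' the intimal compartments at the `init_*` values of the parameter set.
#'
#' @param params An [athero_params()] object.
#' @return Named numeric state vector.
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "athero_params"))
  c(MONO_B = 1, MONO = params$init_MONO, IM = params$init_IM,
    L = params$init_L, F = params$init_F, L_B = 1, R = params$R0)
}

# observable kinds used in measurement tables
.observable_kinds <- c("LDL_blood", "MONO_blood", "lesion_area_pct")
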