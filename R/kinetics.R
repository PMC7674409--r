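# Trophic roles. Complete reducers (competition scenario) and producers grow
# on nitrate; consumers grow on nitrite supplied by producers.
STRAIN_ROLES <- c("complete_reducer", "producer", "consumer")

#' Kinetic parameters (Monod growth, yields, nitrite toxicity)
#'
#' Defaults are the denitrification parameter set used throughout: maximum
#' growth rate 5.4e-6 1/s, half-saturation 0.04 mM for both nitrate and
#' nitrite, nitrite inhibition constant 0.02 mM, maximum yield 0.06 and
#' minimum yield 0.006 kgDW/mol. `toxicity_on` activates the low-pH regime
#' (strong mutualism) where nitrite depresses the biomass yield of both
#' strains; it never affects the growth rate.
#'
#' @param mu_max Maximum specific growth rate, 1/s.
#' @param k_no3,k_no2 Monod half-saturation constants, mM.
#' @param k_inh Nitrite inhibition constant for the yield, mM.
#' @param y_max,y_min Maximum/minimum biomass yield, kgDW/mol.
#' @param toxicity_on Logical; nitrite toxicity acting on the yield (pH 6.5).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(mu_max = 5.4e-6, k_no3 = 0.04, k_no2 = 0.04,
                           k_inh = 0.02, y_max = 0.06, y_min = 0.006,
                           toxicity_on = FALSE) {
  stopifnot(mu_max > 0, k_no3 > 0, k_no2 > 0, k_inh > 0)
  if (!(y_min > 0 && y_min <= y_max))
    stop("need 0 < y_min <= y_max", call. = FALSE)
  structure(list(mu_max = mu_max, k_no3 = k_no3, k_no2 = k_no2,
                 k_inh = k_inh, y_max = y_max, y_min = y_min,
                 toxicity_on = isTRUE(toxicity_on)),
            class = "kinetic_params")
}

#' Local specific growth rate
#'
#' Monod kinetics on the role's substrate: complete reducers and producers
#' saturate on nitrate, consumers on nitrite. Vectorized over nodes.
#'
#' @param role Character vector of roles ("complete_reducer", "producer",
#'   "consumer"), recycled against the concentrations.
#' @param c_no3,c_no2 Concentrations at the node, mM (>= 0).
#' @param params A `kinetic_params`.
#' @return Growth rate(s) in 1/s, within `[0, mu_max]`.
#' @export
growth_rate <- function(role, c_no3, c_no2, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(c_no3 < 0) || any(c_no2 < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  bad <- setdiff(unique(role), STRAIN_ROLES)
  if (length(bad)) stop("unknown role: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n <- max(length(role), length(c_no3), length(c_no2))
  role <- rep_len(role, n)
  c_no3 <- rep_len(c_no3, n); c_no2 <- rep_len(c_no2, n)
  s <- ifelse(role == "consumer", c_no2, c_no3)
  k <- ifelse(role == "consumer", params$k_no2, params$k_no3)
  params$mu_max * s / (s + k)
}

#' Biomass yield coefficient under optional nitrite toxicity
#'
#' With toxicity off (pH 7.5) the yield is `y_max` regardless of nitrite.
#' With toxicity on (pH 6.5) the yield interpolates from `y_max` at zero
#' nitrite down toward `y_min`:
#' `(y_max - y_min) * k_inh / (k_inh + c_no2) + y_min`. Applied to both
#' strains in the strong-mutualism scenario.
#'
#' @param c_no2 Nitrite concentration, mM (>= 0). Vectorized.
#' @param params A `kinetic_params`.
#' @return Yield(s), kgDW/mol, within `[y_min, y_max]`.
#' @export
yield_coefficient <- function(c_no2, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(c_no2 < 0)) stop("c_no2 must be non-negative", call. = FALSE)
  if (!params$toxicity_on) return(rep_len(params$y_max, length(c_no2)))
  (params$y_max - params$y_min) * params$k_inh / (params$k_inh + c_no2) +
    params$y_min
}

#' Explicit biomass update
#'
#' `m_next = m * (1 + mu * dt)` — the explicit Euler form of exponential
#' growth over one macro step.
#'
#' @param mass Biomass, kg (> 0). Vectorized.
#' @param mu Specific growth rate, 1/s (>= 0).
#' @param dt Time step, s.
#' @return Updated biomass, kg.
#' @export
biomass_step <- function(mass, mu, dt) {
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  if (any(mu < 0) || dt <= 0) stop("need mu >= 0 and dt > 0", call. = FALSE)
  mass * (1 + mu * dt)
}

#' Nutrient consumption over a step
#'
#' Moles of substrate consumed by a growing super-agent over `dt`:
#' `mu * mass * dt / yield` (start-of-step mass, explicit Euler, consistent
#' with [biomass_step()]). For the producer role an equal molar amount of
#' nitrite is released (1:1 stoichiometry of the nitrate-to-nitrite step).
#'
#' @param mass Biomass, kg. Vectorized.
#' @param mu Specific growth rate, 1/s.
#' @param yield Biomass yield, kgDW/mol (> 0).
#' @param dt Time step, s.
#' @return Moles consumed over the step.
#' @export
consumption <- function(mass, mu, yield, dt) {
  if (any(yield <= 0)) stop("yield must be positive", call. = FALSE)
  mu * mass * dt / yield
}
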