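#' Association constant from binding free energy
#'
#' Converts a binding free energy into the 1:1 association constant
#' Ka = exp(-dG / (R T)), with R = 1.9872e-3 kcal/(mol K).
#'
#' @param dG Binding free energy, kcal/mol. Vectorised.
#' @param temperature Absolute temperature, kelvin.
#' @return Association constant in 1/M.
#' @export
#' @examples
#' association_constant(-10, 298.15)
association_constant <- function(dG, temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    abort("`temperature` must be positive.", class = "itcbayes_invalid_design")
  exp(-dG / (R_GAS * temperature))
}

#' Equilibrium complex concentration for 1:1 binding
#'
#' Solves the mass-action quadratic for the bound complex at total
#' concentrations `Rtot` (titrand) and `Ltot` (titrant) with association
#' constant `Ka`:
#' \deqn{[RL] = \tfrac12\left[(R + L + 1/K_a) -
#'   \sqrt{(R + L + 1/K_a)^2 - 4RL}\right].}
#' The physically admissible root always satisfies
#' `0 <= [RL] <= min(Rtot, Ltot)`. The arithmetically equivalent form
#' `2RL / (b + sqrt(b^2 - 4RL))` is used to avoid cancellation when binding
#' is weak.
#'
#' @param Rtot,Ltot Total titrand / titrant concentrations, mol/L.
#'   Vectorised.
#' @param Ka Association constant, 1/M.
#' @return Complex concentration, mol/L.
#' @export
complex_concentration <- function(Rtot, Ltot, Ka) {
  if (any(Rtot < 0) || any(Ltot < 0))
    abort("Total concentrations must be non-negative.",
          class = "itcbayes_invalid_input")
  if (any(Ka <= 0))
    abort("`Ka` must be positive.", class = "itcbayes_invalid_input")
  b <- Rtot + Ltot + 1 / Ka
  disc <- pmax(b * b - 4 * Rtot * Ltot, 0)
  rl <- 2 * Rtot * Ltot / (b + sqrt(disc))
  pmin(pmax(rl, 0), pmin(Rtot, Ltot))
}

#' Noise-free model injection heats
#'
#' Evaluates the 1:1 perfusion-cell binding isotherm: for each injection the
#' heat is the enthalpy times the change in moles of complex in the cell,
#' accounting for the displaced volume, plus a constant per-injection
#' dilution/stirring heat.
#'
#' With the displaced-volume convention the cumulative dilution factor after
#' injection n is \eqn{d_n = \prod_{i \le n} (1 - v_i/V_0)}; total cell
#' concentrations are \eqn{R_n = [R]_0 d_n} and \eqn{L_n = [L]_s (1 - d_n)}.
#' With complex concentration \eqn{c_n} at equilibrium, the modelled heat of
#' injection n (cal) is
#' \deqn{q^*_n = V_0\,\Delta H\,(c_n - c_{n-1}(1 - v_n/V_0)) \cdot 10^3
#'   + \Delta H_0,}
#' the factor \eqn{10^3} converting \eqn{\Delta H} from kcal/mol to cal/mol,
#' and \eqn{c_0 = 0}. An exponential continuous-overflow convention
#' \eqn{d_n = \exp(-\sum_{i\le n} v_i / V_0)} is available as an
#' alternative.
#'
#' @param state Parameter state (see [itc_state()]).
#' @param design Experiment design (see [itc_design()]).
#' @param dilution Dilution convention: `"displaced"` (default) or
#'   `"exponential"`.
#' @return Numeric vector of model heats, cal, one per injection.
#' @export
#' @examples
#' d <- mg_edta_design()
#' s <- itc_state(dG = -10, dH = -5, dH0 = 0.5e-6,
#'                Ls = 1e-3, R0 = 1e-4, sigma = 1e-6)
#' model_heats(s, d)
model_heats <- function(state, design,
                        dilution = c("displaced", "exponential")) {
  dilution <- match.arg(dilution)
  s <- as_state_vector(state)
  v <- design$injection_volumes
  V0 <- design$cell_volume
  if (any(v >= V0))
    abort("Injection volume >= cell volume: cell fully displaced.",
          class = "itcbayes_invalid_design")
  d <- switch(dilution,
    displaced   = cumprod(1 - v / V0),
    exponential = exp(-cumsum(v) / V0)
  )
  Ka <- association_constant(s[["dG"]], design$temperature)
  Rn <- s[["R0"]] * d
  Ln <- s[["Ls"]] * (1 - d)
  cn <- complex_concentration(Rn, Ln, Ka)
  c_prev <- c(0, cn[-length(cn)])
  V0 * s[["dH"]] * 1e3 * (cn - c_prev * (1 - v / V0)) + s[["dH0"]]
}
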