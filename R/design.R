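#' Describe an ITC experiment design
#'
#' Bundles the instrument and protocol constants needed to evaluate the
#' binding heat model: cell volume, per-injection volumes, temperature, and
#' the concentrations of titrand (cell) and titrant (syringe) stated by the
#' experimenter. All values are in base units: litres, kelvin, mol/L.
#'
#' @param cell_volume Sample cell volume V0 in litres.
#' @param injection_volumes Numeric vector of injection volumes in litres,
#'   one per injection.
#' @param temperature Absolute temperature in kelvin.
#' @param stated_R0 Stated (intended) titrand concentration in the cell,
#'   mol/L.
#' @param stated_Ls Stated titrant concentration in the syringe, mol/L.
#'
#' @return An object of class `itc_design`.
#' @seealso [mg_edta_design()] for the VP-ITC protocol used throughout the
#'   package examples.
#' @export
#' @examples
#' itc_design(
#'   cell_volume = 1.43e-3,
#'   injection_volumes = c(2e-6, rep(12e-6, 23)),
#'   temperature = 298.15,
#'   stated_R0 = 1e-4,
#'   stated_Ls = 1e-3
#' )
itc_design <- function(cell_volume, injection_volumes, temperature,
                       stated_R0, stated_Ls) {
  if (!is.numeric(cell_volume) || length(cell_volume) != 1 || cell_volume <= 0)
    abort("`cell_volume` must be a single positive number (litres).",
          class = "itcbayes_invalid_design")
  if (!is.numeric(injection_volumes) || length(injection_volumes) < 1 ||
      any(injection_volumes <= 0))
    abort("`injection_volumes` must be positive (litres), length >= 1.",
          class = "itcbayes_invalid_design")
  if (any(injection_volumes >= cell_volume))
    abort("An injection volume equals or exceeds the cell volume.",
          class = "itcbayes_invalid_design")
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    abort("`temperature` must be a single positive number (kelvin).",
          class = "itcbayes_invalid_design")
  if (stated_R0 <= 0 || stated_Ls <= 0)
    abort("Stated concentrations must be positive (mol/L).",
          class = "itcbayes_invalid_design")
  structure(
    list(
      cell_volume = as.numeric(cell_volume),
      injection_volumes = as.numeric(injection_volumes),
      temperature = as.numeric(temperature),
      stated_R0 = as.numeric(stated_R0),
      stated_Ls = as.numeric(stated_Ls)
    ),
    class = "itc_design"
  )
}

#' VP-ITC protocol design for a metal:chelator titration
#'
#' The injection schedule used for Mg(II):EDTA titrations on a MicroCal
#' VP-ITC: one 2 uL priming injection followed by 23 injections of 12 uL,
#' nominal cell volume 1.43 mL, 298.15 K, with 0.1 mM titrand and 1 mM
#' titrant as stated concentrations. This schedule is also the default
#' design for simulated experiments.
#'
#' @param stated_R0,stated_Ls Stated concentrations (mol/L); defaults 1e-4
#'   and 1e-3.
#' @param n_injections Total number of injections (first is 2 uL).
#' @return An `itc_design`.
#' @export
mg_edta_design <- function(stated_R0 = 1e-4, stated_Ls = 1e-3,
                           n_injections = 24) {
  itc_design(
    cell_volume = 1.43e-3,
    injection_volumes = c(2e-6, rep(12e-6, n_injections - 1)),
    temperature = 298.15,
    stated_R0 = stated_R0,
    stated_Ls = stated_Ls
  )
}

#' @export
print.itc_design <- function(x, ...) {
  cat("<itc_design>\n")
  cat(sprintf("  cell volume : %.4g mL\n", x$cell_volume * 1e3))
  cat(sprintf("  injections  : %d (%.3g-%.3g uL)\n",
              length(x$injection_volumes),
              min(x$injection_volumes) * 1e6,
              max(x$injection_volumes) * 1e6))
  cat(sprintf("  temperature : %.2f K\n", x$temperature))
  cat(sprintf("  stated [R]0 : %.4g mM, stated [L]s : %.4g mM\n",
              x$stated_R0 * 1e3, x$stated_Ls * 1e3))
  invisible(x)
}

#' Construct a thermodynamic parameter state
#'
#' One point in the six-dimensional parameter space sampled by the Bayesian
#' model: binding free energy and enthalpy (kcal/mol), per-injection
#' dilution/stirring heat (cal), true syringe and cell concentrations
#' (mol/L), and the per-injection heat noise standard deviation (cal).
#'
#' @param dG Binding free energy, kcal/mol.
#' @param dH Binding enthalpy, kcal/mol.
#' @param dH0 Per-injection dilution/stirring heat, cal.
#' @param Ls True syringe titrant concentration, mol/L.
#' @param R0 True cell titrand concentration, mol/L.
#' @param sigma Heat measurement standard deviation, cal.
#' @return A named numeric vector with class `itc_state`.
#' @export
itc_state <- function(dG, dH, dH0, Ls, R0, sigma) {
  if (Ls <= 0 || R0 <= 0 || sigma <= 0)
    abort("`Ls`, `R0` and `sigma` must be positive.",
          class = "itcbayes_invalid_state")
  structure(
    c(dG = as.numeric(dG), dH = as.numeric(dH), dH0 = as.numeric(dH0),
      Ls = as.numeric(Ls), R0 = as.numeric(R0), sigma = as.numeric(sigma)),
    class = "itc_state"
  )
}

state_names <- c("dG", "dH", "dH0", "Ls", "R0", "sigma")

## Accept an itc_state, a plain named vector, or a one-row data frame.
as_state_vector <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, state_names])
  s <- as.numeric(state[state_names])
  if (anyNA(s))
    abort("State must supply dG, dH, dH0, Ls, R0 and sigma.",
          class = "itcbayes_invalid_state")
  names(s) <- state_names
  s
}

## Pull a numeric heat vector (cal) out of whatever the user passed:
## a numeric vector, or a data frame with a `heat` column.
heat_vector <- function(heats) {
  if (is.data.frame(heats)) {
    if (!"heat" %in% names(heats))
      abort("Heat data frame must have a `heat` column (cal).",
            class = "itcbayes_format_error")
    return(as.numeric(heats$heat))
  }
  as.numeric(heats)
}
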