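#' Specify a synthetic titration study
#'
#' Parameters of the simulated ITC validation study: true thermodynamic
#' values, stated concentrations, the fractional lognormal concentration
#' error applied when drawing the true concentrations, and the Gaussian
#' heat noise. The defaults reproduce the 50-curve study used to validate
#' credible-interval calibration: 24 injections, dG = -10 kcal/mol,
#' dH = -5 kcal/mol, dH0 = 0.5 ucal, stated 0.1 mM (cell) and 1 mM
#' (syringe) with 10% concentration error and 1 ucal heat noise.
#'
#' @param dG,dH True binding free energy and enthalpy, kcal/mol.
#' @param dH0 True per-injection dilution heat, cal.
#' @param stated_R0,stated_Ls Stated concentrations, mol/L.
#' @param concentration_cv Fractional (lognormal) concentration error;
#'   the true concentration of each replicate is drawn with mean equal to
#'   the stated value and coefficient of variation `concentration_cv`.
#' @param noise_sd Standard deviation of additive Gaussian heat noise, cal.
#' @param n_injections Number of injections per experiment.
#' @param n_replicates Number of independent simulated experiments.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(dG = -10, dH = -5, dH0 = 0.5e-6,
                            stated_R0 = 1e-4, stated_Ls = 1e-3,
                            concentration_cv = 0.1, noise_sd = 1e-6,
                            n_injections = 24, n_replicates = 50) {
  if (concentration_cv < 0 || noise_sd < 0)
    abort("`concentration_cv` and `noise_sd` must be non-negative.",
          class = "itcbayes_invalid_input")
  if (n_injections < 1 || n_replicates < 1)
    abort("`n_injections` and `n_replicates` must be >= 1.",
          class = "itcbayes_invalid_input")
  structure(
    list(dG = dG, dH = dH, dH0 = dH0,
         stated_R0 = stated_R0, stated_Ls = stated_Ls,
         concentration_cv = concentration_cv, noise_sd = noise_sd,
         n_injections = as.integer(n_injections),
         n_replicates = as.integer(n_replicates)),
    class = "simulation_spec"
  )
}

#' Log-scale parameters of a lognormal with given mean and SD
#'
#' The lognormal convention used throughout the package (simulator and
#' concentration priors alike): the concentration itself is lognormal with
#' arithmetic mean equal to the stated value and standard deviation
#' `cv * mean`. Returns the corresponding `meanlog` and `sdlog`.
#'
#' @param mean Arithmetic mean of the lognormal variable.
#' @param sd Arithmetic standard deviation.
#' @return Named list with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  if (mean <= 0 || sd < 0)
    abort("`mean` must be positive and `sd` non-negative.",
          class = "itcbayes_invalid_input")
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Draw true concentrations for one simulated experiment
#'
#' Draws the true cell and syringe concentrations from lognormal laws whose
#' mean equals the stated value and whose coefficient of variation equals
#' `concentration_cv`. A CV of zero returns the stated values exactly. Uses
#' the current R random number stream.
#'
#' @param spec A [simulation_spec()].
#' @return Named list with `R0` and `Ls` (mol/L).
#' @export
draw_true_concentrations <- function(spec) {
  if (spec$concentration_cv == 0)
    return(list(R0 = spec$stated_R0, Ls = spec$stated_Ls))
  pr <- lognormal_params(spec$stated_R0, spec$concentration_cv * spec$stated_R0)
  pl <- lognormal_params(spec$stated_Ls, spec$concentration_cv * spec$stated_Ls)
  list(R0 = rlnorm(1, pr$meanlog, pr$sdlog),
       Ls = rlnorm(1, pl$meanlog, pl$sdlog))
}

#' Simulate one ITC experiment
#'
#' Draws true concentrations (unless supplied), evaluates the noise-free
#' binding isotherm, and adds independent Gaussian heat noise:
#' `q_i = q*_i + e_i`, `e_i ~ N(0, noise_sd^2)`. Uses the current R random
#' number stream; call `set.seed()` beforehand for reproducibility.
#'
#' @param spec A [simulation_spec()].
#' @param design An [itc_design()]; defaults to the VP-ITC schedule of
#'   [mg_edta_design()] with the spec's stated concentrations.
#' @param truth Optional `itc_state` giving the true parameters; when
#'   `NULL`, concentrations are drawn via [draw_true_concentrations()] and
#'   thermodynamic values taken from `spec` (the true `sigma` is
#'   `noise_sd`, floored at 1e-12 cal so the state stays valid in the
#'   noiseless limit).
#' @return A list with `data` (tibble: `injection`, `volume` in L, `heat`
#'   in cal) and `truth` (the `itc_state` used).
#' @export
simulate_experiment <- function(spec, design = NULL, truth = NULL) {
  if (is.null(design))
    design <- mg_edta_design(stated_R0 = spec$stated_R0,
                             stated_Ls = spec$stated_Ls,
                             n_injections = spec$n_injections)
  if (length(design$injection_volumes) != spec$n_injections)
    abort("Design does not have `n_injections` injection volumes.",
          class = "itcbayes_invalid_design")
  if (is.null(truth)) {
    conc <- draw_true_concentrations(spec)
    truth <- itc_state(dG = spec$dG, dH = spec$dH, dH0 = spec$dH0,
                       Ls = conc$Ls, R0 = conc$R0,
                       sigma = max(spec$noise_sd, 1e-12))
  }
  qstar <- model_heats(truth, design)
  eps <- if (spec$noise_sd > 0)
    rnorm(spec$n_injections, 0, spec$noise_sd) else 0
  list(
    data = tibble(
      injection = seq_len(spec$n_injections),
      volume = design$injection_volumes,
      heat = qstar + eps
    ),
    truth = truth
  )
}

#' Generate a replicated simulation study
#'
#' Simulates `n_replicates` independent experiments, each with freshly
#' drawn true concentrations and heat noise.
#'
#' @param spec A [simulation_spec()].
#' @param design Optional [itc_design()] shared by all replicates.
#' @param seed Optional integer seed; when given the study is reproducible.
#' @return A tibble with one row per replicate: `replicate`, list-column
#'   `data` (heat tibbles) and list-column `truth` (`itc_state`s).
#' @export
#' @examples
#' study <- generate_study(simulation_spec(n_replicates = 3), seed = 1)
#' study$data[[1]]
generate_study <- function(spec, design = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sims <- purrr::map(seq_len(spec$n_replicates),
                     function(i) simulate_experiment(spec, design))
  tibble(
    replicate = seq_len(spec$n_replicates),
    data = purrr::map(sims, "data"),
    truth = purrr::map(sims, "truth")
  )
}
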