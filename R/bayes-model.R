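#' Configure the prior model
#'
#' The prior factorises over parameters: uniform boxes for dG, dH and dH0
#' (the dH0 box is data-driven, spanning the observed heat range extended
#' by one range-width on each side), a Jeffreys prior p(sigma) ~ 1/sigma
#' restricted to finite log-scale bounds, and one of three concentration
#' models:
#'
#' * `"general"` — lognormal priors on both concentrations, mean equal to
#'   the stated value, CV 0.1 (recommended for most analyses);
#' * `"flat-r0"` — uniform titrand concentration on
#'   (stated/10, 10 x stated), lognormal titrant with CV 0.1 (for impure or
#'   partially degraded titrand);
#' * `"comparison"` — uniform titrand as above and a sharply peaked
#'   lognormal titrant (CV 0.001), mimicking the standard least-squares
#'   treatment in which the titrant concentration is taken as known.
#'
#' @param model Concentration prior model.
#' @param dG_bounds,dH_bounds Uniform prior boxes, kcal/mol.
#' @param titrant_cv,titrand_cv Fractional uncertainties for the lognormal
#'   concentration priors; defaults follow the selected model. `titrand_cv`
#'   is ignored by the flat-titrand models.
#' @param R0_flat_factor Half-decade factor f of the uniform titrand prior
#'   (stated/f, f x stated) used by `"flat-r0"` and `"comparison"`.
#' @param log_sigma_bounds Optional bounds for ln(sigma/1 cal). Default,
#'   computed from the data at evaluation time: ln of (heat range x 1e-4)
#'   to ln of (heat range x 10).
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(model = c("general", "flat-r0", "comparison"),
                         dG_bounds = c(-40, 40),
                         dH_bounds = c(-100, 100),
                         titrant_cv = NULL,
                         titrand_cv = NULL,
                         R0_flat_factor = 10,
                         log_sigma_bounds = NULL) {
  model <- match.arg(model)
  if (is.null(titrant_cv))
    titrant_cv <- if (model == "comparison") 0.001 else 0.1
  if (is.null(titrand_cv))
    titrand_cv <- if (model == "general") 0.1 else NA_real_
  stopifnot(dG_bounds[1] < dG_bounds[2], dH_bounds[1] < dH_bounds[2],
            titrant_cv >= 0, R0_flat_factor > 1)
  structure(
    list(model = model, dG_bounds = dG_bounds, dH_bounds = dH_bounds,
         titrant_cv = titrant_cv, titrand_cv = titrand_cv,
         R0_flat_factor = R0_flat_factor,
         log_sigma_bounds = log_sigma_bounds),
    class = "prior_config"
  )
}

## dH0 prior box (cal) from the observed heats: (qmin - dq, qmax + dq).
dH0_bounds <- function(q) {
  qr <- range(q)
  dq <- qr[2] - qr[1]
  c(qr[1] - dq, qr[2] + dq)
}

## Default ln(sigma) bounds from the observed heat range.
default_log_sigma_bounds <- function(q) {
  qr <- diff(range(q))
  if (qr <= 0) qr <- max(abs(q), 1e-12)
  c(log(qr * 1e-4), log(qr * 10))
}

resolve_log_sigma_bounds <- function(config, q) {
  if (is.null(config$log_sigma_bounds)) default_log_sigma_bounds(q)
  else config$log_sigma_bounds
}

#' Gaussian log-likelihood of the injection heats
#'
#' Independent homoscedastic Gaussian errors about the model heats:
#' \deqn{\ln p(D|\theta) = -\tfrac{N}{2}\ln(2\pi) - N\ln\sigma
#'   - \frac{1}{2\sigma^2}\sum_n (q_n - q^*_n(\theta))^2.}
#'
#' @param state Parameter state ([itc_state()] or named vector).
#' @param heats Observed heats: numeric vector (cal) or a data frame with a
#'   `heat` column.
#' @param design An [itc_design()].
#' @return Log-likelihood in nats.
#' @export
log_likelihood <- function(state, heats, design) {
  s <- as_state_vector(state)
  if (s[["sigma"]] <= 0)
    abort("`sigma` must be positive.", class = "itcbayes_invalid_state")
  q <- heat_vector(heats)
  qstar <- model_heats(s, design)
  n <- length(q)
  if (length(qstar) != n)
    abort("Design and heats disagree on the number of injections.",
          class = "itcbayes_format_error")
  -n / 2 * log(2 * pi) - n * log(s[["sigma"]]) -
    sum((q - qstar)^2) / (2 * s[["sigma"]]^2)
}

#' Log prior density of a parameter state
#'
#' Sum of the log prior terms described in [prior_config()], up to additive
#' constants that do not depend on the state. States outside any bound have
#' log prior `-Inf`.
#'
#' @inheritParams log_likelihood
#' @param config A [prior_config()].
#' @return Log prior density in nats (up to a constant).
#' @export
log_prior <- function(state, config, heats, design) {
  s <- as_state_vector(state)
  q <- heat_vector(heats)
  b_dH0 <- dH0_bounds(q)
  b_lsig <- resolve_log_sigma_bounds(config, q)
  if (s[["dG"]] < config$dG_bounds[1] || s[["dG"]] > config$dG_bounds[2] ||
      s[["dH"]] < config$dH_bounds[1] || s[["dH"]] > config$dH_bounds[2] ||
      s[["dH0"]] < b_dH0[1] || s[["dH0"]] > b_dH0[2] ||
      s[["sigma"]] <= 0 || s[["Ls"]] <= 0 || s[["R0"]] <= 0)
    return(-Inf)
  lsig <- log(s[["sigma"]])
  if (lsig < b_lsig[1] || lsig > b_lsig[2]) return(-Inf)

  lp <- -lsig  # Jeffreys: p(sigma) ~ 1/sigma (sigma0 = 1 cal)

  # titrant [L]s: lognormal in every model
  pl <- lognormal_params(design$stated_Ls,
                         config$titrant_cv * design$stated_Ls)
  lp <- lp + dlnorm(s[["Ls"]], pl$meanlog, pl$sdlog, log = TRUE)

  # titrand [R]0: lognormal (general) or uniform box (flat-r0, comparison)
  if (config$model == "general") {
    pr <- lognormal_params(design$stated_R0,
                           config$titrand_cv * design$stated_R0)
    lp <- lp + dlnorm(s[["R0"]], pr$meanlog, pr$sdlog, log = TRUE)
  } else {
    f <- config$R0_flat_factor
    if (s[["R0"]] < design$stated_R0 / f || s[["R0"]] > design$stated_R0 * f)
      return(-Inf)
  }
  lp
}

#' Log posterior density
#'
#' `log_likelihood + log_prior`; `-Inf` outside the prior support.
#'
#' @inheritParams log_prior
#' @return Unnormalised log posterior density in nats.
#' @export
log_posterior <- function(state, config, heats, design) {
  lp <- log_prior(state, config, heats, design)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(state, heats, design)
}
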