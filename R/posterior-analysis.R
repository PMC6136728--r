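#' Shortest credible interval
#'
#' The shortest contiguous interval containing a fraction `level` of the
#' samples: among all windows of `ceiling(level * n)` consecutive order
#' statistics, the one of minimal width (ties broken by the lower lower
#' bound). For unimodal posteriors this is the highest-density interval.
#'
#' @param x Numeric vector of posterior draws (length >= 2).
#' @param level Credible level in (0, 1].
#' @param parameter Optional parameter name recorded in the result.
#' @return One-row tibble: `parameter`, `lower`, `upper`, `level`,
#'   `method = "BCI"`.
#' @export
#' @examples
#' shortest_credible_interval(rnorm(1e4), 0.95)
shortest_credible_interval <- function(x, level, parameter = NA_character_) {
  x <- as.numeric(x)
  if (length(x) < 2 || anyNA(x))
    abort("Need at least two non-missing samples.",
          class = "itcbayes_invalid_input")
  if (level <= 0 || level > 1)
    abort("`level` must be in (0, 1].", class = "itcbayes_invalid_input")
  xs <- sort(x)
  n <- length(xs)
  m <- min(ceiling(level * n), n)
  if (m < 2) m <- 2
  widths <- xs[m:n] - xs[1:(n - m + 1)]
  i <- which.min(widths)  # first minimum = lowest lower bound on ties
  tibble(parameter = parameter, lower = xs[i], upper = xs[i + m - 1],
         level = level, method = "BCI")
}

fit_samples <- function(fit) {
  if (inherits(fit, "itc_bayes_fit")) fit$samples else as_tibble(fit)
}

#' Summarise a posterior sample
#'
#' Per-parameter median, mean, and shortest credible intervals at the
#' requested levels, for the six sampled parameters plus the derived
#' entropic term `TdS = dH - dG` (computed draw by draw before
#' summarising).
#'
#' @param fit An `itc_bayes_fit`, or a data frame of draws with columns
#'   `dG`, `dH`, `dH0`, `Ls`, `R0`, `sigma`.
#' @param levels Credible levels for the intervals.
#' @return Tibble: `parameter`, `level`, `median`, `mean`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(fit, levels = 0.95) {
  draws <- fit_samples(fit)
  if (nrow(draws) == 0)
    abort("Empty posterior sample.", class = "itcbayes_invalid_input")
  draws <- mutate(draws, TdS = .data$dH - .data$dG)
  pars <- c(state_names, "TdS")
  purrr::map(pars, function(p) {
    purrr::map(levels, function(l) {
      ci <- shortest_credible_interval(draws[[p]], l, parameter = p)
      tibble(parameter = p, level = l,
             median = median(draws[[p]]), mean = mean(draws[[p]]),
             lower = ci$lower, upper = ci$upper)
    }) |> bind_rows()
  }) |> bind_rows()
}

#' @describeIn fit_bayes Tidy per-parameter summary (median point
#'   estimate, mean, and shortest credible interval bounds).
#' @param x An `itc_bayes_fit`.
#' @param level Credible level for the interval columns.
#' @param ... Unused.
#' @export
tidy.itc_bayes_fit <- function(x, level = 0.95, ...) {
  posterior_summary(x, levels = level) |>
    select(term = "parameter", estimate = "median", "mean",
           conf.low = "lower", conf.high = "upper", "level")
}

#' @describeIn fit_bayes One-row fit summary (sample count, thinning,
#'   prior model, acceptance range, log-posterior of the last draw).
#' @export
glance.itc_bayes_fit <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    thin = x$sampler$thin,
    prior_model = x$prior$model,
    min_acceptance = min(x$acceptance, na.rm = TRUE),
    max_acceptance = max(x$acceptance, na.rm = TRUE),
    final_lp = x$samples$lp[nrow(x$samples)]
  )
}

#' Posterior correlation matrix with bootstrap uncertainty
#'
#' Pearson correlations over the six sampled quantities (dG, dH, dH0, Ls,
#' R0, ln sigma), with per-entry standard deviations from bootstrap
#' resampling of the stored draws with replacement.
#'
#' @param fit An `itc_bayes_fit` or a data frame of draws.
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @return List of class `itc_correlation` with `estimate` and `sd`
#'   (6 x 6 matrices over `dG`, `dH`, `dH0`, `Ls`, `R0`, `lsig`).
#' @export
correlation_matrix <- function(fit, n_bootstrap = 1000) {
  draws <- fit_samples(fit)
  if (nrow(draws) < 10)
    abort("Need at least 10 draws.", class = "itcbayes_invalid_input")
  m <- cbind(dG = draws$dG, dH = draws$dH, dH0 = draws$dH0,
             Ls = draws$Ls, R0 = draws$R0, lsig = log(draws$sigma))
  degenerate <- apply(m, 2, function(col) var(col) == 0)
  if (any(degenerate))
    warn(paste("Zero-variance column(s):",
               paste(colnames(m)[degenerate], collapse = ", "),
               "- correlations undefined (NA)."))
  est <- suppressWarnings(cor(m))
  diag(est) <- 1
  boots <- array(NA_real_, c(6, 6, n_bootstrap))
  n <- nrow(m)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[, , b] <- suppressWarnings(cor(m[idx, , drop = FALSE]))
  }
  sd_mat <- apply(boots, c(1, 2), sd)
  dimnames(sd_mat) <- dimnames(est)
  structure(list(estimate = est, sd = sd_mat, n_bootstrap = n_bootstrap),
            class = "itc_correlation")
}

#' @export
print.itc_correlation <- function(x, ...) {
  cat("<itc_correlation> posterior correlation matrix",
      sprintf("(bootstrap SDs from %d replicates)\n", x$n_bootstrap))
  print(round(x$estimate, 3))
  invisible(x)
}

#' Enthalpy-concentration trade-off along the posterior ridge
#'
#' The titrant concentration and enthalpy are nearly linear functions of
#' the titrand concentration along the posterior: this fits least-squares
#' lines for `Ls` and `dH` versus `R0` over the draws and evaluates the
#' model heat curve at a grid of `R0` values along the fitted ridge (with
#' `dG` and `dH0` taken from the last stored draw), illustrating that
#' compensating parameter changes leave the heat curve nearly unchanged.
#'
#' @param fit An `itc_bayes_fit`.
#' @param design An [itc_design()]; defaults to the fit's design.
#' @param r0_values Grid of titrand concentrations (mol/L); defaults to
#'   five values spanning the sampled `R0` range.
#' @return List of class `itc_tradeoff`: `fits` (tibble with slope and
#'   intercept of each regression) and `curves` (tibble: `R0`,
#'   `injection`, `heat`).
#' @export
enthalpy_concentration_tradeoff <- function(fit, design = NULL,
                                            r0_values = NULL) {
  draws <- fit_samples(fit)
  if (is.null(design)) design <- fit$design
  if (var(draws$R0) == 0)
    abort("Draws have zero variance in R0; ridge undefined.",
          class = "itcbayes_invalid_input")
  ls_fit <- lm(Ls ~ R0, data = draws)
  dh_fit <- lm(dH ~ R0, data = draws)
  if (is.null(r0_values))
    r0_values <- seq(min(draws$R0), max(draws$R0), length.out = 5)
  last <- draws[nrow(draws), ]
  curves <- purrr::map(r0_values, function(r0) {
    s <- itc_state(
      dG = last$dG, dH = coef(dh_fit)[1] + coef(dh_fit)[2] * r0,
      dH0 = last$dH0,
      Ls = coef(ls_fit)[1] + coef(ls_fit)[2] * r0,
      R0 = r0, sigma = last$sigma
    )
    tibble(R0 = r0,
           injection = seq_along(design$injection_volumes),
           heat = model_heats(s, design))
  }) |> bind_rows()
  structure(
    list(
      fits = tibble(
        response = c("Ls", "dH"),
        intercept = unname(c(coef(ls_fit)[1], coef(dh_fit)[1])),
        slope = unname(c(coef(ls_fit)[2], coef(dh_fit)[2]))
      ),
      curves = curves
    ),
    class = "itc_tradeoff"
  )
}
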