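#' Nonlinear least-squares fit of a titration curve
#'
#' The standard frequentist analysis: minimises the sum of squared
#' residuals between observed and model heats over the association
#' constant Ka, enthalpy dH, stoichiometry n, and per-injection offset
#' dH0. The titrant concentration is fixed at its stated value and the
#' effective titrand concentration is `n * stated_R0`, so titrand
#' concentration error is absorbed by the free stoichiometry. The fit is
#' parameterised in ln(Ka) for stability; standard errors come from the
#' residual-scaled inverse of the approximate normal matrix at the
#' optimum, with errors for Ka and dG obtained from the ln(Ka) error by
#' the delta method.
#'
#' @param data Observed heats: tibble with a `heat` column (cal) or
#'   numeric vector.
#' @param design An [itc_design()].
#' @param exclude_first Drop the first injection from the fit (a common
#'   guard against the first-injection anomaly)?
#' @param start Optional named list of starting values (`logKa`, `dH`,
#'   `n`, `dH0`).
#' @return Object of class `itc_nls_fit`: `estimates` tibble (`term`,
#'   `estimate`, `std.error` for Ka, dG, dH, n, dH0), residual standard
#'   deviation `sigma`, and the underlying `nls` object.
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_experiment(simulation_spec())
#' fit <- fit_nls(sim$data, mg_edta_design())
#' tidy(fit)
fit_nls <- function(data, design, exclude_first = FALSE, start = NULL) {
  q <- heat_vector(data)
  keep <- if (exclude_first) -1 else seq_along(q)
  q_fit <- q[keep]
  if (length(q_fit) < 5)
    abort("Need at least 5 injections for a 4-parameter fit.",
          class = "itcbayes_invalid_input")

  RT <- R_GAS * design$temperature
  model_fn <- function(logKa, dH, n, dH0) {
    s <- c(dG = -RT * logKa, dH = dH, dH0 = dH0,
           Ls = design$stated_Ls, R0 = n * design$stated_R0, sigma = 1)
    model_heats(s, design)[keep]
  }

  if (is.null(start)) {
    dH0_start <- mean(utils::tail(q, 3))
    total <- sum(q - dH0_start)
    dH_start <- total / (design$cell_volume * design$stated_R0 * 1e3)
    if (!is.finite(dH_start) || dH_start == 0) dH_start <- -1
    start <- list(logKa = NA, dH = dH_start, n = 1, dH0 = dH0_start)
  }
  logKa_grid <- if (is.na(start$logKa)) log(10^seq(3, 9)) else start$logKa

  best <- NULL
  for (lk in logKa_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        q_fit ~ model_fn(logKa, dH, n, dH0),
        start = list(logKa = lk, dH = start$dH, n = start$n,
                     dH0 = start$dH0),
        lower = c(logKa = log(1e-2), dH = -200, n = 1e-3, dH0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    abort("Nonlinear least-squares fit failed to converge.",
          class = "itcbayes_fit_failure")

  fit <- best$fit
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  Ka <- exp(cf[["logKa"]])
  estimates <- tibble(
    term = c("Ka", "dG", "dH", "n", "dH0"),
    estimate = c(Ka, -RT * cf[["logKa"]], cf[["dH"]], cf[["n"]],
                 cf[["dH0"]]),
    std.error = c(Ka * se[["logKa"]], RT * se[["logKa"]], se[["dH"]],
                  se[["n"]], se[["dH0"]])
  )
  structure(
    list(estimates = estimates, sigma = summary(fit)$sigma, nls = fit,
         design = design, exclude_first = exclude_first),
    class = "itc_nls_fit"
  )
}

#' @describeIn fit_nls Tidy coefficient table.
#' @param x An `itc_nls_fit`.
#' @param ... Unused.
#' @export
tidy.itc_nls_fit <- function(x, ...) x$estimates

#' @describeIn fit_nls One-row fit summary.
#' @export
glance.itc_nls_fit <- function(x, ...) {
  tibble(sigma = x$sigma,
         n_injections = length(stats::resid(x$nls)),
         exclude_first = x$exclude_first)
}

#' @export
print.itc_nls_fit <- function(x, ...) {
  cat("<itc_nls_fit> nonlinear least-squares titration fit\n")
  print(as.data.frame(x$estimates), digits = 4)
  invisible(x)
}

#' Normal-theory confidence interval for a fitted parameter
#'
#' The interval is the point estimate plus/minus the standard normal
#' quantile for the requested level times the standard error; it is always
#' symmetric about the point estimate. A zero standard error yields a
#' zero-width interval and a warning.
#'
#' @param fit An `itc_nls_fit`.
#' @param parameter One of `"Ka"`, `"dG"`, `"dH"`, `"n"`, `"dH0"`.
#' @param level Confidence level in (0, 1).
#' @return One-row tibble: `parameter`, `lower`, `upper`, `level`,
#'   `method = "NlRCI"`.
#' @export
nls_confidence_interval <- function(fit, parameter, level = 0.95) {
  row <- fit$estimates[fit$estimates$term == parameter, ]
  if (nrow(row) != 1)
    abort(paste0("Unknown parameter '", parameter, "'."),
          class = "itcbayes_invalid_input")
  if (!is.finite(row$std.error))
    abort("Standard error is not finite.", class = "itcbayes_invalid_input")
  if (row$std.error == 0)
    warn(paste0("Zero standard error for '", parameter,
                "': zero-width interval."))
  z <- qnorm((1 + level) / 2)
  tibble(parameter = parameter,
         lower = row$estimate - z * row$std.error,
         upper = row$estimate + z * row$std.error,
         level = level, method = "NlRCI")
}

#' Observed interval coverage across experiments
#'
#' For each nominal level, the fraction of experiments whose interval
#' contains the reference value (the true value for simulations, or a
#' median-of-medians for replicate experiments), with bootstrap standard
#' deviations obtained by resampling experiments with replacement. A
#' calibrated interval method lies on the diagonal of observed versus
#' nominal level.
#'
#' @param intervals Tibble with columns `experiment`, `level`, `lower`,
#'   `upper` (one row per experiment and level).
#' @param reference Reference parameter value.
#' @param n_bootstrap Bootstrap replicates for the error bars.
#' @return Tibble: `level`, `observed`, `boot_sd`, `n`.
#' @export
coverage_curve <- function(intervals, reference, n_bootstrap = 1000) {
  req <- c("experiment", "level", "lower", "upper")
  if (!all(req %in% names(intervals)) || nrow(intervals) == 0)
    abort("`intervals` needs columns experiment, level, lower, upper.",
          class = "itcbayes_invalid_input")
  if (length(unique(intervals$experiment)) < 2)
    abort("Need intervals from at least two experiments.",
          class = "itcbayes_invalid_input")
  hits <- intervals |>
    mutate(hit = .data$lower <= reference & reference <= .data$upper)
  wide <- tidyr::pivot_wider(hits[, c("experiment", "level", "hit")],
                             names_from = "level", values_from = "hit")
  hit_mat <- as.matrix(wide[, -1, drop = FALSE])
  levels <- as.numeric(colnames(hit_mat))
  n_exp <- nrow(hit_mat)
  boot <- matrix(NA_real_, n_bootstrap, length(levels))
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n_exp, n_exp, replace = TRUE)
    boot[b, ] <- colMeans(hit_mat[idx, , drop = FALSE])
  }
  tibble(level = levels,
         observed = colMeans(hit_mat),
         boot_sd = apply(boot, 2, sd),
         n = n_exp) |>
    arrange(.data$level)
}

## Log KDE density of `at` under a Gaussian product kernel on `pts`
## (shared bandwidth in both dimensions, matching a Euclidean Gaussian
## kernel density estimate). Chunked to bound memory.
kde2d_log_density <- function(at, pts, bandwidth) {
  at <- as.matrix(at)
  pts <- as.matrix(pts)
  h2 <- bandwidth^2
  n <- nrow(pts)
  const <- -log(n) - log(2 * pi * h2)
  out <- numeric(nrow(at))
  chunk <- 512L
  for (start in seq(1, nrow(at), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(at))
    d2 <- outer(at[idx, 1], pts[, 1], "-")^2 +
      outer(at[idx, 2], pts[, 2], "-")^2
    ex <- -d2 / (2 * h2)
    mx <- apply(ex, 1, max)
    out[idx] <- mx + log(rowSums(exp(ex - mx))) + const
  }
  out
}

#' Kullback-Leibler divergence between two posterior clouds
#'
#' Estimates D_KL(p1 || p2) between the joint (dG, dH) densities of two
#' sample sets. Each density is a Gaussian kernel density estimate
#' (default bandwidth 0.03 kcal/mol); the integral is evaluated as the
#' Monte-Carlo average over the first sample set of the log density
#' ratio. The divergence is asymmetric in its arguments and exactly zero
#' when the two sets coincide.
#'
#' @param samples_1,samples_2 Data frames (or matrices) with columns `dG`
#'   and `dH`, kcal/mol.
#' @param bandwidth Kernel bandwidth, kcal/mol.
#' @return List of class `kl_estimate`: `value` (nats), `bandwidth`,
#'   `n1`, `n2`.
#' @export
kl_divergence_2d <- function(samples_1, samples_2, bandwidth = 0.03) {
  s1 <- extract_gh(samples_1)
  s2 <- extract_gh(samples_2)
  lp1 <- kde2d_log_density(s1, s1, bandwidth)
  lp2 <- kde2d_log_density(s1, s2, bandwidth)
  bad <- !is.finite(lp2)
  if (any(bad)) {
    warn(sprintf(
      "%d of %d evaluation points underflow the second density; clipped.",
      sum(bad), length(lp2)))
    lp2[bad] <- min(lp2[!bad], min(lp1) - 50)
  }
  structure(
    list(value = mean(lp1 - lp2), bandwidth = bandwidth,
         n1 = nrow(s1), n2 = nrow(s2)),
    class = "kl_estimate"
  )
}

extract_gh <- function(x) {
  if (inherits(x, "itc_bayes_fit")) x <- x$samples
  x <- as.data.frame(x)
  if (!all(c("dG", "dH") %in% names(x))) {
    if (ncol(x) >= 2) names(x)[1:2] <- c("dG", "dH")
    else abort("Samples must have columns dG and dH.",
               class = "itcbayes_invalid_input")
  }
  if (nrow(x) == 0)
    abort("Empty sample set.", class = "itcbayes_invalid_input")
  as.matrix(x[, c("dG", "dH")])
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("<kl_estimate> D_KL = %.4g nats (bandwidth %.3g, n1 = %d, n2 = %d)\n",
              x$value, x$bandwidth, x$n1, x$n2))
  invisible(x)
}

#' Pairwise Kullback-Leibler divergence matrix
#'
#' Computes [kl_divergence_2d()] for every ordered pair of experiments.
#' The matrix is asymmetric; entry (i, j) is D_KL(p_i || p_j). The
#' diagonal divergence is identically zero; when `log = TRUE` the natural
#' log of each divergence is returned and the diagonal (log of zero) is
#' replaced by `diag_sentinel` for display.
#'
#' @param experiments List (>= 2) of sample sets accepted by
#'   [kl_divergence_2d()].
#' @param bandwidth Kernel bandwidth, kcal/mol.
#' @param log Return the natural log of the divergences?
#' @param diag_sentinel Value placed on the diagonal when `log = TRUE`
#'   (default 1).
#' @return Square numeric matrix.
#' @export
kl_matrix <- function(experiments, bandwidth = 0.03, log = FALSE,
                      diag_sentinel = 1) {
  k <- length(experiments)
  if (k < 2)
    abort("Need at least two experiments.", class = "itcbayes_invalid_input")
  out <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j)
      out[i, j] <- kl_divergence_2d(experiments[[i]], experiments[[j]],
                                    bandwidth)$value
  }
  if (log) {
    out <- base::log(pmax(out, 0))
    diag(out) <- diag_sentinel
  }
  nm <- names(experiments)
  if (!is.null(nm)) dimnames(out) <- list(nm, nm)
  out
}

#' Parameter draws implied by a least-squares fit
#'
#' Draws (dG, dH) pairs from independent normal distributions with mean
#' and standard deviation equal to the fit's point estimates and standard
#' errors, giving the Gaussian cloud that the normal-theory analysis
#' implicitly asserts; used to compare least-squares uncertainty with
#' Bayesian posteriors on the same divergence scale.
#'
#' @param fit An `itc_nls_fit`.
#' @param n Number of draws.
#' @return Tibble with columns `dG` and `dH`.
#' @export
draw_nls_samples <- function(fit, n = 5000) {
  est <- fit$estimates
  g <- est[est$term == "dG", ]
  h <- est[est$term == "dH", ]
  tibble(dG = rnorm(n, g$estimate, g$std.error),
         dH = rnorm(n, h$estimate, h$std.error))
}
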