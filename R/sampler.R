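#' Configure the MCMC sampler
#'
#' The posterior is sampled by sequential-Gibbs Metropolis-Hastings: one
#' parameter at a time is perturbed by a normal proposal and accepted by
#' the Metropolis criterion, cycling through (dG, dH, dH0, Ls, R0, ln
#' sigma). A state is stored after every `thin` trial moves until
#' `n_samples` states are kept. Defaults follow the reference protocol:
#' 5000 stored samples, thinning 2000.
#'
#' @param n_samples Number of stored posterior samples.
#' @param thin Trial moves per stored sample.
#' @param scales Optional named numeric vector of proposal standard
#'   deviations for `dG`, `dH`, `dH0`, `Ls`, `R0`, `lsig`. Defaults: 1
#'   kcal/mol for dG and dH, 1 ucal for dH0, the stated concentration for
#'   Ls and R0, and 1 (log units) for ln sigma.
#' @param burn_in Stored samples to discard from the front of the chain.
#' @param tune Number of discarded adaptive-tuning trial moves run before
#'   sampling (0 = fixed scales, the reference behaviour).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 5000, thin = 2000, scales = NULL,
                           burn_in = 0, tune = 0) {
  stopifnot(n_samples >= 1, thin >= 1, burn_in >= 0, tune >= 0)
  if (!is.null(scales)) {
    if (!all(c("dG", "dH", "dH0", "Ls", "R0", "lsig") %in% names(scales)) ||
        any(scales <= 0))
      abort("`scales` must be positive and named dG, dH, dH0, Ls, R0, lsig.",
            class = "itcbayes_invalid_input")
  }
  structure(
    list(n_samples = as.integer(n_samples), thin = as.integer(thin),
         scales = scales, burn_in = as.integer(burn_in),
         tune = as.integer(tune)),
    class = "sampler_config"
  )
}

#' Initial parameter state for MCMC
#'
#' Concentrations start at their stated values; dG, dH and dH0 start at
#' zero; sigma starts at the standard deviation of the last four injection
#' heats (by then the titrand is usually saturated, so those heats reflect
#' noise about the dilution baseline). Degenerate cases are nudged back
#' into the prior support: a zero last-four SD falls back to a 1e-6 cal
#' floor, and when the data-driven dH0 box excludes zero the initial dH0
#' is its midpoint.
#'
#' @inheritParams log_likelihood
#' @return An [itc_state()].
#' @export
initialize_state <- function(heats, design) {
  q <- heat_vector(heats)
  sigma0 <- if (length(q) >= 4) sd(utils::tail(q, 4)) else 0
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 1e-6
  b <- dH0_bounds(q)
  dH0_init <- if (b[1] < 0 && b[2] > 0) 0 else mean(b)
  itc_state(dG = 0, dH = 0, dH0 = dH0_init,
            Ls = design$stated_Ls, R0 = design$stated_R0, sigma = sigma0)
}

default_scales <- function(heats, design) {
  q <- heat_vector(heats)
  sigma0 <- if (length(q) >= 4) sd(utils::tail(q, 4)) else 0
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 1e-6
  c(dG = 1, dH = 1, dH0 = 1e-6,
    Ls = design$stated_Ls, R0 = design$stated_R0, lsig = 1)
}

#' One Metropolis-Hastings coordinate update
#'
#' Perturbs coordinate `index` of `state` by a normal proposal of standard
#' deviation `scale` and accepts with probability min(1, posterior ratio).
#' With `log_scale = TRUE` the proposal is made on the logarithm of the
#' coordinate and the Jacobian of the transformation enters the acceptance
#' ratio, so the target remains the density of the untransformed state.
#'
#' @param state Named numeric parameter vector.
#' @param index Coordinate to update (integer or name).
#' @param log_post_fn Function mapping a state vector to a log density.
#' @param scale Proposal standard deviation.
#' @param log_scale Propose on the log of the coordinate?
#' @param log_post Optional cached `log_post_fn(state)` to avoid
#'   re-evaluation.
#' @return List with `state`, `accepted`, and the updated `log_post`.
#' @export
metropolis_update <- function(state, index, log_post_fn, scale,
                              log_scale = FALSE, log_post = NULL) {
  if (is.null(log_post)) log_post <- log_post_fn(state)
  proposal <- state
  if (log_scale) {
    proposal[index] <- exp(log(state[index]) + rnorm(1, 0, scale))
    jac <- log(proposal[index]) - log(state[index])
  } else {
    proposal[index] <- state[index] + rnorm(1, 0, scale)
    jac <- 0
  }
  lp_new <- log_post_fn(proposal)
  log_ratio <- lp_new - log_post + jac
  if (is.finite(log_ratio) && log(runif(1)) < log_ratio) {
    list(state = proposal, accepted = TRUE, log_post = lp_new)
  } else {
    list(state = state, accepted = FALSE, log_post = log_post)
  }
}

## Prior constants handed to the compiled kernel.
prior_constants <- function(config, heats, design) {
  q <- heat_vector(heats)
  pl <- lognormal_params(design$stated_Ls,
                         config$titrant_cv * design$stated_Ls)
  out <- list(
    conc_model = switch(config$model, general = 0L, `flat-r0` = 1L,
                        comparison = 2L),
    dG_bounds = config$dG_bounds,
    dH_bounds = config$dH_bounds,
    dH0_bounds = dH0_bounds(q),
    lsig_bounds = resolve_log_sigma_bounds(config, q),
    Ls_meanlog = pl$meanlog, Ls_sdlog = pl$sdlog
  )
  if (config$model == "general") {
    pr <- lognormal_params(design$stated_R0,
                           config$titrand_cv * design$stated_R0)
    out$R0_meanlog <- pr$meanlog
    out$R0_sdlog <- pr$sdlog
  } else {
    f <- config$R0_flat_factor
    out$R0_bounds <- c(design$stated_R0 / f, design$stated_R0 * f)
  }
  out
}

#' Sample the posterior of one ITC experiment
#'
#' Runs the Metropolis-within-Gibbs chain on the six-parameter posterior
#' for one experiment's injection heats. The default engine is a compiled
#' kernel; `engine = "r"` runs the same algorithm through
#' [metropolis_update()] in R (slow, used for cross-validation).
#' Randomness comes from the R random number stream: call `set.seed()` or
#' pass `seed` for reproducibility.
#'
#' @param data Observed heats: tibble with a `heat` column (cal) or a
#'   numeric vector.
#' @param design An [itc_design()].
#' @param prior A [prior_config()].
#' @param sampler A [sampler_config()].
#' @param seed Optional integer seed.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return An object of class `itc_bayes_fit`: list with `samples` (tibble
#'   of stored draws: `.draw`, `dG`, `dH`, `dH0`, `Ls`, `R0`, `sigma`,
#'   `lp`), per-parameter `acceptance` rates, and the configuration used.
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_experiment(simulation_spec())
#' fit <- fit_bayes(sim$data, mg_edta_design(),
#'                  sampler = sampler_config(n_samples = 200, thin = 20))
#' tidy(fit)
fit_bayes <- function(data, design, prior = prior_config(),
                      sampler = sampler_config(), seed = NULL,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  q <- heat_vector(data)
  if (length(q) != length(design$injection_volumes))
    abort("Design and heats disagree on the number of injections.",
          class = "itcbayes_format_error")
  init <- initialize_state(q, design)
  scales <- if (is.null(sampler$scales)) default_scales(q, design)
            else sampler$scales[c("dG", "dH", "dH0", "Ls", "R0", "lsig")]
  pc <- prior_constants(prior, q, design)
  # clamp the initial ln(sigma) into its sampling bounds
  lsig0 <- min(max(log(init[["sigma"]]), pc$lsig_bounds[1]),
               pc$lsig_bounds[2])
  x0 <- c(init[["dG"]], init[["dH"]], init[["dH0"]],
          init[["Ls"]], init[["R0"]], lsig0)

  if (engine == "cpp") {
    res <- itc_chain_cpp(q, design$injection_volumes, design$cell_volume,
                         1 / (R_GAS * design$temperature), pc, x0, scales,
                         sampler$n_samples, sampler$thin, sampler$tune)
    m <- res$samples
    acc <- setNames(as.numeric(res$acceptance), names(scales))
    scales <- setNames(as.numeric(res$scales), names(scales))
  } else {
    res <- run_chain_r(q, design, prior, x0, scales, sampler)
    m <- res$samples
    acc <- res$acceptance
  }
  colnames(m) <- c(state_names, "lp")
  samples <- as_tibble(as.data.frame(m))
  samples <- tibble(.draw = seq_len(nrow(samples)), !!!samples)
  if (sampler$burn_in > 0)
    samples <- samples[samples$.draw > sampler$burn_in, , drop = FALSE]
  if (all(acc == 0, na.rm = TRUE))
    warn("No proposals were accepted; check the proposal scales.")
  structure(
    list(samples = samples, acceptance = acc, scales = scales,
         prior = prior, sampler = sampler, design = design,
         data = tibble(injection = seq_along(q),
                       volume = design$injection_volumes, heat = q),
         seed = seed, engine = engine),
    class = "itc_bayes_fit"
  )
}

## Reference R implementation of the kernel (x-space, sigma on log scale).
run_chain_r <- function(q, design, prior, x0, scales, sampler) {
  pc <- prior_constants(prior, q, design)
  target <- function(x) {
    s <- c(x[1:5], exp(x[6]))
    names(s) <- state_names
    lp <- log_posterior(s, prior, q, design)
    if (!is.finite(lp)) return(-Inf)
    lp + x[6]  # Jacobian of sigma -> ln sigma
  }
  x <- x0
  lt <- target(x)
  if (!is.finite(lt))
    abort("Initial state has zero posterior density.",
          class = "itcbayes_invalid_state")
  n <- sampler$n_samples
  out <- matrix(NA_real_, n, 7)
  acc <- prop <- numeric(6)
  j <- 1
  for (s in seq_len(n)) {
    for (t in seq_len(sampler$thin)) {
      step <- metropolis_update(x, j, target, scales[j], log_post = lt)
      x <- step$state
      lt <- step$log_post
      prop[j] <- prop[j] + 1
      acc[j] <- acc[j] + step$accepted
      j <- if (j == 6) 1 else j + 1
    }
    out[s, ] <- c(x[1:5], exp(x[6]), lt - x[6])
  }
  list(samples = out, acceptance = setNames(acc / pmax(prop, 1),
                                            names(scales)))
}

#' @export
print.itc_bayes_fit <- function(x, ...) {
  cat("<itc_bayes_fit>\n")
  cat(sprintf("  %d stored samples (thin %d), prior model '%s'\n",
              nrow(x$samples), x$sampler$thin, x$prior$model))
  cat("  acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}

#' Run replicate chains on one experiment
#'
#' Runs `chains` independent chains with consecutive seeds, for use with
#' [convergence_report()].
#'
#' @inheritParams fit_bayes
#' @param chains Number of independent chains (>= 2).
#' @param seed Seed of the first chain; chain k uses `seed + k - 1`.
#' @return List of `itc_bayes_fit` objects.
#' @export
run_chains <- function(data, design, prior = prior_config(),
                       sampler = sampler_config(), chains = 5, seed = 1) {
  purrr::map(seq_len(chains), function(k) {
    fit_bayes(data, design, prior = prior, sampler = sampler,
              seed = seed + k - 1)
  })
}

#' Convergence diagnostics from replicate chains
#'
#' For each parameter and chain, computes running estimates of the
#' shortest credible interval bounds as the number of samples grows, then
#' compares the final bounds across chains. Sampling is flagged as
#' unconverged for a parameter when the across-chain standard deviation of
#' either bound exceeds 5% of the mean interval length.
#'
#' @param fits List of at least two `itc_bayes_fit` objects (replicate
#'   chains on the same data).
#' @param level Credible level (default 0.95).
#' @param checkpoints Sample counts at which running bounds are evaluated;
#'   defaults to 40 counts spaced evenly up to the chain length.
#' @return An object of class `itc_convergence`: list with `running`
#'   (tibble: `chain`, `parameter`, `n`, `lower`, `upper`) and `final`
#'   (tibble: `parameter`, mean/SD of the bounds, `mean_length`,
#'   `rel_sd`, `flag`).
#' @export
convergence_report <- function(fits, level = 0.95, checkpoints = NULL) {
  if (!is.list(fits) || length(fits) < 2)
    abort("At least two chains are required.",
          class = "itcbayes_invalid_input")
  n <- min(purrr::map_int(fits, ~ nrow(.x$samples)))
  if (is.null(checkpoints))
    checkpoints <- unique(pmax(2, round(seq(n / 40, n, length.out = 40))))
  running <- purrr::imap(fits, function(fit, k) {
    purrr::map(state_names, function(p) {
      draws <- fit$samples[[p]]
      bounds <- purrr::map(checkpoints, function(m) {
        ci <- shortest_credible_interval(draws[seq_len(m)], level)
        c(lower = ci$lower, upper = ci$upper)
      })
      tibble(chain = k, parameter = p, n = checkpoints,
             lower = purrr::map_dbl(bounds, "lower"),
             upper = purrr::map_dbl(bounds, "upper"))
    }) |> bind_rows()
  }) |> bind_rows()
  final <- running |>
    group_by(.data$parameter) |>
    filter(.data$n == max(.data$n)) |>
    summarise(
      mean_lower = mean(.data$lower), mean_upper = mean(.data$upper),
      sd_lower = sd(.data$lower), sd_upper = sd(.data$upper),
      .groups = "drop"
    ) |>
    mutate(
      mean_length = .data$mean_upper - .data$mean_lower,
      rel_sd = pmax(.data$sd_lower, .data$sd_upper) / .data$mean_length,
      flag = .data$rel_sd > 0.05
    )
  structure(list(running = running, final = final, level = level),
            class = "itc_convergence")
}

#' @export
print.itc_convergence <- function(x, ...) {
  cat(sprintf("<itc_convergence> %.0f%% interval stability across %d chains\n",
              x$level * 100, max(x$running$chain)))
  print(as.data.frame(x$final), digits = 4)
  if (any(x$final$flag))
    cat("Flagged parameters: ",
        paste(x$final$parameter[x$final$flag], collapse = ", "), "\n")
  invisible(x)
}
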