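test_that("least-squares fit recovers noiseless parameters", {
  d <- mg_edta_design()
  truth <- true_state()
  q <- model_heats(truth, d)
  fit <- fit_nls(q, d)
  est <- fit$estimates
  Ka_true <- association_constant(-10, d$temperature)
  expect_equal(est$estimate[est$term == "Ka"], Ka_true, tolerance = 1e-3)
  expect_equal(est$estimate[est$term == "dH"], -5, tolerance = 1e-3)
  expect_equal(est$estimate[est$term == "n"], 1, tolerance = 0.01)
  expect_equal(est$estimate[est$term == "dH0"], 0.5e-6, tolerance = 1e-2)
})

test_that("titrand concentration error is absorbed by the stoichiometry", {
  d <- mg_edta_design()
  truth <- itc_state(dG = -10, dH = -5, dH0 = 0.5e-6, Ls = 1e-3,
                     R0 = 0.9e-4, sigma = 1e-6)
  q <- model_heats(truth, d)  # true R0 is 90% of stated
  fit <- fit_nls(q, d)
  n_hat <- fit$estimates$estimate[fit$estimates$term == "n"]
  expect_equal(n_hat, 0.9, tolerance = 0.01)
})

test_that("a constant heat offset moves only the dilution term", {
  d <- mg_edta_design()
  q <- model_heats(true_state(), d)
  f0 <- fit_nls(q, d)
  f1 <- fit_nls(q + 2e-6, d)
  e0 <- f0$estimates$estimate
  e1 <- f1$estimates$estimate
  names(e0) <- names(e1) <- f0$estimates$term
  expect_equal(e1[["dH0"]] - e0[["dH0"]], 2e-6, tolerance = 1e-8)
  expect_equal(e1[["dH"]], e0[["dH"]], tolerance = 1e-5)
  expect_equal(e1[["n"]], e0[["n"]], tolerance = 1e-5)
})

test_that("normal-theory confidence intervals follow the closed form", {
  d <- mg_edta_design()
  set.seed(30)
  sim <- simulate_experiment(simulation_spec(), d)
  fit <- fit_nls(sim$data, d)

  # synthetic check of the quantile arithmetic: estimate 0, SE 1
  fake <- fit
  fake$estimates <- tibble::tibble(term = "dG", estimate = 0, std.error = 1)
  ci <- nls_confidence_interval(fake, "dG", 0.95)
  expect_equal(ci$lower, -1.95996, tolerance = 1e-4)
  expect_equal(ci$upper, 1.95996, tolerance = 1e-4)

  # width = 2 z SE at every level; midpoint is the estimate
  for (lvl in c(0.1, 0.5, 0.8, 0.99)) {
    ci <- nls_confidence_interval(fit, "dH", lvl)
    est <- fit$estimates
    se <- est$std.error[est$term == "dH"]
    mid <- est$estimate[est$term == "dH"]
    expect_equal(ci$upper - ci$lower, 2 * qnorm((1 + lvl) / 2) * se,
                 tolerance = 1e-12)
    expect_equal((ci$upper + ci$lower) / 2, mid, tolerance = 1e-12)
  }

  fake$estimates$std.error <- 0
  expect_warning(ci0 <- nls_confidence_interval(fake, "dG", 0.95),
                 "Zero standard error")
  expect_equal(ci0$upper - ci0$lower, 0)
})

test_that("coverage curve handles the all-in and all-out extremes", {
  grid <- seq(0.1, 0.9, by = 0.2)
  base <- tidyr::expand_grid(experiment = 1:10, level = grid)
  all_in <- dplyr::mutate(base, lower = -1, upper = 1)
  cc <- coverage_curve(all_in, reference = 0, n_bootstrap = 50)
  expect_true(all(cc$observed == 1))
  all_out <- dplyr::mutate(base, lower = 2, upper = 3)
  cc0 <- coverage_curve(all_out, reference = 0, n_bootstrap = 50)
  expect_true(all(cc0$observed == 0))
  expect_error(coverage_curve(all_in[0, ], 0),
               class = "itcbayes_invalid_input")
})

test_that("coverage of calibrated Gaussian intervals sits on the diagonal", {
  # null test: normal-theory intervals with exactly correct coverage
  set.seed(33)
  n_exp <- 400
  grid <- seq(0.1, 0.9, by = 0.1)
  est <- rnorm(n_exp)  # estimate of a true value 0 with SE 1
  intervals <- purrr::map(seq_len(n_exp), function(i) {
    tibble::tibble(experiment = i, level = grid,
                   lower = est[i] - qnorm((1 + grid) / 2),
                   upper = est[i] + qnorm((1 + grid) / 2))
  }) |> dplyr::bind_rows()
  cc <- coverage_curve(intervals, reference = 0, n_bootstrap = 100)
  band <- 1.96 * sqrt(grid * (1 - grid) / n_exp)
  expect_true(all(abs(cc$observed - cc$level) < band + 0.02))
})

test_that("KL divergence is zero for identical clouds and asymmetric otherwise", {
  set.seed(34)
  s1 <- tibble::tibble(dG = rnorm(500, -10, 0.1), dH = rnorm(500, -5, 0.2))
  expect_identical(kl_divergence_2d(s1, s1)$value, 0)

  s2 <- tibble::tibble(dG = rnorm(500, -9.5, 0.1), dH = rnorm(500, -5, 0.2))
  kl12 <- kl_divergence_2d(s1, s2, bandwidth = 0.1)$value
  kl21 <- kl_divergence_2d(s2, s1, bandwidth = 0.1)$value
  expect_gt(kl12, 0)
  expect_false(isTRUE(all.equal(kl12, kl21)))
})

test_that("KDE estimate approaches the closed-form Gaussian divergence", {
  set.seed(35)
  n <- 1e4
  mu1 <- c(0, 0); S1 <- diag(c(0.04, 0.04))
  mu2 <- c(0.15, -0.1); S2 <- diag(c(0.06, 0.03))
  s1 <- tibble::tibble(dG = rnorm(n, mu1[1], sqrt(S1[1, 1])),
                       dH = rnorm(n, mu1[2], sqrt(S1[2, 2])))
  s2 <- tibble::tibble(dG = rnorm(n, mu2[1], sqrt(S2[1, 1])),
                       dH = rnorm(n, mu2[2], sqrt(S2[2, 2])))
  truth <- gaussian_kl_2d(mu1, S1, mu2, S2)
  est <- kl_divergence_2d(s1, s2, bandwidth = 0.03)$value
  expect_equal(est, truth, tolerance = 0.10)
})

test_that("KL divergence is bounded below near zero on shared support", {
  set.seed(36)
  s1 <- tibble::tibble(dG = rnorm(2000, -10, 0.1), dH = rnorm(2000, -5, 0.1))
  s2 <- tibble::tibble(dG = rnorm(2000, -10, 0.1), dH = rnorm(2000, -5, 0.1))
  expect_gt(kl_divergence_2d(s1, s2)$value, -1e-6)
})

test_that("KL matrix applies the diagonal sentinel and orders pairs", {
  set.seed(37)
  mk <- function(mu) tibble::tibble(dG = rnorm(300, mu, 0.05),
                                    dH = rnorm(300, -5, 0.05))
  ex <- list(a = mk(-10), b = mk(-10.2), c = mk(-9.8))
  m <- kl_matrix(ex, bandwidth = 0.05)
  expect_equal(diag(m), setNames(rep(0, 3), names(ex)))
  expect_true(all(m[upper.tri(m)] > 0))

  lm <- kl_matrix(ex, bandwidth = 0.05, log = TRUE, diag_sentinel = 1)
  expect_equal(diag(lm), setNames(rep(1, 3), names(ex)))
  expect_equal(lm["a", "b"], log(m["a", "b"]))

  dup <- list(ex$a, ex$a)
  m2 <- kl_matrix(dup, bandwidth = 0.05)
  expect_equal(m2[1, 2], 0)
  expect_error(kl_matrix(ex[1]), class = "itcbayes_invalid_input")
})

test_that("Bayesian posteriors are more mutually consistent than NLS clouds", {
  d <- mg_edta_design()
  spec <- simulation_spec(n_replicates = 4)
  study <- generate_study(spec, seed = 44)
  bayes_clouds <- purrr::map(seq_len(4), function(i) {
    fit <- fit_bayes(study$data[[i]], d,
                     sampler = quick_sampler(1500, 1000, 30000),
                     seed = 600 + i)
    fit$samples[, c("dG", "dH")]
  })
  nls_clouds <- purrr::map(seq_len(4), function(i) {
    set.seed(700 + i)
    draw_nls_samples(fit_nls(study$data[[i]], d), n = 1500)
  })
  kb <- kl_matrix(bayes_clouds, bandwidth = 0.05)
  kn <- kl_matrix(nls_clouds, bandwidth = 0.05)
  expect_lt(stats::median(kb[row(kb) != col(kb)]),
            stats::median(kn[row(kn) != col(kn)]))
})
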