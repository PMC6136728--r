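# Shared fixtures and independent oracles used across the test files.

R_GAS_TEST <- 1.9872e-3

default_design <- function(...) mg_edta_design(...)

true_state <- function(sigma = 1e-6) {
  itc_state(dG = -10, dH = -5, dH0 = 0.5e-6, Ls = 1e-3, R0 = 1e-4,
            sigma = sigma)
}

# Fixed-point oracle for the 1:1 mass-action equilibrium:
# iterate [RL] = Ka (R - [RL]) (L - [RL]) with damping until convergence.
complex_fixed_point <- function(Rtot, Ltot, Ka, tol = 1e-14) {
  if (Rtot == 0 || Ltot == 0) return(0)
  x <- 0
  # Newton iteration on g(x) = Ka (R - x)(L - x) - x = 0; starting from 0,
  # g is convex decreasing on [0, min(R, L)] so the iterates converge to
  # the physically admissible root from below.
  for (i in 1:10000) {
    g <- Ka * (Rtot - x) * (Ltot - x) - x
    gp <- -Ka * (Ltot - x) - Ka * (Rtot - x) - 1
    x_new <- min(max(x - g / gp, 0), min(Rtot, Ltot))
    if (abs(x_new - x) < tol * max(x_new, 1e-300)) return(x_new)
    x <- x_new
  }
  x
}

# Step-by-step mass-balance re-implementation of the injection heats,
# written as an explicit loop with scalar updates (independent of the
# vectorised implementation under test).
model_heats_loop <- function(dG, dH, dH0, Ls, R0, design) {
  Ka <- exp(-dG / (R_GAS_TEST * design$temperature))
  V0 <- design$cell_volume
  d <- 1
  c_prev <- 0
  q <- numeric(length(design$injection_volumes))
  for (n in seq_along(q)) {
    v <- design$injection_volumes[n]
    d <- d * (1 - v / V0)
    Rn <- R0 * d
    Ln <- Ls * (1 - d)
    b <- Rn + Ln + 1 / Ka
    cn <- (b - sqrt(b^2 - 4 * Rn * Ln)) / 2
    q[n] <- V0 * dH * 1e3 * (cn - c_prev * (1 - v / V0)) + dH0
    c_prev <- cn
  }
  q
}

# Brute-force shortest-interval scan over every window of m consecutive
# order statistics.
shortest_interval_bruteforce <- function(x, level) {
  xs <- sort(x)
  n <- length(xs)
  m <- max(2, min(ceiling(level * n), n))
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    if (xs[i + m - 1] - xs[i] < best[2] - best[1])
      best <- c(xs[i], xs[i + m - 1])
  }
  best
}

# Closed-form KL divergence between two bivariate normals.
gaussian_kl_2d <- function(mu1, S1, mu2, S2) {
  S2inv <- solve(S2)
  0.5 * (sum(diag(S2inv %*% S1)) +
           t(mu2 - mu1) %*% S2inv %*% (mu2 - mu1) - 2 +
           log(det(S2) / det(S1)))[1, 1]
}

quick_sampler <- function(n_samples = 1500, thin = 200, tune = 20000) {
  sampler_config(n_samples = n_samples, thin = thin, tune = tune)
}
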