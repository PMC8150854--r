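# Shared fixture builders. Everything is generated in code; seeds are fixed
# per call site.

# generic full-network parameter set with all processes active
full_params <- function(N = 200) {
  model_params(N = N, lambda_R = 0.4, delta_R = 0.3, lambda_A = 0.05,
               delta_A = 1, beta = 1.2, alpha = 2, nu = 1.5,
               chi = 3, eta = 2)
}

# transcritical-figure parameterization: lambda_R = 2 beta, delta_A = 3 alpha/2
transcritical_params <- function(q, alpha = 1, beta = 1.5, nu = 1,
                                 N = 1000) {
  p <- model_params(N = N, lambda_R = 2 * beta, beta = beta,
                    delta_A = 3 * alpha / 2, alpha = alpha, nu = nu)
  p$delta_R <- (1 - q) * beta
  p
}

# Hopf-analysis parameterization: lambda_R = lambda_A = delta_R = 0, no triplets
hopf_params <- function(beta, alpha = 2, delta_A = 1, nu = 1, N = 1000) {
  model_params(N = N, beta = beta, delta_A = delta_A, alpha = alpha,
               nu = nu)
}

random_valid_state <- function(N) {
  system_state(nR = sample.int(N + 1L, 1L) - 1L,
               nA = sample.int(50L, 1L) - 1L,
               nAR = sample.int(30L, 1L) - 1L,
               nARA = sample.int(20L, 1L) - 1L)
}

random_rate_params <- function(N = 100, triplets = TRUE) {
  model_params(N = N,
               lambda_R = runif(1, 0, 2), delta_R = runif(1, 0, 2),
               lambda_A = runif(1, 0, 1), delta_A = runif(1, 0.1, 2),
               beta = runif(1, 0, 2), alpha = runif(1, 0.1, 3),
               nu = runif(1, 0.1, 3),
               chi = if (triplets) runif(1, 0, 3) else 0,
               eta = if (triplets) runif(1, 0.1, 3) else 0)
}

# final cumulative feeding count of one chemostatic replicate
chemostat_count <- function(alpha, nu, T, nA0, nR0, N, seed) {
  fr <- simulate_chemostat("holling2", alpha = alpha, nu = nu, nR0 = nR0,
                           nA0 = nA0, N = N, max_time = T, seed = seed)
  n <- length(fr$cumulative_n)
  if (n) fr$cumulative_n[n] else 0
}

# piecewise-constant trajectory value at requested times
step_interp <- function(times, values, at) {
  idx <- findInterval(at, times)
  idx[idx < 1L] <- 1L
  values[idx]
}
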