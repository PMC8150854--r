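test_that("pure-death dynamics match the closed-form decay", {
  p <- model_params(N = 10, delta_A = 0.8)
  # single run reaches the empty absorbing state
  tr <- simulate_full(p, system_state(nA = 5), max_time = 100, seed = 1)
  expect_true(tr$absorbed)
  expect_identical(unname(tr$states[nrow(tr$states), ]), c(0, 0, 0, 0))

  # ensemble mean of nA(t) vs 5 exp(-delta_A t) at t = 1
  n_rep <- 2000
  at <- 1
  vals <- vapply(seq_len(n_rep), function(i) {
    tri <- simulate_full(p, system_state(nA = 5), max_time = at, seed = 10000 + i)
    step_interp(tri$times, tri$states[, "nA"], at)
  }, numeric(1))
  expected <- 5 * exp(-p$delta_A * at)
  se <- sd(vals) / sqrt(n_rep)
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("the same seed reproduces the identical event sequence", {
  p <- full_params()
  t1 <- simulate_full(p, system_state(nR = 50, nA = 5), max_events = 500,
                      seed = 7)
  t2 <- simulate_full(p, system_state(nR = 50, nA = 5), max_events = 500,
                      seed = 7)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
})

test_that("consecutive SSA states differ by exactly one stoichiometry row", {
  p <- full_params(N = 60)
  tr <- simulate_full(p, system_state(nR = 30, nA = 8), max_events = 400,
                      seed = 3)
  S <- stoichiometry()
  key <- apply(S, 1, paste, collapse = ",")
  steps <- diff(tr$states)
  step_key <- apply(steps, 1, paste, collapse = ",")
  expect_true(all(step_key %in% key))
  expect_true(all(diff(tr$times) > 0))
})

test_that("the consumer-free subsystem fluctuates about N fR+", {
  # lambda_A = 0 and no consumers: resources alone, equilibrium N fR+
  p <- model_params(N = 400, lambda_R = 0.5, delta_R = 0.5, beta = 1)
  pr <- 1 - p$delta_R / p$beta            # q
  lRp <- p$lambda_R / p$beta
  fRp <- 0.5 * (pr - lRp + sqrt((lRp - pr)^2 + 4 * lRp))
  tr <- simulate_full(p, system_state(nR = round(p$N * fRp)),
                      max_time = 300, seed = 11)
  expect_identical(sum(tr$states[, c("nA", "nAR", "nARA")]), 0)
  keep <- tr$times > 30
  tmav <- sum(tr$states[keep, "nR"] * diff(c(tr$times[keep], tr$end_time))) /
    (tr$end_time - tr$times[keep][1])
  expect_lt(abs(tmav - p$N * fRp) / (p$N * fRp), 0.05)
})

test_that("ensemble means approach the mean-field solution as N grows", {
  base <- list(beta = 1, delta_A = 1, alpha = 2.5, nu = 1)
  t_grid <- seq(0.25, 5, by = 0.25)
  sup_err <- vapply(c(100, 1000, 10000), function(N) {
    p <- do.call(model_params, c(list(N = N), base))
    n_rep <- 30
    acc <- matrix(0, length(t_grid), 4)
    for (i in seq_len(n_rep)) {
      tr <- simulate_full(p, system_state(nR = round(0.4 * N),
                                          nA = round(0.1 * N)),
                          max_time = 5, seed = 5000 + i)
      for (k in 1:4)
        acc[, k] <- acc[, k] + step_interp(tr$times, tr$states[, k], t_grid)
    }
    acc <- acc / n_rep
    ode <- integrate_meanfield(p, c(round(0.4 * N), round(0.1 * N), 0, 0),
                               t_span = c(0, t_grid), n_out = NULL)
    max(abs(acc - ode$states[-1, ]) / N)
  }, numeric(1))
  expect_true(all(diff(sup_err) < 0))
})

test_that("chemostatic conservation laws hold at every event", {
  # holling2: nA + nAR = nA0; triplets: nA + nAR + 2 nARA = nA0
  fr <- simulate_chemostat("holling2", alpha = 2, nu = 1, nR0 = 60,
                           nA0 = 25, N = 100, max_events = 2000, seed = 2)
  expect_true(all(fr$nA_path >= 0 & fr$nA_path <= fr$nA0))

  fr3 <- simulate_chemostat("triplets", alpha = 2, nu = 1, chi = 5, eta = 1,
                            nR0 = 60, nA0 = 25, N = 100, max_events = 3000,
                            seed = 2)
  # replay events to reconstruct all three classes
  dA <- c(feed = -1, pair_release = +1, triplet_formation = -1,
          triplet_release = +1)
  dAR <- c(feed = +1, pair_release = -1, triplet_formation = -1,
           triplet_release = +1)
  dARA <- c(feed = 0, pair_release = 0, triplet_formation = +1,
            triplet_release = -1)
  ev <- as.character(fr3$event)
  nA <- fr3$nA0 + cumsum(dA[ev])
  nAR <- cumsum(dAR[ev])
  nARA <- cumsum(dARA[ev])
  expect_identical(unname(nA), fr3$nA_path)
  expect_true(all(nA >= 0 & nAR >= 0 & nARA >= 0))
  expect_true(all(nA + nAR + 2 * nARA == fr3$nA0))
  # cumulative_n counts exactly the feeding events
  expect_equal(unname(as.numeric(cumsum(ev == "feed"))), fr3$cumulative_n)
})

test_that("triplet scheme with chi = 0 reproduces the pair scheme exactly", {
  f1 <- simulate_chemostat("holling2", alpha = 2, nu = 1, nR0 = 300,
                           nA0 = 50, N = 1000, max_events = 800, seed = 5)
  f2 <- simulate_chemostat("triplets", alpha = 2, nu = 1, chi = 0, eta = 1,
                           nR0 = 300, nA0 = 50, N = 1000, max_events = 800,
                           seed = 5)
  expect_identical(f1$event_times, f2$event_times)
  expect_identical(f1$nA_path, f2$nA_path)
  expect_identical(f1$cumulative_n, f2$cumulative_n)
})

test_that("Hill order 1 is identical in law to the pair scheme", {
  f1 <- simulate_chemostat("holling2", alpha = 2.2, nu = 0.8, nR0 = 400,
                           nA0 = 30, N = 1000, max_events = 600, seed = 9)
  f3 <- simulate_chemostat("holling3", alpha = 2.2, nu = 0.8, hill_order = 1,
                           nR0 = 400, nA0 = 30, N = 1000, max_events = 600,
                           seed = 9)
  expect_identical(f1$event_times, f3$event_times)
  expect_identical(f1$cumulative_n, f3$cumulative_n)
  # hill_order > 1 damps theta below half density
  f2 <- simulate_chemostat("holling3", alpha = 2.2, nu = 0.8, hill_order = 2,
                           nR0 = 400, nA0 = 30, N = 1000, max_events = 600,
                           seed = 9)
  expect_equal(f2$theta, 2.2 * 0.4^2)
})

test_that("feeding-rate estimation is consistent and nA0-independent", {
  # zero feeding when alpha = 0 (frozen run still covers the window)
  fr0 <- simulate_chemostat("holling2", alpha = 0, nu = 1, nR0 = 500,
                            nA0 = 20, N = 1000, max_time = 10, seed = 1)
  expect_identical(length(fr0$event_times), 0L)
  est0 <- estimate_feeding_rate(fr0, transient_fraction = 0)
  expect_identical(est0$rate, 0)

  # stationary estimate does not depend on nA0 at fixed theta
  est_a <- estimate_feeding_rate(
    simulate_chemostat("holling2", alpha = 2.5, nu = 1, nR0 = 400, nA0 = 100,
                       N = 1000, max_events = 20000, seed = 21), 0.5)
  est_b <- estimate_feeding_rate(
    simulate_chemostat("holling2", alpha = 2.5, nu = 1, nR0 = 400, nA0 = 200,
                       N = 1000, max_events = 20000, seed = 22), 0.5)
  expect_lt(abs(est_a$rate - est_b$rate),
            3 * sqrt(est_a$se^2 + est_b$se^2))

  # nu >> theta: handling is instantaneous, rate -> theta
  est_f <- estimate_feeding_rate(
    simulate_chemostat("holling2", alpha = 0.5, nu = 60, nR0 = 200, nA0 = 50,
                       N = 1000, max_events = 20000, seed = 23), 0.5)
  theta <- 0.5 * 0.2
  expect_lt(abs(est_f$rate - theta), 3 * est_f$se + 0.002)

  # transient handling: time-based transient and step-based agree in spirit
  fr <- simulate_chemostat("holling2", alpha = 2.5, nu = 1, nR0 = 400,
                           nA0 = 100, N = 1000, max_events = 10000, seed = 30)
  est_t <- estimate_feeding_rate(fr, transient_time = fr$event_times[5000])
  est_s <- estimate_feeding_rate(fr, transient_fraction = 0.5)
  expect_equal(est_t$rate, est_s$rate)
  expect_error(estimate_feeding_rate(fr, transient_time = fr$end_time + 1),
               "post-transient")
})
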