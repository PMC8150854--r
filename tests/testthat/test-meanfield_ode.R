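test_that("mean-field right-hand side matches the rate equations", {
  p <- full_params()
  # empty system: only immigration
  expect_equal(unname(meanfield_rhs(c(0, 0, 0, 0), p)),
               c(p$lambda_R * p$N, p$lambda_A * p$N, 0, 0))

  # consumer-mass sum rule: d(nA + nAR + 2 nARA)/dt =
  # lambda_A N - delta_A nA + nu nAR  (binding conserves mass, release
  # adds the converted resource)
  set.seed(17)
  for (i in 1:20) {
    pi <- random_rate_params(N = 150)
    s <- as.numeric(random_valid_state(pi$N))
    d <- meanfield_rhs(s, pi)
    expect_equal(d[["nA"]] + d[["nAR"]] + 2 * d[["nARA"]],
                 pi$lambda_A * pi$N - pi$delta_A * s[2] + pi$nu * s[3])
  }
})

test_that("analytic equilibria zero the vector field", {
  # with and without triplets, on both branches
  for (chi in c(0, 4)) {
    p <- model_params(N = 500, lambda_R = 0.6, delta_R = 0.2, beta = 1.5,
                      delta_A = 0.8, alpha = 2, nu = 1.2, chi = chi,
                      eta = if (chi > 0) 1.5 else 0)
    for (eq in equilibrium_branches(p)) {
      expect_lt(eq$residual, 1e-9)
    }
  }
  # Fig-1-style parameterization: coexistence branch sits at fR = 3/2
  p1 <- transcritical_params(q = 2.5)
  eb <- equilibrium_branches(p1)
  expect_identical(eb[[2]]$branch_label, "coexistence")
  expect_equal(eb[[2]]$scaled_fR, 3 / 2)
  expect_lt(eb[[2]]$residual, 1e-9)

  # q = 0 with no immigration: the resource-only branch is empty
  p0 <- model_params(N = 100, beta = 1, delta_R = 1, delta_A = 1,
                     alpha = 2, nu = 1)
  expect_equal(equilibrium_branches(p0)[[1]]$scaled_fR, 0)

  expect_error(equilibrium_branches(full_params()), "lambda_A")
})

test_that("the equilibrium cubic factorizes and perturbs continuously", {
  p <- model_params(N = 300, lambda_R = 0.5, delta_R = 0.3, beta = 1.4,
                    delta_A = 0.9, alpha = 1.8, nu = 1)
  # lambda_A = 0: root set contains delta_A' and fR+
  cr <- cubic_roots(p)
  fr <- Re(cr$fR[cr$real])
  dAp <- p$delta_A / p$alpha
  lRp <- p$lambda_R / p$beta
  q <- 1 - p$delta_R / p$beta
  fRp <- 0.5 * (q - lRp + sqrt((lRp - q)^2 + 4 * lRp))
  expect_true(any(abs(fr - dAp) < 1e-10))
  expect_true(any(abs(fr - fRp) < 1e-10))
  # residual of the cubic at each returned real root
  for (f in fr) expect_lt(abs(cubic_residual(p, f)), 1e-10)

  # continuity in lambda_A near 0
  root_near <- function(lambda_A, ref) {
    p$lambda_A <- lambda_A
    fr <- Re(cubic_roots(p)$fR[cubic_roots(p)$real])
    fr[which.min(abs(fr - ref))]
  }
  r0 <- root_near(0, dAp)
  r1 <- root_near(1e-4, r0)
  r2 <- root_near(1e-3, r0)
  expect_lt(abs(r1 - r0), 5e-3)
  expect_lt(abs(r2 - r0), 5e-2)
  expect_lt(abs(r1 - r0), abs(r2 - r0))
})

test_that("integration settles on the stable branch and stays there", {
  # q > q*: generic positive initial conditions reach the coexistence values
  p <- transcritical_params(q = 2.5)
  tr <- integrate_meanfield(p, c(1400, 50, 10, 0), c(0, 400))
  coex <- equilibrium_branches(p)[[2]]$abundances
  expect_equal(unname(tr$states[nrow(tr$states), ]), unname(coex),
               tolerance = 1e-5)
  expect_lt(attr(tr, "terminal_residual"), 1e-8)

  # starting exactly at an equilibrium: drift below 1e-6 over 100 time units
  p2 <- hopf_params(beta = 0.5, alpha = 2)
  eq <- equilibrium_branches(p2)[[2]]$abundances
  tr2 <- integrate_meanfield(p2, eq, c(0, 100))
  expect_lt(max(abs(sweep(tr2$states, 2, eq))) / p2$N, 1e-6)

  # non-negativity is preserved along the flow
  expect_true(all(tr$states > -1e-8))
})

test_that("a limit cycle emerges above the Hopf threshold", {
  # alpha_c = 3.25 for delta_A = nu = 1 (small beta); alpha = 4 oscillates
  p <- hopf_params(beta = 0.05, alpha = 4)
  start <- equilibrium_branches(p)[[2]]$abundances * 1.1 + 1
  tr <- integrate_meanfield(p, start, c(0, 4000), n_out = 20000)
  lc <- detect_limit_cycle(tr)
  expect_true(lc$cycle)
  expect_gt(lc$amplitude, 1e-3 * p$N)

  # well below the threshold the oscillations damp out
  p2 <- hopf_params(beta = 0.05, alpha = 2)
  start2 <- equilibrium_branches(p2)[[2]]$abundances * 1.1 + 1
  tr2 <- integrate_meanfield(p2, start2, c(0, 4000), n_out = 20000)
  expect_false(detect_limit_cycle(tr2)$cycle)
})

test_that("fast pair turnover reduces to Lotka-Volterra", {
  p <- model_params(N = 1000, beta = 1.2, delta_R = 0.2, delta_A = 1,
                    alpha = 2.5, nu = 100)
  lv <- reduce_lotka_volterra(p)
  expect_equal(lv$effective_params$r, 1.0)
  expect_equal(lv$effective_params$K, 1.0 * 1000 / 1.2)
  # reduction equilibrium: nR = N delta_A / alpha
  eqR <- p$N * p$delta_A / p$alpha
  eqP <- lv$effective_params$r * (1 - eqR / lv$effective_params$K) *
    p$N / p$alpha
  expect_equal(unname(lv$rhs(c(eqR, eqP))), c(0, 0), tolerance = 1e-12)

  # 3D trajectory vs 2D reduction within 5% sup-norm (nR, nA)
  tr3 <- integrate_meanfield(p, c(600, 80, 0, 0), c(0, 12), n_out = 600)
  rhs2 <- function(t, y, parms) list(unname(lv$rhs(y)))
  tr2 <- deSolve::ode(c(nR = 600, nP = 80), times = tr3$times, func = rhs2,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  err <- max(abs(tr3$states[, c("nR", "nA")] - tr2[, c("nR", "nP")])) / p$N
  expect_lt(err, 0.05)

  expect_false(reduce_lotka_volterra(
    model_params(N = 10, beta = 0.5, delta_R = 0.6, delta_A = 1, alpha = 1,
                 nu = 1))$effective_params$logistic_growth)
  expect_error(reduce_lotka_volterra(full_params()), "chi")
})

test_that("slow pair turnover reduces to Rosenzweig-MacArthur", {
  eps_list <- c(0.1, 0.03, 0.01)
  dev <- numeric(length(eps_list))
  for (k in seq_along(eps_list)) {
    eps <- eps_list[k]
    # nu and r are the eps-scaled slow rates: nu_tilde = 1, r_tilde = 0.8
    p <- model_params(N = 1000, beta = 0.8 * eps, delta_A = 1, alpha = 2,
                      nu = eps)
    rm <- reduce_rosenzweig_macarthur(p, eps)
    ep <- rm$effective_params
    expect_equal(ep$alpha_bar, 2 * p$alpha * ep$nu_tilde / p$delta_A)
    expect_equal(ep$tauH_bar, 1 / (2 * ep$nu_tilde))
    expect_equal(ep$delta_P, ep$nu_tilde)
    # alpha_bar * tauH_bar = alpha / delta_A independent of nu_tilde
    expect_equal(ep$alpha_bar * ep$tauH_bar, p$alpha / p$delta_A)

    # full 3D dynamics vs reduction, on the slow time grid
    t_slow <- seq(0, 6, length.out = 200)
    tr3 <- integrate_meanfield(p, c(500, 0, 40, 0), t_slow / eps)
    rhs2 <- function(t, y, parms) list(unname(rm$rhs(y)))
    tr2 <- deSolve::ode(c(nR = 500, nP = 40), times = t_slow, func = rhs2,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
    nP3 <- tr3$states[, "nA"] + tr3$states[, "nAR"]
    dev[k] <- max(abs(cbind(tr3$states[, "nR"], nP3) -
                        tr2[, c("nR", "nP")])) / p$N

    # slaving: nA tracks 2 eps nu_tilde nAR / (delta_A + alpha nR / N)
    mid <- tr3$times > 1 / eps
    nA_slaved <- 2 * eps * ep$nu_tilde * tr3$states[mid, "nAR"] /
      (p$delta_A + p$alpha * tr3$states[mid, "nR"] / p$N)
    rel <- abs(tr3$states[mid, "nA"] - nA_slaved) /
      pmax(tr3$states[mid, "nA"], 1)
    expect_lt(stats::median(rel), 5 * eps)
  }
  # reduction error decreases with eps
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 0.05)
})

test_that("interference reduces to a Beddington-DeAngelis-type model", {
  eps <- 0.02
  # interference as a perturbation: the kappa-closed reduction is exact
  # only to O(eps) in the interference flux, so chi is kept moderate
  p <- model_params(N = 1000, beta = 0.8 * eps, delta_A = 1, alpha = 2,
                    nu = eps, chi = 0.05, eta = 2 * eps^2)
  # kappa = 0 keeps the bare interference rate
  bd0 <- reduce_beddington_deangelis(p, eps, kappa = 0)
  expect_equal(bd0$effective_params$chi_bar, p$chi)

  # chi -> 0 recovers the Rosenzweig-MacArthur field
  p_nochi <- model_params(N = 1000, beta = 0.8 * eps, delta_A = 1,
                          alpha = 2, nu = eps)
  bd_nochi <- reduce_beddington_deangelis(
    model_params(N = 1000, beta = 0.8 * eps, delta_A = 1, alpha = 2,
                 nu = eps, chi = 0, eta = 0), eps, kappa = 0)
  rm <- reduce_rosenzweig_macarthur(p_nochi, eps)
  for (s in list(c(300, 20), c(800, 5), c(100, 60))) {
    expect_equal(unname(bd_nochi$rhs(s)), unname(rm$rhs(s)),
                 tolerance = 1e-12)
  }

  # with kappa at the equilibrium pair/triplet ratio the reduction's
  # coexistence equilibrium tracks the 4D system's (nR, nP) within 2%
  kap <- suggest_kappa(p)
  bd <- reduce_beddington_deangelis(p, eps, kappa = kap)
  eq4 <- equilibrium_branches(p)[[2]]$abundances
  target <- c(eq4[["nR"]], eq4[["nAR"]] + eq4[["nARA"]])
  rhs2 <- function(t, y, parms) list(unname(bd$rhs(y)))
  long <- deSolve::ode(c(nR = target[1] * 1.2, nP = target[2] * 0.8),
                       times = c(0, 4000), func = rhs2, parms = NULL,
                       rtol = 1e-10, atol = 1e-10)
  eq2 <- long[nrow(long), c("nR", "nP")]
  expect_lt(max(abs(eq2 - target) / target), 0.02)
})
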