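## Mean-field (deterministic, large-N) layer: the 4D ODE system, its
## equilibrium branches and the cubic for the scaled resource abundance.
## Internally integrations run in scaled per-N coordinates f = n/N for
## conditioning; counts are used at the API boundary.

## primed parameters used throughout the equilibrium algebra
primed <- function(params) {
  list(lambda_Ap = if (params$alpha > 0) params$lambda_A / params$alpha else NA_real_,
       lambda_Rp = if (params$beta > 0) params$lambda_R / params$beta else NA_real_,
       delta_Ap  = if (params$alpha > 0) params$delta_A / params$alpha else NA_real_,
       delta_Rp  = if (params$beta > 0) params$delta_R / params$beta else NA_real_)
}

#' Mean-field right-hand side
#'
#' The deterministic rate equations obtained as the large-`N` limit of the
#' reaction network:
#' \deqn{\dot n_R = \lambda_R(N - n_R) - \delta_R n_R +
#'       (\beta N - \beta n_R - \alpha n_A) n_R / N}
#' \deqn{\dot n_A = \lambda_A N - \delta_A n_A + 2\nu n_{AR} +
#'       \eta n_{ARA} - (\alpha n_R + \chi n_{AR}) n_A / N}
#' \deqn{\dot n_{AR} = \eta n_{ARA} - \nu n_{AR} +
#'       (\alpha n_R - \chi n_{AR}) n_A / N}
#' \deqn{\dot n_{ARA} = \chi n_{AR} n_A / N - \eta n_{ARA}}
#'
#' @param state real 4-vector `(nR, nA, nAR, nARA)` (counts; need not be
#'   integer).
#' @param params a [model_params()] object.
#' @return Named numeric derivative 4-vector.
#' @export
meanfield_rhs <- function(state, params) {
  N <- params$N
  nR <- state[[1L]]; nA <- state[[2L]]
  nAR <- state[[3L]]; nARA <- state[[4L]]
  with(params, {
    d <- c(lambda_R * (N - nR) - delta_R * nR +
             (beta * N - beta * nR - alpha * nA) * nR / N,
           lambda_A * N - delta_A * nA + 2 * nu * nAR + eta * nARA -
             (alpha * nR + chi * nAR) * nA / N,
           eta * nARA - nu * nAR + (alpha * nR - chi * nAR) * nA / N,
           chi * nAR * nA / N - eta * nARA)
    names(d) <- STATE_VARS
    d
  })
}

#' Integrate the mean-field ODE system
#'
#' Adaptive stiff-capable integration (`deSolve::ode`, `lsoda`) of
#' [meanfield_rhs()], carried out in scaled per-`N` coordinates.
#'
#' @param params a [model_params()] object.
#' @param init initial 4-vector (counts).
#' @param t_span either a length-2 interval or a full output time grid.
#' @param rtol,atol solver tolerances (on the scaled variables).
#' @param n_out number of output points when `t_span` is an interval.
#' @return A `trajectory` object (deterministic: `times` is the solver
#'   output grid). Attribute `terminal_residual` holds the scaled RHS norm
#'   at the final state.
#' @export
integrate_meanfield <- function(params, init, t_span, rtol = 1e-10,
                                atol = 1e-12, n_out = 400) {
  if (any(init < 0)) stop("initial state must be non-negative")
  times <- if (length(t_span) == 2L)
    seq(t_span[1L], t_span[2L], length.out = n_out) else t_span
  N <- params$N
  rhs_scaled <- function(t, f, p) list(meanfield_rhs(f * N, params) / N)
  sol <- deSolve::ode(y = setNames(as.numeric(init) / N, STATE_VARS),
                      times = times, func = rhs_scaled, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("mean-field integration failed; solver diagnostics: ",
         paste(attr(sol, "istate"), collapse = " "))
  states <- as.matrix(sol[, STATE_VARS, drop = FALSE]) * N
  res <- max(abs(meanfield_rhs(states[nrow(states), ], params))) / N
  structure(list(times = sol[, "time"], states = states, absorbed = FALSE,
                 end_time = sol[nrow(sol), "time"], seed = NULL,
                 params = params),
            class = "trajectory", terminal_residual = res)
}

#' Equilibrium branches of the mean-field system (no consumer immigration)
#'
#' For `lambda_A = 0` the system has two analytic equilibrium branches, in
#' terms of the scaled resource abundance `fR = nR/N`, the control parameter
#' `q = 1 - delta_R/beta` and the primed rates `lambda_R' = lambda_R/beta`,
#' `delta_A' = delta_A/alpha`:
#' \describe{
#'   \item{resource-only}{`fR+ = (q - lambda_R' +
#'     sqrt((lambda_R' - q)^2 + 4 lambda_R'))/2` with no consumers (the
#'     `fR-` root is always negative and is discarded);}
#'   \item{coexistence}{`fR = delta_A'`, `nA = N (beta/alpha) (q - q*)`,
#'     `nAR = N (beta/nu) delta_A' (q - q*)`, and
#'     `nARA = (chi/eta) nAR nA / N` (from the triplet stationarity
#'     relation), where `q*` is the [transcritical_threshold()].}
#' }
#' Branches with any negative abundance are flagged inadmissible but still
#' returned (they are the formal continuation that exchanges stability at
#' the transcritical point).
#'
#' @param params a [model_params()] object with `lambda_A = 0`, `beta > 0`.
#' @return List of `equilibrium` objects, each with fields `abundances`
#'   (named 4-vector of counts), `branch_label`, `scaled_fR`, `admissible`.
#' @seealso [cubic_roots()] for the general `lambda_A > 0` case.
#' @export
equilibrium_branches <- function(params) {
  if (params$lambda_A != 0)
    stop("equilibrium_branches requires lambda_A = 0; ",
         "use cubic_roots() for lambda_A > 0")
  if (params$beta <= 0) stop("requires beta > 0")
  N <- params$N
  pr <- primed(params)
  q <- 1 - pr$delta_Rp
  lRp <- pr$lambda_Rp
  fRp <- 0.5 * (q - lRp + sqrt((lRp - q)^2 + 4 * lRp))
  out <- list(new_equilibrium(c(N * fRp, 0, 0, 0), "resource_only", params))
  if (params$alpha > 0 && params$nu > 0) {
    dAp <- pr$delta_Ap
    qstar <- transcritical_threshold(params)
    nA <- N * (params$beta / params$alpha) * (q - qstar)
    nAR <- N * (params$beta / params$nu) * dAp * (q - qstar)
    nARA <- if (params$chi > 0) params$chi * nAR * nA / (params$eta * N) else 0
    out <- c(out, list(new_equilibrium(c(N * dAp, nA, nAR, nARA),
                                       "coexistence", params)))
  }
  out
}

new_equilibrium <- function(ab, label, params) {
  ab <- setNames(as.numeric(ab), STATE_VARS)
  structure(list(abundances = ab, branch_label = label,
                 scaled_fR = ab[["nR"]] / params$N,
                 admissible = all(ab >= -1e-12) &&
                   ab[["nR"]] <= params$N * (1 + 1e-12),
                 residual = max(abs(meanfield_rhs(ab, params))) / params$N),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("Equilibrium [", x$branch_label, "] fR =", format(x$scaled_fR),
      if (!x$admissible) "(inadmissible)", "\n")
  print(x$abundances)
  invisible(x)
}

#' Cubic equation for the scaled resource equilibrium
#'
#' With consumer immigration (`lambda_A > 0`) the equilibrium conditions
#' reduce to a cubic in `fR = nR/N`:
#' \deqn{-f_R^3 + (1 - \lambda_R' - \delta_R' + \delta_A') f_R^2 +
#'  [(\alpha/\beta)\lambda_A' + (\delta_R' - 1)\delta_A' +
#'   (\delta_A' + 1)\lambda_R'] f_R - \lambda_R' \delta_A' = 0,}
#' with the primed rates `lambda_A' = lambda_A/alpha`,
#' `lambda_R' = lambda_R/beta`, `delta_A' = delta_A/alpha`,
#' `delta_R' = delta_R/beta`. Roots are found as companion-matrix
#' eigenvalues; roots with `|Im| < 1e-10` are treated as real. A root is
#' admissible when it is real, lies in `[0, 1]`, and implies a non-negative
#' consumer abundance `nA = lambda_A N / (delta_A - alpha fR)`.
#'
#' @param params a [model_params()] object with `alpha, beta > 0`.
#' @return A data frame with columns `fR` (complex roots), `real`,
#'   `admissible` and `nA_implied`.
#' @export
cubic_roots <- function(params) {
  if (params$alpha <= 0 || params$beta <= 0)
    stop("cubic_roots requires alpha > 0 and beta > 0")
  pr <- primed(params)
  c2 <- 1 - pr$lambda_Rp - pr$delta_Rp + pr$delta_Ap
  c1 <- (params$alpha / params$beta) * pr$lambda_Ap +
    (pr$delta_Rp - 1) * pr$delta_Ap + (pr$delta_Ap + 1) * pr$lambda_Rp
  c0 <- -pr$lambda_Rp * pr$delta_Ap
  ## monic form f^3 + a2 f^2 + a1 f + a0 after dividing by -1
  a2 <- -c2; a1 <- -c1; a0 <- -c0
  comp <- rbind(c(-a2, -a1, -a0), c(1, 0, 0), c(0, 1, 0))
  roots <- eigen(comp, only.values = TRUE)$values
  is_real <- abs(Im(roots)) < 1e-10
  fr <- ifelse(is_real, Re(roots), NA_real_)
  nA_impl <- ifelse(is_real & abs(params$delta_A - params$alpha * fr) > 0,
                    params$lambda_A * params$N /
                      (params$delta_A - params$alpha * fr),
                    NA_real_)
  if (params$lambda_A == 0) {
    ## boundary of the immigration-free case: consumers vanish on the
    ## resource-only roots, Eq-(28)-style abundance on the fR = delta_A' root
    dAp <- pr$delta_Ap
    on_coex <- is_real & abs(fr - dAp) < 1e-8
    qstar <- transcritical_threshold(params)
    q <- 1 - pr$delta_Rp
    nA_impl[on_coex] <- params$N * (params$beta / params$alpha) * (q - qstar)
    nA_impl[is_real & !on_coex] <- 0
  }
  data.frame(fR = roots, real = is_real,
             admissible = is_real & Re(roots) >= -1e-12 &
               Re(roots) <= 1 + 1e-12 & !is.na(nA_impl) & nA_impl >= -1e-9,
             nA_implied = nA_impl)
}

## residual of the cubic at a value fR (used in tests)
cubic_residual <- function(params, fR) {
  pr <- primed(params)
  c2 <- 1 - pr$lambda_Rp - pr$delta_Rp + pr$delta_Ap
  c1 <- (params$alpha / params$beta) * pr$lambda_Ap +
    (pr$delta_Rp - 1) * pr$delta_Ap + (pr$delta_Ap + 1) * pr$lambda_Rp
  c0 <- -pr$lambda_Rp * pr$delta_Ap
  -fR^3 + c2 * fR^2 + c1 * fR + c0
}

#' Detect a limit cycle in a trajectory
#'
#' Discards the first half of the trajectory, locates successive local
#' maxima of `nR(t)`, and declares a limit cycle if the last maxima agree
#' to within 1% relative difference while the oscillation amplitude exceeds
#' `1e-3 * N` (so slowly damped foci are not misclassified).
#'
#' @param traj a `trajectory` (typically from [integrate_meanfield()]).
#' @param params the [model_params()] used (defaults to `traj$params`).
#' @return List with `cycle` (logical), `amplitude`, `peaks` (times of the
#'   detected maxima).
#' @export
detect_limit_cycle <- function(traj, params = traj$params) {
  keep <- traj$times >= traj$times[1L] +
    0.5 * (traj$end_time - traj$times[1L])
  x <- traj$states[keep, "nR"]
  tt <- traj$times[keep]
  if (length(x) < 5L) return(list(cycle = FALSE, amplitude = 0,
                                  peaks = numeric()))
  i <- which(diff(sign(diff(x))) < 0) + 1L
  amp <- max(x) - min(x)
  if (length(i) < 3L || amp <= 1e-3 * params$N)
    return(list(cycle = FALSE, amplitude = amp, peaks = tt[i]))
  pk <- x[i]
  last <- utils::tail(pk, 3L)
  rel <- abs(diff(last)) / pmax(abs(last[-1L]), .Machine$double.eps)
  list(cycle = all(rel < 0.01), amplitude = amp, peaks = tt[i])
}
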