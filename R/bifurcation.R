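#' Transcritical threshold of the control parameter q
#'
#' With no consumer immigration the resource-only and coexistence
#' equilibrium branches cross, exchanging stability, at
#' \deqn{q^\star = \delta_A/\alpha + \lambda_R/\beta -
#'       \alpha\lambda_R/(\beta\delta_A)
#'     = \delta_A' + \lambda_R' - \lambda_R'/\delta_A',}
#' where `q = 1 - delta_R/beta` is the ratio of the intrinsic resource
#' growth rate to the birth rate.
#'
#' @param params a [model_params()] with `lambda_A = 0` and
#'   `alpha, beta, delta_A > 0`.
#' @return The threshold `q*`.
#' @export
transcritical_threshold <- function(params) {
  if (params$lambda_A != 0) stop("requires lambda_A = 0")
  if (params$delta_A <= 0) stop("requires delta_A > 0")
  if (params$alpha <= 0 || params$beta <= 0)
    stop("requires alpha > 0 and beta > 0")
  pr <- primed(params)
  pr$delta_Ap + pr$lambda_Rp - pr$lambda_Rp / pr$delta_Ap
}

#' Jacobian of the mean-field system
#'
#' Analytic partial derivatives of [meanfield_rhs()] at a point. When the
#' triplet reactions are absent (`chi = eta = 0`) and `drop_triplets =
#' TRUE`, the matrix is reduced to the active 3x3 block in
#' `(nR, nA, nAR)`.
#'
#' @param params a [model_params()] object.
#' @param point an `equilibrium` (from [equilibrium_branches()]) or a
#'   numeric 4-vector of counts.
#' @param drop_triplets drop the decoupled `nARA` row/column when the
#'   triplet rates are zero (default).
#' @return A real 4x4 (or 3x3) matrix.
#' @export
meanfield_jacobian <- function(params, point, drop_triplets = TRUE) {
  x <- if (inherits(point, "equilibrium")) point$abundances else
    setNames(as.numeric(point), STATE_VARS)
  N <- params$N
  nR <- x[[1L]]; nA <- x[[2L]]; nAR <- x[[3L]]; nARA <- x[[4L]]
  J <- with(params, rbind(
    c(-lambda_R - delta_R + beta - 2 * beta * nR / N - alpha * nA / N,
      -alpha * nR / N, 0, 0),
    c(-alpha * nA / N,
      -delta_A - (alpha * nR + chi * nAR) / N,
      2 * nu - chi * nA / N, eta),
    c(alpha * nA / N,
      (alpha * nR - chi * nAR) / N,
      -nu - chi * nA / N, eta),
    c(0, chi * nAR / N, chi * nA / N, -eta)))
  dimnames(J) <- list(STATE_VARS, STATE_VARS)
  if (drop_triplets && params$chi == 0 && params$eta == 0)
    J <- J[1:3, 1:3]
  J
}

#' Hopf bifurcation threshold in the small-beta limit
#'
#' For `lambda_R = lambda_A = delta_R = 0` and no triplets, the coexistence
#' equilibrium undergoes a Hopf bifurcation (in the limit of small resource
#' birth rate `beta`) at the attack rate
#' \deqn{\alpha_c = 3\delta_A + \frac{\nu^2}{2(\delta_A + \nu)}.}
#' Note `alpha_c > delta_A` always, so the bifurcating eigenvalue pair is
#' complex.
#'
#' @param delta_A consumer death rate, `> 0`.
#' @param nu pair degradation rate, `> 0`.
#' @return The critical attack rate `alpha_c`.
#' @export
hopf_threshold_smallbeta <- function(delta_A, nu) {
  if (delta_A <= 0 || nu <= 0) stop("delta_A and nu must be > 0")
  3 * delta_A + nu^2 / (2 * (delta_A + nu))
}

#' Small-beta eigenvalue series at the coexistence equilibrium
#'
#' Series expansion (in the resource birth rate `beta`) of the three
#' eigenvalues of the Jacobian at the coexistence equilibrium for
#' `lambda_R = lambda_A = delta_R = 0`, no triplets, `alpha > delta_A`:
#' a complex-conjugate pair
#' \deqn{\lambda_\pm = -\beta\,\frac{\delta_A(\nu^2 +
#'   2(3\delta_A - \alpha)(\delta_A + \nu))}{2\alpha(2\delta_A + \nu)^2}
#'   \pm i\sqrt{\beta\,\frac{\delta_A\nu(\alpha - \delta_A)}
#'   {\alpha(2\delta_A + \nu)}} + O(\beta^{3/2})}
#' and a real eigenvalue
#' \deqn{\lambda_3 = -2\delta_A - \nu -
#'   2\beta\,\frac{\delta_A(\alpha - \delta_A)(\delta_A + \nu)}
#'   {\alpha(2\delta_A + \nu)^2} + O(\beta^{3/2}).}
#' The real part of the pair vanishes at `alpha = alpha_c`
#' ([hopf_threshold_smallbeta()]).
#'
#' @param alpha attack rate, must exceed `delta_A`.
#' @param delta_A,nu consumer death and pair degradation rates, `> 0`.
#' @param beta small resource birth rate, `>= 0`.
#' @return Complex vector `(pair_plus, pair_minus, third)`.
#' @export
eigenvalue_series_smallbeta <- function(alpha, delta_A, nu, beta) {
  if (delta_A <= 0 || nu <= 0) stop("delta_A and nu must be > 0")
  if (alpha <= delta_A)
    stop("series requires alpha > delta_A (complex pair regime)")
  if (beta < 0) stop("beta must be >= 0")
  re <- -beta * delta_A * (nu^2 + 2 * (3 * delta_A - alpha) *
                             (delta_A + nu)) /
    (2 * alpha * (2 * delta_A + nu)^2)
  im <- sqrt(beta * delta_A * nu * (alpha - delta_A) /
               (alpha * (2 * delta_A + nu)))
  third <- -2 * delta_A - nu -
    2 * beta * delta_A * (alpha - delta_A) * (delta_A + nu) /
    (alpha * (2 * delta_A + nu)^2)
  c(complex(real = re, imaginary = im),
    complex(real = re, imaginary = -im),
    complex(real = third, imaginary = 0))
}

#' Stability report at an equilibrium
#'
#' Computes the Jacobian eigenvalues at an equilibrium and labels the
#' regime: `resource_only_stable` (resource-only branch attracts),
#' `coexistence_stable_node` (all eigenvalues real negative),
#' `coexistence_damped_oscillations` (complex pair with negative real
#' part), or `limit_cycle` (positive real part; confirmed by integration
#' when `confirm_cycle = TRUE`). Real parts with `|Re| < tol` are treated
#' as marginal (regime reported with a `marginal` flag).
#'
#' @param params a [model_params()] with `lambda_A = 0`.
#' @param confirm_cycle integrate 500 time units and run
#'   [detect_limit_cycle()] before labelling `limit_cycle`.
#' @param tol zero-eigenvalue tolerance.
#' @return A `stability_report`: list with `equilibrium`, `eigenvalues`,
#'   `regime`, `marginal`, `control_values` (`q`, `alpha`, `beta`).
#' @export
stability_report <- function(params, confirm_cycle = FALSE, tol = 1e-8) {
  eqs <- equilibrium_branches(params)
  res_only <- eqs[[1L]]
  coex <- if (length(eqs) > 1L) eqs[[2L]] else NULL
  ev_res <- eigen(meanfield_jacobian(params, res_only),
                  only.values = TRUE)$values
  if (max(Re(ev_res)) < tol || is.null(coex)) {
    return(structure(list(equilibrium = res_only, eigenvalues = ev_res,
                          regime = "resource_only_stable",
                          marginal = max(abs(Re(ev_res))) < tol,
                          control_values = control_values(params)),
                     class = "stability_report"))
  }
  ev <- eigen(meanfield_jacobian(params, coex), only.values = TRUE)$values
  max_re <- max(Re(ev))
  oscillatory <- any(abs(Im(ev)) > tol)
  regime <- if (max_re < -tol) {
    if (oscillatory) "coexistence_damped_oscillations"
    else "coexistence_stable_node"
  } else "limit_cycle"
  if (regime == "limit_cycle" && confirm_cycle) {
    start <- pmax(coex$abundances * 1.05 + 1e-3 * params$N, 0)
    start[1L] <- min(start[1L], params$N)
    ## the unstable focus grows like exp(max_re * t): the confirmation
    ## window must cover both that growth and several cycle periods
    t_conf <- min(2e4, max(500, 15 / max(max_re, 1e-4)))
    tr <- integrate_meanfield(params, start, c(0, t_conf), n_out = 8000)
    if (!detect_limit_cycle(tr)$cycle)
      regime <- "coexistence_damped_oscillations"
  }
  structure(list(equilibrium = coex, eigenvalues = ev, regime = regime,
                 marginal = abs(max_re) < tol,
                 control_values = control_values(params)),
            class = "stability_report")
}

control_values <- function(params) {
  c(q = if (params$beta > 0) 1 - params$delta_R / params$beta else NA_real_,
    alpha = params$alpha, beta = params$beta)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Regime:", x$regime, if (x$marginal) "(marginal)", "\n")
  cat("max Re(lambda) =", format(max(Re(x$eigenvalues))), "\n")
  invisible(x)
}

#' Classify stability regimes over an (alpha, beta) grid
#'
#' Evaluates [stability_report()] on every point of an `alpha` x `beta`
#' grid (the phase-diagram construction for
#' `lambda_R = lambda_A = delta_R = 0`; general parameters are allowed).
#'
#' @param params a baseline [model_params()]; `alpha` and `beta` are
#'   overridden at each grid point.
#' @param alpha,beta numeric vectors of grid values.
#' @param confirm_cycle confirm `limit_cycle` labels by integration (slower).
#' @return A data frame with columns `alpha`, `beta`, `regime`,
#'   `max_re_lambda`, `q`.
#' @export
classify_regime <- function(params, alpha, beta, confirm_cycle = FALSE) {
  grid <- expand.grid(alpha = alpha, beta = beta, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$alpha <- grid$alpha[i]; p$beta <- grid$beta[i]
    rep_i <- stability_report(p, confirm_cycle = confirm_cycle)
    data.frame(alpha = p$alpha, beta = p$beta, regime = rep_i$regime,
               max_re_lambda = max(Re(rep_i$eigenvalues)),
               q = unname(control_values(p)["q"]))
  })
  do.call(rbind, rows)
}

#' Numerically locate the transcritical point along q
#'
#' Finds the sign change of the leading Jacobian eigenvalue of the
#' resource-only equilibrium as the control parameter `q = 1 -
#' delta_R/beta` varies (by bisection on `delta_R` at fixed `beta`), and
#' returns the detected `q`. Used to cross-check
#' [transcritical_threshold()].
#'
#' @param params a [model_params()] with `lambda_A = 0`; `delta_R` is the
#'   swept parameter.
#' @param q_range interval of `q` to search.
#' @param tol bisection tolerance on `q`.
#' @return The numerically detected threshold `q`.
#' @export
find_transcritical_q <- function(params, q_range = c(-1, 2), tol = 1e-9) {
  lead_re <- function(q) {
    p <- params
    p$delta_R <- (1 - q) * p$beta
    max(Re(eigen(meanfield_jacobian(p, equilibrium_branches(p)[[1L]]),
                 only.values = TRUE)$values))
  }
  uniroot(lead_re, interval = q_range, tol = tol)$root
}

#' Numerically locate the Hopf point along alpha
#'
#' Finds, by root bracketing on the maximum real part of the coexistence
#' Jacobian eigenvalues, the attack rate at which the leading eigenvalue
#' pair crosses the imaginary axis (for `lambda_R = lambda_A = delta_R =
#' 0`, no triplets, at finite `beta`). Converges to
#' [hopf_threshold_smallbeta()] as `beta -> 0`.
#'
#' @param params a [model_params()] (the `alpha` slot is the swept
#'   parameter; `beta` is used as given).
#' @param alpha_range search interval; must bracket the sign change.
#' @param tol tolerance on `alpha`.
#' @return The numerically detected critical attack rate.
#' @export
find_hopf_alpha <- function(params, alpha_range, tol = 1e-10) {
  max_re <- function(a) {
    p <- params
    p$alpha <- a
    coex <- equilibrium_branches(p)[[2L]]
    max(Re(eigen(meanfield_jacobian(p, coex), only.values = TRUE)$values))
  }
  uniroot(max_re, interval = alpha_range, tol = tol)$root
}
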