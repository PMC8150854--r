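## Exact distribution of cumulative feeding events under chemostatic
## Holling-II conditions. The joint generating function
## G(x,y;t) = sum_{n,nA} P(n,nA;t) x^n y^nA of the feeding/release process
## (feed: rate theta*nA, n+1, nA-1; release: rate nu*(nA0-nA), nA+1)
## satisfies the transport PDE
##   dG/dt = nu nA0 (y-1) G + [theta (x-y) - nu y (y-1)] dG/dy,
## solved by the method of characteristics. The characteristic quadratic in
## y is -nu y^2 + (nu-theta) y + theta x = 0, with roots y0+-(x) and gap
## Delta(x) = nu (y0+ - y0-) = sqrt((nu-theta)^2 + 4 nu theta x).

#' Probability generating function solution of the feeding process
#'
#' Precomputes the characteristic structure of the chemostatic feeding
#' PGF. The returned object carries `characteristic_roots(x)` (the two
#' roots `y0-(x)`, `y0+(x)` of the characteristic quadratic) and `gap(x)`
#' (`Delta(x)`), plus the rates.
#'
#' @param theta composite encounter rate `alpha * nR0/N`, `>= 0`.
#' @param nu pair degradation rate, `> 0`.
#' @param nA0 total (conserved) consumer count, integer `>= 1`.
#' @return A `pgf_solution` object.
#' @seealso [pgf_full()], [marginal_pmf()]
#' @export
pgf_solution <- function(theta, nu, nA0) {
  if (nu <= 0) stop("nu must be > 0")
  if (theta < 0) stop("theta must be >= 0")
  if (nA0 < 1 || nA0 != round(nA0)) stop("nA0 must be an integer >= 1")
  gap <- function(x) sqrt(as.complex((nu - theta)^2 + 4 * nu * theta * x))
  roots <- function(x) {
    d <- gap(x)
    list(minus = ((nu - theta) - d) / (2 * nu),
         plus = ((nu - theta) + d) / (2 * nu))
  }
  structure(list(theta = theta, nu = nu, nA0 = nA0,
                 characteristic_roots = roots, gap = gap),
            class = "pgf_solution")
}

#' @export
print.pgf_solution <- function(x, ...) {
  cat("Feeding-process PGF: theta =", x$theta, " nu =", x$nu,
      " nA0 =", x$nA0, "\n")
  invisible(x)
}

#' Evaluate the joint feeding-process PGF
#'
#' Evaluates `G(x, y; t)` in the singularity-free form
#' \deqn{G = e^{\nu n_{A0} (y_0^+ - 1) t}
#'   \left[\frac{\nu}{\Delta}\left(y_0^+ (y - y_0^-) -
#'   y_0^- e^{-\Delta t} (y - y_0^+)\right)\right]^{n_{A0}},}
#' which is symmetric under exchange of the two characteristic roots
#' (hence single-valued in `x`), satisfies `G(x, y; 0) = y^{nA0}` and the
#' normalization `G(1, 1; t) = 1`. The degenerate case `Delta -> 0` (root
#' coincidence) is handled by the analytic confluent limit
#' `G = e^{\nu n_{A0}(y^*-1)t} [y^*(1 + \nu t (y - y^*)) + (y - y^*)]^{nA0}`
#' with `y^* = (\nu-\theta)/(2\nu)`, not by division by zero.
#'
#' @param x,y complex arguments (vectorized over `x`), `|x|, |y| <= 1` for
#'   probabilistic use (evaluation elsewhere is allowed).
#' @param t time, `>= 0`.
#' @param solution a [pgf_solution()].
#' @return Complex value(s) of `G`.
#' @export
pgf_full <- function(x, y, t, solution) {
  s <- solution
  x <- as.complex(x); y <- as.complex(y)
  d <- s$gap(x)
  degen <- abs(d) < 1e-9 * (s$nu + s$theta + 1)
  out <- vector("complex", length(x))
  if (any(!degen)) {
    xd <- x[!degen]; dd <- d[!degen]
    yp <- ((s$nu - s$theta) + dd) / (2 * s$nu)
    ym <- ((s$nu - s$theta) - dd) / (2 * s$nu)
    E <- exp(-dd * t)
    core <- (yp * (y - ym) - ym * E * (y - yp)) * s$nu / dd
    out[!degen] <- exp(s$nu * s$nA0 * (yp - 1) * t) * core^s$nA0
  }
  if (any(degen)) {
    ystar <- (s$nu - s$theta) / (2 * s$nu)
    core <- ystar * (1 + s$nu * t * (y - ystar)) + (y - ystar)
    out[degen] <- exp(s$nu * s$nA0 * (ystar - 1) * t) * core^s$nA0
  }
  out
}

#' Marginal probability mass function of cumulative feeding events
#'
#' The distribution `P(n; t)` of the number of feeding events accumulated
#' by `nA0` consumers over `[0, t]`, regardless of how many consumers are
#' free: the coefficients of `x^n` in `G(x, 1; t)`. Extraction evaluates
#' the PGF at `M >= 4 * n_max` points on a circle of radius `radius < 1`
#' and inverts by FFT.
#'
#' The default radius grows toward 1 with `n_max`
#' (`exp(-1.5/(n_max+1))`, floored at 0.7): since `|G| <= 1` on the closed
#' unit disk, this keeps the `radius^-n` roundoff amplification of the
#' highest-order coefficients at the `exp(1.5)` scale, so extraction stays
#' at machine precision for any `n_max` that covers the distribution. A
#' small fixed radius is accurate only for low orders.
#'
#' @param t elapsed time, `> 0` (t = 0 returns the point mass at 0).
#' @param theta,nu,nA0 process parameters as in [pgf_solution()].
#' @param n_max largest event count retained, `>= 1`.
#' @param radius extraction radius in `(0, 1)`; `NULL` (default) picks the
#'   adaptive radius described above.
#' @param tol negative coefficients below `-tol` (and below the estimated
#'   FFT roundoff scale) raise a precision error suggesting a smaller
#'   radius; negative values within roundoff are clamped to 0.
#' @return A `feeding_pmf`: list with `t`, `probabilities` (vector over
#'   `n = 0..n_max`), `truncation_mass` (`1 - sum`).
#' @export
marginal_pmf <- function(t, theta, nu, nA0, n_max, radius = NULL,
                         tol = 1e-12) {
  if (t < 0) stop("t must be >= 0")
  if (n_max < 1 || n_max != round(n_max)) stop("n_max must be integer >= 1")
  if (is.null(radius)) radius <- max(0.7, exp(-1.5 / (n_max + 1)))
  if (radius <= 0 || radius >= 1) stop("radius must be in (0, 1)")
  if (t == 0 || theta == 0) {
    p <- c(1, rep(0, n_max))
    return(new_feeding_pmf(t, p))
  }
  s <- pgf_solution(theta, nu, nA0)
  M <- max(64L, 2L^ceiling(log2(4 * (n_max + 1L))))
  xk <- radius * exp(2i * pi * (seq_len(M) - 1L) / M)
  gk <- pgf_full(xk, 1 + 0i, t, s)
  coef <- Re(stats::fft(gk, inverse = FALSE)) / M / radius^(0:(M - 1L))
  p <- coef[seq_len(n_max + 1L)]
  ## roundoff floor of the inverse DFT, propagated through the 1/radius^n
  ## rescaling: negatives within this are numerical zeros
  fft_err <- 64 * .Machine$double.eps * max(abs(gk)) /
    radius^(0:n_max)
  bad <- p < -pmax(tol, fft_err)
  if (any(bad))
    stop("coefficient extraction lost precision (negative probability ",
         format(min(p)), "); reduce radius or n_max")
  p[p < 0] <- 0
  new_feeding_pmf(t, p)
}

new_feeding_pmf <- function(t, p) {
  structure(list(t = t, probabilities = p,
                 truncation_mass = max(0, 1 - sum(p))),
            class = "feeding_pmf")
}

#' @export
print.feeding_pmf <- function(x, ...) {
  n <- seq_along(x$probabilities) - 1L
  cat("Feeding-event PMF at t =", x$t, ": support 0..", max(n),
      " mean =", format(sum(n * x$probabilities)),
      " truncated mass =", format(x$truncation_mass), "\n")
  invisible(x)
}

#' @export
as.data.frame.feeding_pmf <- function(x, ...) {
  data.frame(n = seq_along(x$probabilities) - 1L,
             probability = x$probabilities)
}

#' Truncated master-equation oracle for the feeding distribution
#'
#' Independent route to `P(n; t)`: builds the exact finite Markov
#' generator over states `(n, nA)` with `0 <= n <= n_max`,
#' `0 <= nA <= nA0` (feeding events beyond `n_max` flow into an absorbing
#' overflow state whose mass is reported as `truncation_mass`), propagates
#' the initial distribution (all consumers free, no events) by matrix
#' exponential (or stiff ODE integration for large state spaces), and
#' marginalizes over `nA`. Used to validate [marginal_pmf()]; refuses
#' state spaces above `1e5` states.
#'
#' @inheritParams marginal_pmf
#' @param method `"expm"` (exact matrix exponential, default for up to
#'   4000 states), `"ode"`, or `"auto"`.
#' @return A `feeding_pmf`.
#' @export
cme_oracle_pmf <- function(t, theta, nu, nA0, n_max,
                           method = c("auto", "expm", "ode")) {
  method <- match.arg(method)
  if (nu <= 0 || theta < 0) stop("need nu > 0, theta >= 0")
  nstate <- (n_max + 1L) * (nA0 + 1L)
  if (nstate > 1e5)
    stop("state space too large: ", nstate, " states (limit 1e5)")
  if (method == "auto") method <- if (nstate <= 4000) "expm" else "ode"
  idx <- function(n, nA) n * (nA0 + 1L) + nA + 1L
  ## transitions within the truncated lattice
  n_all <- rep(0:n_max, each = nA0 + 1L)
  nA_all <- rep(0:nA0, times = n_max + 1L)
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  ## feed: (n, nA) -> (n+1, nA-1), rate theta * nA
  f <- nA_all > 0
  from <- c(from, idx(n_all[f], nA_all[f]))
  over <- n_all[f] == n_max
  dest <- ifelse(over, nstate + 1L, idx(n_all[f] + 1L, nA_all[f] - 1L))
  to <- c(to, dest)
  rate <- c(rate, theta * nA_all[f])
  ## release: (n, nA) -> (n, nA+1), rate nu * (nA0 - nA)
  g <- nA_all < nA0
  from <- c(from, idx(n_all[g], nA_all[g]))
  to <- c(to, idx(n_all[g], nA_all[g] + 1L))
  rate <- c(rate, nu * (nA0 - nA_all[g]))
  ntot <- nstate + 1L  # + overflow
  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate,
                            dims = c(ntot, ntot))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  p0 <- numeric(ntot)
  p0[idx(0L, nA0)] <- 1
  pt <- if (method == "expm") {
    as.numeric(p0 %*% Matrix::expm(Q * t))
  } else {
    Qt <- Matrix::t(Q)
    fun <- function(tt, p, parms) list(as.numeric(Qt %*% p))
    sol <- deSolve::ode(y = p0, times = c(0, t), func = fun, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-14)
    as.numeric(sol[2L, -1L])
  }
  P <- rowsum(pt[seq_len(nstate)],
              group = rep(0:n_max, each = nA0 + 1L))[, 1L]
  P[P < 0] <- 0
  new_feeding_pmf(t, unname(P))
}

#' Exact log-likelihood of an observed feeding count
#'
#' `log P(n_obs; T)` under the chemostatic Holling-II feeding process with
#' `theta = alpha * nR0 / N`, computed from [marginal_pmf()]. The
#' likelihood depends on `alpha` and `nR0/N` only through their product
#' `theta`. Vectorized over `n_obs` (replicate experiments are
#' independent: sum the results).
#'
#' @param n_obs observed cumulative feeding count(s), `>= 0`.
#' @param T observation time, `> 0`.
#' @param alpha,nu process rates (`nu > 0`).
#' @param nR0,nA0,N chemostatic condition.
#' @param n_max truncation (defaults to a generous margin above
#'   `max(n_obs)`).
#' @return Log-probability vector, one entry per `n_obs`.
#' @export
feeding_loglik <- function(n_obs, T, alpha, nu, nR0, nA0, N,
                           n_max = NULL) {
  if (any(n_obs < 0) || any(n_obs != round(n_obs)))
    stop("n_obs must be non-negative integers")
  if (T <= 0) stop("T must be > 0")
  theta <- alpha * nR0 / N
  if (is.null(n_max)) {
    mean_n <- nA0 * T * mean_rate_transient(max(theta, 1e-12), nu, T)
    n_max <- max(max(n_obs) + 10L, ceiling(mean_n + 12 * sqrt(mean_n + 1)))
  }
  pmf <- marginal_pmf(T, theta, nu, nA0, n_max)
  p <- pmf$probabilities[n_obs + 1L]
  log(pmax(p, 1e-300))
}

#' Maximum-likelihood fit of feeding-experiment counts
#'
#' Fits the chemostatic Holling-II feeding model to replicate cumulative
#' feeding counts by maximizing the exact likelihood over
#' `(log theta, log nu)`, then reports `alpha = theta * N / nR0`. Profile
#' log-likelihood confidence intervals use the chi-square(1) cutoff.
#'
#' @param counts integer vector of observed counts (one per replicate).
#' @param T common observation time.
#' @param nA0,nR0,N chemostatic condition.
#' @param conf confidence level for the profile intervals.
#' @param start optional named vector `c(alpha =, nu =)` of starting
#'   values.
#' @return List with `alpha`, `nu`, `theta`, `loglik`, `ci_alpha`,
#'   `ci_nu` (each a length-2 vector), `convergence`.
#' @export
fit_feeding_mle <- function(counts, T, nA0, nR0, N, conf = 0.95,
                            start = NULL) {
  if (length(counts) < 2L) stop("need at least two replicate counts")
  n_max <- max(counts) + max(20L, ceiling(3 * sqrt(max(counts) + 1)))
  nll <- function(lpar) {
    th <- exp(lpar[1L]); nu <- exp(lpar[2L])
    pmf <- try(marginal_pmf(T, th, nu, nA0, n_max), silent = TRUE)
    if (inherits(pmf, "try-error")) return(1e10)
    -sum(log(pmax(pmf$probabilities[counts + 1L], 1e-300)))
  }
  ## moment-flavoured start: stationary rate mean(counts)/(T nA0), split
  ## between encounter and handling
  if (is.null(start)) {
    rbar <- max(mean(counts) / (T * nA0), 1e-6)
    start <- c(alpha = 2 * rbar * N / nR0, nu = max(2 * rbar, 0.5))
  }
  lp0 <- log(c(start[["alpha"]] * nR0 / N, start[["nu"]]))
  fit <- optim(lp0, nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  th_hat <- exp(fit$par[1L]); nu_hat <- exp(fit$par[2L])
  ll_max <- -fit$value
  cut <- qchisq(conf, df = 1) / 2
  profile_ci <- function(which) {
    prof <- function(lv) {
      inner <- function(lw) {
        par <- if (which == 1L) c(lv, lw) else c(lw, lv)
        nll(par)
      }
      o <- optimize(inner, interval = log(c(1e-3, 1e3)) +
                      fit$par[3L - which], tol = 1e-9)
      -o$objective
    }
    hat <- fit$par[which]
    ## guard against the inner optimizer undershooting the joint maximum
    ll_ref <- max(ll_max, prof(hat))
    pl <- function(lv) prof(lv) - (ll_ref - cut)
    lo <- tryCatch({
      a <- hat
      while (pl(a) > 0 && a > hat - 12) a <- a - 0.5
      if (pl(a) > 0) -Inf else uniroot(pl, c(a, min(a + 0.5, hat)),
                                       tol = 1e-6)$root
    }, error = function(e) -Inf)
    hi <- tryCatch({
      b <- hat
      while (pl(b) > 0 && b < hat + 12) b <- b + 0.5
      if (pl(b) > 0) Inf else uniroot(pl, c(max(b - 0.5, hat), b),
                                      tol = 1e-6)$root
    }, error = function(e) Inf)
    exp(c(lo, hi))
  }
  ci_th <- profile_ci(1L)
  ci_nu <- profile_ci(2L)
  list(alpha = th_hat * N / nR0, nu = nu_hat, theta = th_hat,
       loglik = ll_max,
       ci_alpha = ci_th * N / nR0, ci_nu = ci_nu,
       convergence = fit$convergence)
}
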