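#' Chemostatic condition record
#'
#' Bundles the fixed resource count `nR0`, total consumer count `nA0` and
#' system size `N` of a chemostatic feeding setting, together with the
#' composite per-free-consumer encounter rate
#' `theta = alpha * (nR0/N)^hill_order` (Hill order 1 gives the plain
#' `alpha * nR0 / N`). All closed-form responses are written in terms of
#' `theta`, computed here once, so the density convention (`nR0/N`, not
#' `nR0`) cannot drift between formulas.
#'
#' @param nR0 fixed resource count, `0 <= nR0 <= N`.
#' @param nA0 fixed total consumer count, `>= 1`.
#' @param N system size.
#' @param alpha encounter rate (time^-1).
#' @param hill_order integer Hill order `>= 1`.
#' @return A `chemostat_condition` list with `nR0`, `nA0`, `N`, `alpha`,
#'   `hill_order`, `theta` and `fA0 = nA0/N`.
#' @export
chemostat_condition <- function(nR0, nA0, N, alpha, hill_order = 1) {
  if (nR0 < 0 || nR0 > N) stop("need 0 <= nR0 <= N")
  if (nA0 < 1) stop("need nA0 >= 1")
  if (alpha < 0) stop("need alpha >= 0")
  if (hill_order < 1 || hill_order != round(hill_order))
    stop("hill_order must be an integer >= 1")
  structure(list(nR0 = nR0, nA0 = nA0, N = N, alpha = alpha,
                 hill_order = hill_order,
                 theta = alpha * (nR0 / N)^hill_order,
                 fA0 = nA0 / N),
            class = "chemostat_condition")
}

#' Transient mean per-capita feeding rate
#'
#' Mean feeding rate per consumer over a finite observation window `[0, T]`
#' under chemostatic Holling-II conditions, starting with all consumers
#' free:
#' \deqn{\langle f \rangle_T = \frac{\theta\nu}{\nu + \theta} +
#'   \frac{\theta^2 (1 - e^{-(\theta+\nu)T})}{T(\nu + \theta)^2}.}
#' It decreases monotonically from `theta` at `T -> 0+` (all consumers
#' free and feeding at the full encounter rate) to the stationary Holling
#' type II value `theta nu / (nu + theta)` as `T -> Inf`.
#'
#' @param theta composite encounter rate `alpha * nR0 / N` (time^-1).
#' @param nu pair degradation rate, `> 0`.
#' @param T observation time, `> 0`.
#' @return Per-capita rate (time^-1).
#' @export
mean_rate_transient <- function(theta, nu, T) {
  if (any(T <= 0)) stop("T must be > 0")
  if (nu <= 0) stop("nu must be > 0")
  if (theta < 0) stop("theta must be >= 0")
  theta * nu / (nu + theta) +
    theta^2 * (1 - exp(-(theta + nu) * T)) / (T * (nu + theta)^2)
}

#' Holling type II stationary feeding rate
#'
#' The stationary per-capita feeding rate of the chemostatic
#' search-and-handle process,
#' \deqn{\langle f \rangle = \frac{\alpha n_{R0}/N}
#'       {1 + (\alpha/\nu)\, n_{R0}/N},}
#' a Holling type II functional response with attack rate `alpha` and
#' handling time `1/nu`. Bounded above by both `theta` and `nu`.
#'
#' @param alpha encounter (attack) rate (time^-1).
#' @param nu pair degradation rate (inverse handling time), `> 0`.
#' @param nR0 fixed resource count.
#' @param N system size.
#' @return Per-capita rate (time^-1); vectorized over `nR0`.
#' @export
holling2 <- function(alpha, nu, nR0, N) {
  if (nu <= 0) stop("nu must be > 0")
  th <- alpha * nR0 / N
  th / (1 + th / nu)
}

#' Holling type III stationary feeding rate
#'
#' As [holling2()] but with resource-facilitated attack of Hill order `n`:
#' `theta_n = alpha (nR0/N)^n`, giving the sigmoidal
#' \deqn{\langle f \rangle = \frac{\theta_n}{1 + \theta_n/\nu}.}
#' `n = 1` recovers Holling type II exactly.
#'
#' @inheritParams holling2
#' @param n integer Hill order `>= 1`.
#' @return Per-capita rate (time^-1); vectorized over `nR0`.
#' @export
holling3 <- function(alpha, nu, nR0, N, n) {
  if (nu <= 0) stop("nu must be > 0")
  if (n < 1 || n != round(n)) stop("n must be an integer >= 1")
  th <- alpha * (nR0 / N)^n
  th / (1 + th / nu)
}

#' Stationary free-consumer density with interference
#'
#' Steady-state density of free consumers `fA* = nA*/N` of the chemostatic
#' feeding process with triplet interference, the positive root of
#' `(2 chi theta/(eta nu)) fA^2 + (1 + theta/nu) fA - fA0 = 0`:
#' \deqn{f_A^\star = \frac14\left[-\frac{\eta}{\chi}
#'   \left(1 + \frac{\nu}{\theta}\right) +
#'   \sqrt{\frac{\eta^2}{\chi^2}\left(1 + \frac{\nu}{\theta}\right)^2 +
#'   8\frac{\eta}{\chi}\frac{\nu}{\theta} f_{A0}}\right].}
#' In the no-interference limit `eta/chi -> Inf` this tends to
#' `fA0 * nu/(nu + theta)`.
#'
#' @param theta composite encounter rate, `> 0`.
#' @param nu pair degradation rate, `> 0`.
#' @param chi,eta triplet formation/degradation rates, `> 0`.
#' @param fA0 total consumer density `nA0/N`, `> 0`.
#' @return The stationary free-consumer density.
#' @export
free_consumer_fraction_star <- function(theta, nu, chi, eta, fA0) {
  if (any(c(theta, nu, chi, eta) <= 0))
    stop("theta, nu, chi, eta must all be > 0")
  if (fA0 < 0) stop("fA0 must be >= 0")
  ## algebraically identical to the -b + sqrt(b^2 + ...) form but free of
  ## the cancellation that form suffers as chi/eta -> 0
  b <- 1 + theta / nu
  a <- 2 * (chi / eta) * (theta / nu)
  2 * fA0 / (b + sqrt(b^2 + 4 * a * fA0))
}

#' Predator-dependent stationary feeding rate with interference
#'
#' The exact stationary per-capita feeding rate of the chemostatic feeding
#' process with triplet interference,
#' \deqn{\langle f \rangle = \frac{2\alpha n_{R0}/N}
#'  {1 + \frac{\alpha}{\nu}\frac{n_{R0}}{N} +
#'   \sqrt{\left(1 + \frac{\alpha}{\nu}\frac{n_{R0}}{N}\right)^2 +
#'   8\frac{\chi}{\eta}\frac{\alpha}{\nu}
#'   \frac{n_{R0}}{N}\frac{n_{A0}}{N}}},}
#' equal to `theta * fA*/fA0` with `fA*` from
#' [free_consumer_fraction_star()]. A predator-dependent response that
#' generalizes Holling type II: it equals [holling2()] exactly at
#' `chi = 0`, is monotonically decreasing in `nA0` for `chi > 0`, and only
#' approximately matches the Beddington-DeAngelis form (see
#' [bd_approximation()]).
#'
#' @inheritParams holling2
#' @param chi,eta triplet formation/degradation rates (`chi >= 0`,
#'   `eta > 0`).
#' @param nA0 fixed total consumer count.
#' @return Per-capita rate (time^-1); vectorized over `nR0` and `nA0`.
#' @export
generalized_bd <- function(alpha, nu, chi, eta, nR0, nA0, N) {
  if (nu <= 0 || eta <= 0) stop("nu and eta must be > 0")
  if (chi < 0) stop("chi must be >= 0")
  th <- alpha * nR0 / N
  b <- 1 + th / nu
  2 * th / (b + sqrt(b^2 + 8 * (chi / eta) * (th / nu) * (nA0 / N)))
}

#' Beddington-DeAngelis approximation of the interference response
#'
#' First-order approximation of [generalized_bd()] in the weak-interaction
#' limit `chi/eta << 1`, `alpha/nu << 1`:
#' \deqn{\langle f \rangle \approx \frac{\alpha n_{R0}/N}
#'  {1 + 2\frac{\alpha}{\nu}\frac{n_{R0}}{N} +
#'   2\frac{\chi}{\eta}\frac{\alpha}{\nu}
#'   \frac{n_{R0}}{N}\frac{n_{A0}}{N}}.}
#' This is Beddington-DeAngelis-like, but the interference term carries a
#' factor `nR0/N`; only at very high resource density (`nR0` near `N`)
#' does the denominator match the Beddington-DeAngelis form in `nA0`. At
#' `chi = 0` it reduces to a Holling II with a doubled handling term
#' `2 alpha/nu` -- an artifact of the approximation, not of the exact rate.
#'
#' @inheritParams generalized_bd
#' @return List with `rate`, the dimensionless ratios `tau_AR = alpha/nu`
#'   and `tau_ARA = chi/eta`, and `valid` (`TRUE` when both ratios are
#'   below 0.1).
#' @export
bd_approximation <- function(alpha, nu, chi, eta, nR0, nA0, N) {
  if (nu <= 0 || eta <= 0) stop("nu and eta must be > 0")
  dens <- nR0 / N
  tau_AR <- alpha / nu
  tau_ARA <- chi / eta
  rate <- alpha * dens /
    (1 + 2 * tau_AR * dens + 2 * tau_ARA * tau_AR * dens * (nA0 / N))
  list(rate = rate, tau_AR = tau_AR, tau_ARA = tau_ARA,
       valid = tau_AR < 0.1 && tau_ARA < 0.1)
}

## mean-field feeding ODEs of the chemostatic triplet scheme, in densities
## (used as an independent steady-state check on generalized_bd)
chemostat_triplet_rhs <- function(f, theta, nu, chi, eta, fA0) {
  fA <- f[[1L]]; fAR <- f[[2L]]
  fARA <- (fA0 - fA - fAR) / 2
  c(nu * fAR + eta * fARA - theta * fA - chi * fAR * fA,
    eta * fARA - nu * fAR + theta * fA - chi * fAR * fA)
}
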