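## Asymptotic reductions of the 4D mean-field system to classical 2D
## predator-prey models. Each returns a `reduced_model`: the family label,
## the effective macroscopic parameters, and the 2D vector field
## rhs(c(nR, nP)). For the Rosenzweig-MacArthur and Beddington-DeAngelis
## families the field is expressed in the slow time of the reduction.

new_reduced_model <- function(family, effective_params, rhs) {
  vals <- unlist(Filter(is.numeric, effective_params))
  ## growth rate (and hence K) may be negative; that case is flagged, all
  ## other effective rates must be non-negative
  ok <- names(vals) %in% c("r", "r_tilde", "K") | vals >= 0
  if (!all(ok))
    stop("negative effective parameter: ",
         paste(names(vals)[!ok], collapse = ", "))
  structure(list(family = family, effective_params = effective_params,
                 rhs = rhs),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat("Reduced 2D consumer-resource model:", x$family, "\n")
  print(unlist(x$effective_params))
  invisible(x)
}

#' Lotka-Volterra reduction (fast pair turnover)
#'
#' When handling pairs equilibrate fast (`d nAR/dt = 0`, appropriate for
#' large `nu`) and there is no immigration or interference, the mean-field
#' system collapses to the classical Lotka-Volterra predator-prey equations
#' with logistic prey growth:
#' \deqn{\dot n_R = r n_R (1 - n_R/K) - \alpha n_R n_P / N}
#' \deqn{\dot n_P = \alpha n_R n_P / N - \delta_A n_P}
#' with `r = beta - delta_R`, `K = r N / beta`, and predator variable
#' `nP = nA`. The attack term is linear in resource density (type I
#' functional response) and `alpha` is the macroscopic attack rate.
#'
#' @param params a [model_params()] with `chi = eta = 0` and
#'   `lambda_R = lambda_A = 0`.
#' @return A `reduced_model`; `effective_params` holds `r`, `K`, `alpha`,
#'   `delta_A` plus a flag `logistic_growth` (`FALSE` when `r <= 0`).
#' @export
reduce_lotka_volterra <- function(params) {
  if (params$chi != 0 || params$eta != 0)
    stop("Lotka-Volterra reduction requires chi = eta = 0")
  if (params$lambda_R != 0 || params$lambda_A != 0)
    stop("Lotka-Volterra reduction requires lambda_R = lambda_A = 0")
  r <- growth_rate(params)
  K <- carrying_capacity(params)
  N <- params$N; alpha <- params$alpha; dA <- params$delta_A
  rhs <- function(state) {
    nR <- state[[1L]]; nP <- state[[2L]]
    c(nR = r * nR * (1 - nR / K) - alpha * nR * nP / N,
      nP = alpha * nR * nP / N - dA * nP)
  }
  new_reduced_model("lotka_volterra",
                    list(r = r, K = K, alpha = alpha, delta_A = dA,
                         logistic_growth = r > 0),
                    rhs)
}

#' Rosenzweig-MacArthur reduction (slow pair turnover and slow growth)
#'
#' In the opposite regime, when pair degradation and resource growth are
#' slow -- `nu = eps * nu_tilde`, `r = eps * r_tilde` with `eps << 1` --
#' free consumers are slaved to the pairs,
#' `nA = 2 eps nu_tilde nAR / (delta_A + alpha nR/N) + O(eps^2)`, and in the
#' slow time the dynamics become the classical Rosenzweig-MacArthur model
#' with a Holling type II functional response:
#' \deqn{\dot n_R = \tilde r n_R (1 - n_R/K) -
#'   \frac{\bar\alpha (n_R/N) n_P}{1 + \bar\alpha \bar\tau_H n_R/N}}
#' \deqn{\dot n_P = \frac{\bar\alpha (n_R/N) n_P}
#'   {1 + \bar\alpha \bar\tau_H n_R/N} - \delta_P n_P}
#' with effective attack rate `alpha_bar = 2 alpha nu_tilde / delta_A`,
#' handling time `tauH_bar = 1/(2 nu_tilde)`, death rate
#' `delta_P = nu_tilde`, and predator variable `nP = nA + nAR`.
#' Note `alpha_bar * tauH_bar = alpha / delta_A`, independent of
#' `nu_tilde`, and that these macroscopic parameters differ from the
#' chemostatic Holling II parameterization ([holling2()]).
#'
#' @param params a [model_params()] with `chi = eta = 0`,
#'   `lambda_R = lambda_A = 0`; `params$nu` and `growth_rate(params)` are
#'   the epsilon-scaled slow rates.
#' @param epsilon time-scale separation parameter, `> 0`.
#' @return A `reduced_model` (field in slow time `t_tilde = eps * t`).
#' @export
reduce_rosenzweig_macarthur <- function(params, epsilon) {
  if (params$chi != 0 || params$eta != 0)
    stop("Rosenzweig-MacArthur reduction requires chi = eta = 0")
  if (params$lambda_R != 0 || params$lambda_A != 0)
    stop("reduction requires lambda_R = lambda_A = 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  nu_t <- params$nu / epsilon
  r_t <- growth_rate(params) / epsilon
  K <- carrying_capacity(params)
  N <- params$N; alpha <- params$alpha; dA <- params$delta_A
  ab <- 2 * alpha * nu_t / dA
  tH <- 1 / (2 * nu_t)
  rhs <- function(state) {
    nR <- state[[1L]]; nP <- state[[2L]]
    feed <- ab * (nR / N) * nP / (1 + ab * tH * nR / N)
    c(nR = r_t * nR * (1 - nR / K) - feed,
      nP = feed - nu_t * nP)
  }
  new_reduced_model("rosenzweig_macarthur",
                    list(alpha_bar = ab, tauH_bar = tH, delta_P = nu_t,
                         r_tilde = r_t, K = K, nu_tilde = nu_t),
                    rhs)
}

#' Beddington-DeAngelis-type reduction (interference, slow triplets)
#'
#' With triplets and the scalings `nu = eps * nu_tilde`,
#' `r = eps * r_tilde`, `eta = eps^2 * eta_tilde`, and assuming triplets
#' stay proportional to pairs along the dynamics (`nARA = kappa * nAR`),
#' the slow dynamics of `nP = nAR + nARA = (1 + kappa) nAR` take the
#' Beddington-DeAngelis functional form:
#' \deqn{\dot n_R = \tilde r n_R (1 - n_R/K) -
#'   \frac{\bar\alpha n_R n_P}{N\delta_A + \alpha n_R + \bar\chi n_P}}
#' \deqn{\dot n_P = \frac{\bar\alpha n_R n_P}
#'   {N\delta_A + \alpha n_R + \bar\chi n_P} - \bar\delta_P n_P}
#' with `chi_bar = chi/(1+kappa)`, `alpha_bar = 2 alpha nu_tilde/(1+kappa)`
#' and `deltaP_bar = nu_tilde/(1+kappa)`.
#'
#' The proportionality constant `kappa` is not determined by the reduction
#' itself; it is a required argument. [suggest_kappa()] computes the
#' equilibrium ratio `nARA/nAR` of the full system as a clearly-labelled
#' heuristic default.
#'
#' @param params a [model_params()] with `chi, eta > 0` and
#'   `lambda_R = lambda_A = 0`.
#' @param epsilon time-scale separation parameter, `> 0`.
#' @param kappa assumed triplet/pair ratio, `>= 0`.
#' @return A `reduced_model` (field in slow time).
#' @export
reduce_beddington_deangelis <- function(params, epsilon, kappa) {
  if (params$lambda_R != 0 || params$lambda_A != 0)
    stop("reduction requires lambda_R = lambda_A = 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  nu_t <- params$nu / epsilon
  r_t <- growth_rate(params) / epsilon
  K <- carrying_capacity(params)
  N <- params$N; alpha <- params$alpha; dA <- params$delta_A
  chib <- params$chi / (1 + kappa)
  ab <- 2 * alpha * nu_t / (1 + kappa)
  dPb <- nu_t / (1 + kappa)
  rhs <- function(state) {
    nR <- state[[1L]]; nP <- state[[2L]]
    feed <- ab * nR * nP / (N * dA + alpha * nR + chib * nP)
    c(nR = r_t * nR * (1 - nR / K) - feed,
      nP = feed - dPb * nP)
  }
  new_reduced_model("beddington_deangelis",
                    list(chi_bar = chib, alpha_bar = ab, deltaP_bar = dPb,
                         kappa = kappa, r_tilde = r_t, K = K,
                         nu_tilde = nu_t),
                    rhs)
}

#' Heuristic kappa from the coexistence equilibrium
#'
#' Returns the triplet-to-pair abundance ratio `nARA/nAR` at the
#' coexistence equilibrium of the full mean-field system,
#' `kappa = (chi/eta) nA / N`. This is a heuristic default for
#' [reduce_beddington_deangelis()] (the reduction assumes the ratio is
#' constant along trajectories, which holds exactly only at equilibrium).
#'
#' @param params a [model_params()] with `lambda_A = 0` and `chi, eta > 0`.
#' @return A single non-negative number.
#' @export
suggest_kappa <- function(params) {
  if (params$chi <= 0 || params$eta <= 0) return(0)
  eq <- equilibrium_branches(params)
  coex <- Filter(function(e) e$branch_label == "coexistence", eq)
  if (!length(coex)) stop("no coexistence branch for these parameters")
  ab <- coex[[1L]]$abundances
  if (ab[["nAR"]] <= 0) stop("coexistence branch has no pairs (nAR <= 0)")
  ab[["nARA"]] / ab[["nAR"]]
}
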