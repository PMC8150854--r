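#' Reaction propensities
#'
#' Evaluates the eight transition rates of the consumer-resource network at
#' a given state. The reactions, in fixed order, are: resource gain
#' (immigration into empty sites plus density-dependent birth), resource
#' death, consumer immigration, consumer death, pair formation, pair
#' release, triplet formation and triplet release:
#' \deqn{T_R^+ = \lambda_R (N - n_R) + \beta n_R (N - n_R)/N}
#' \deqn{T_R^- = \delta_R n_R, \quad T_A^+ = \lambda_A N, \quad
#'       T_A^- = \delta_A n_A}
#' \deqn{T_{AR}^+ = \alpha n_A n_R / N, \quad T_{AR}^- = \nu n_{AR}}
#' \deqn{T_{ARA}^+ = \chi n_A n_{AR} / N, \quad T_{ARA}^- = \eta n_{ARA}}
#'
#' Density factors use exact integer counts divided by `N`. With
#' `birth_divisor = "N-1"` the birth term divides by `N - 1` instead
#' (alternative finite-size convention; the default matches the mean-field
#' limit).
#'
#' @param state a [system_state()] (or any numeric 4-vector
#'   `(nR, nA, nAR, nARA)`).
#' @param params a [model_params()] object.
#' @return Named numeric vector of 8 non-negative rates, in the fixed
#'   reaction order (see `rownames(stoichiometry())`).
#' @seealso [stoichiometry()], [simulate_full()]
#' @examples
#' p <- model_params(N = 10, lambda_R = 1, beta = 2)
#' propensities(system_state(nR = 4), p)  # resource_gain = 6 + 2*4*6/10
#' @export
propensities <- function(state, params) {
  check_state(state, params)
  if (params$delta_R < 0)
    stop("propensities undefined for delta_R < 0 ",
         "(negative death rate is an analytic continuation only)")
  N <- params$N
  nR <- state[[1L]]; nA <- state[[2L]]
  nAR <- state[[3L]]; nARA <- state[[4L]]
  bdiv <- if (params$birth_divisor == "N-1") max(N - 1, 1) else N
  a <- c(params$lambda_R * (N - nR) + params$beta * nR * (N - nR) / bdiv,
         params$delta_R * nR,
         params$lambda_A * N,
         params$delta_A * nA,
         params$alpha * nA * nR / N,
         params$nu * nAR,
         params$chi * nA * nAR / N,
         params$eta * nARA)
  names(a) <- REACTIONS
  a
}

#' Stoichiometry matrix of the reaction network
#'
#' The 8 x 4 integer matrix of state changes, one row per reaction in the
#' fixed propensity order, one column per state variable
#' `(nR, nA, nAR, nARA)`. Pair formation consumes one resource and one free
#' consumer; pair release turns the pair into two free consumers (the
#' consumed resource has been converted into a new consumer); triplet
#' formation binds a free consumer to a pair; triplet release restores them.
#'
#' @return An 8 x 4 integer matrix with reaction names as row names and
#'   state-variable names as column names.
#' @examples
#' stoichiometry()["pair_release", ]  # c(0, 2, -1, 0)
#' @export
stoichiometry <- function() {
  S <- rbind(
    resource_gain     = c( 1L,  0L,  0L,  0L),
    resource_death    = c(-1L,  0L,  0L,  0L),
    consumer_gain     = c( 0L,  1L,  0L,  0L),
    consumer_death    = c( 0L, -1L,  0L,  0L),
    pair_formation    = c(-1L, -1L,  1L,  0L),
    pair_release      = c( 0L,  2L, -1L,  0L),
    triplet_formation = c( 0L, -1L, -1L,  1L),
    triplet_release   = c( 0L,  1L,  1L, -1L))
  colnames(S) <- STATE_VARS
  S
}
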