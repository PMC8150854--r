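#' Model parameters for the consumer-resource reaction network
#'
#' Bundles all rate constants of the individual-based consumer-resource
#' model together with the system size `N` (the number of resource sites).
#' This object is the single source of parameter truth shared by the
#' stochastic simulator, the mean-field ODEs and the bifurcation analysis.
#'
#' The processes and their rates are:
#' \describe{
#'   \item{`lambda_R`}{resource immigration rate per empty site (time^-1);
#'     the total immigration rate is `lambda_R * (N - nR)`.}
#'   \item{`delta_R`}{resource per-capita death rate (time^-1).}
#'   \item{`beta`}{resource per-capita birth rate when the system is almost
#'     empty (time^-1); births fill empty sites at rate
#'     `beta * nR * (N - nR) / N`.}
#'   \item{`lambda_A`}{consumer immigration rate per site (time^-1); total
#'     rate `lambda_A * N`.}
#'   \item{`delta_A`}{consumer per-capita death rate (time^-1).}
#'   \item{`alpha`}{consumer-resource encounter (attack) rate (time^-1);
#'     pair formation occurs at total rate `alpha * nA * nR / N`.}
#'   \item{`nu`}{handling-pair degradation rate (time^-1); `1/nu` is the
#'     handling time. A pair releases two free consumers (the consumed
#'     resource is converted into a new consumer).}
#'   \item{`chi`}{triplet formation rate (time^-1): the propensity of a free
#'     consumer to attack a handling pair, total rate
#'     `chi * nA * nAR / N`.}
#'   \item{`eta`}{triplet degradation rate (time^-1); `1/eta` is the
#'     interference time.}
#' }
#'
#' All rates must be non-negative, except that `delta_R` may be formally
#' negative: the control parameter `q = 1 - delta_R/beta` then exceeds 1,
#' an analytic continuation the bifurcation diagrams use. Such parameter
#' sets are valid for mean-field and stability analysis but are rejected
#' by [propensities()] and the simulators.
#'
#' @param N system size: maximum number of resource individuals (positive
#'   integer).
#' @param lambda_R,delta_R,beta,lambda_A,delta_A,alpha,nu,chi,eta
#'   non-negative rates (time^-1), see Details.
#' @param birth_divisor `"N"` (default) or `"N-1"`: divisor of the
#'   density-dependent birth term `beta * nR * (N - nR) / divisor`. The `N`
#'   convention matches the mean-field limit; `"N-1"` is provided as an
#'   alternative finite-size convention.
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [propensities()], [meanfield_rhs()], [simulate_full()]
#' @examples
#' p <- model_params(N = 100, beta = 1.5, delta_A = 1, alpha = 2.5, nu = 1)
#' growth_rate(p)        # r = beta - delta_R
#' carrying_capacity(p)  # K = r N / beta
#' @export
model_params <- function(N,
                         lambda_R = 0, delta_R = 0,
                         lambda_A = 0, delta_A = 0,
                         beta = 0, alpha = 0, nu = 0,
                         chi = 0, eta = 0,
                         birth_divisor = c("N", "N-1")) {
  birth_divisor <- match.arg(birth_divisor)
  rates <- c(lambda_R = lambda_R, delta_R = delta_R,
             lambda_A = lambda_A, delta_A = delta_A,
             beta = beta, alpha = alpha, nu = nu, chi = chi, eta = eta)
  if (any(!is.finite(rates)))
    stop("all rates must be finite")
  ## delta_R may be formally negative: the control parameter
  ## q = 1 - delta_R/beta then exceeds 1, which the bifurcation diagrams
  ## use as an analytic continuation. Stochastic simulation rejects it.
  if (any(rates[names(rates) != "delta_R"] < 0))
    stop("all rates except delta_R must be non-negative")
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != round(N))
    stop("N must be a positive integer")
  if (chi > 0 && eta <= 0)
    stop("chi > 0 requires eta > 0 (triplets must be able to degrade)")
  structure(list(N = as.numeric(N),
                 lambda_R = lambda_R, delta_R = delta_R,
                 lambda_A = lambda_A, delta_A = delta_A,
                 beta = beta, alpha = alpha, nu = nu,
                 chi = chi, eta = eta,
                 birth_divisor = birth_divisor),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Consumer-resource model parameters (N =", format(x$N), ")\n")
  r <- unlist(x[c("lambda_R", "delta_R", "lambda_A", "delta_A",
                  "beta", "alpha", "nu", "chi", "eta")])
  print(r)
  cat("derived: r =", format(growth_rate(x)),
      " K =", format(carrying_capacity(x)), "\n")
  invisible(x)
}

#' Derived resource parameters
#'
#' `growth_rate()` returns the intrinsic resource growth rate
#' `r = beta - delta_R`; `carrying_capacity()` returns `K = r * N / beta`,
#' the carrying capacity of the logistic-like resource dynamics in the
#' mean-field limit.
#'
#' @param params a [model_params()] object.
#' @return A single number.
#' @export
growth_rate <- function(params) params$beta - params$delta_R

#' @rdname growth_rate
#' @export
carrying_capacity <- function(params) {
  if (params$beta <= 0) stop("carrying capacity undefined for beta = 0")
  growth_rate(params) * params$N / params$beta
}

#' System state of the reaction network
#'
#' An integer abundance vector: free resources `nR`, free consumers `nA`,
#' handling pairs `nAR` and interference triplets `nARA`. Valid states have
#' all components non-negative and `nR <= N`.
#'
#' @param nR,nA,nAR,nARA non-negative integer abundances.
#' @return A named numeric vector of class `system_state`.
#' @export
system_state <- function(nR = 0, nA = 0, nAR = 0, nARA = 0) {
  s <- c(nR = nR, nA = nA, nAR = nAR, nARA = nARA)
  if (any(!is.finite(s)) || any(s < 0) || any(s != round(s)))
    stop("state components must be non-negative integers")
  structure(as.numeric(s), names = STATE_VARS, class = "system_state")
}

## internal: stop unless state is valid for params
check_state <- function(state, params) {
  if (length(state) != 4L) stop("state must have 4 components")
  if (any(!is.finite(state)) || any(state < 0))
    stop("invalid state: negative or non-finite abundance")
  if (state[[1L]] > params$N)
    stop("invalid state: nR exceeds system size N")
  invisible(TRUE)
}

#' Read model parameters from a config file
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) configuration
#' whose keys are exactly the argument names of [model_params()]. Unknown
#' keys are an error; `overrides` (e.g. parsed CLI flags) take precedence
#' over file values.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @param overrides named list merged over the file contents.
#' @return A [model_params()] object.
#' @export
read_params <- function(path, overrides = list()) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::yaml.load_file(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- modifyList(cfg, overrides)
  allowed <- names(formals(model_params))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(model_params, cfg)
}
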