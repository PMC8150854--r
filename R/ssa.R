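#' Exact stochastic simulation of the full consumer-resource network
#'
#' Runs the Gillespie direct method over the eight reactions defined by
#' [propensities()] and [stoichiometry()]. Event times are exponential with
#' the total propensity as rate; reactions are chosen proportionally to
#' their propensities. If every propensity vanishes the state is absorbing
#' and the trajectory terminates early with `absorbed = TRUE`.
#'
#' @param params a [model_params()] object.
#' @param init initial [system_state()].
#' @param max_time stop after this much simulated time (ignored if `<= 0`).
#' @param max_events stop after this many reaction events (ignored if
#'   `<= 0`). At least one of `max_time`, `max_events` must be positive.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return A `trajectory` object: list with `times` (event times, starting
#'   at 0), `states` (matrix, one row per event, columns
#'   `nR, nA, nAR, nARA`), `absorbed`, `end_time`, `seed`, `params`.
#' @examples
#' p <- model_params(N = 50, lambda_R = 1, delta_R = 0.5, beta = 1,
#'                   delta_A = 1, alpha = 2, nu = 1)
#' tr <- simulate_full(p, system_state(nR = 25, nA = 5), max_time = 10,
#'                     seed = 1)
#' head(as.data.frame(tr))
#' @export
simulate_full <- function(params, init, max_time = 0, max_events = 0,
                          seed = NULL) {
  check_state(init, params)
  if (params$delta_R < 0)
    stop("cannot simulate with delta_R < 0")
  if (max_time <= 0 && max_events <= 0)
    stop("one of max_time or max_events must be positive")
  if (!is.null(seed)) { seed <- as.integer(seed); set.seed(seed) }
  pv <- unlist(params[c("N", "lambda_R", "delta_R", "lambda_A", "delta_A",
                        "beta", "alpha", "nu", "chi", "eta")])
  res <- .ssa_full_cpp(pv, as.numeric(init), max_time, max_events,
                       as.integer(params$birth_divisor == "N-1"))
  colnames(res$states) <- STATE_VARS
  structure(list(times = res$times, states = res$states,
                 absorbed = res$absorbed, end_time = res$end_time,
                 seed = seed, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("SSA trajectory:", length(x$times), "records, t in [0,",
      format(x$end_time), "]",
      if (isTRUE(x$absorbed)) "(absorbing state reached)" else "", "\n")
  cat("final state:", paste(STATE_VARS, x$states[nrow(x$states), ],
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' Stochastic simulation of the chemostatic feeding process
#'
#' Simulates the feeding subprocess with the resource count held constant at
#' `nR0`: every consumed resource item is instantaneously replenished, which
#' is implemented by never decrementing the resource count. Three reaction
#' schemes are supported:
#' \describe{
#'   \item{`"holling2"`}{feeding at per-free-consumer rate
#'     `theta = alpha * nR0 / N`; pair release at rate `nu * nAR`.
#'     Conservation: `nA + nAR = nA0`.}
#'   \item{`"holling3"`}{as `"holling2"` but
#'     `theta = alpha * (nR0/N)^hill_order` (resource-facilitated attack of
#'     Hill order `hill_order`).}
#'   \item{`"triplets"`}{adds consumer interference: a free consumer attacks
#'     a handling pair at rate `chi * nA * nAR / N` forming a triplet, which
#'     degrades at rate `eta * nARA`. Conservation:
#'     `nA + nAR + 2 nARA = nA0`.}
#' }
#' With `chi = 0` the `"triplets"` scheme consumes the identical random
#' stream as `"holling2"` and so reproduces it exactly.
#'
#' @param mode one of `"holling2"`, `"holling3"`, `"triplets"`.
#' @param alpha,nu encounter and pair-degradation rates (time^-1).
#' @param chi,eta triplet formation/degradation rates (`"triplets"` only).
#' @param hill_order integer Hill order `>= 1` (`"holling3"` only).
#' @param nR0 fixed resource count, `0 <= nR0 <= N`.
#' @param nA0 fixed total consumer count, `>= 1`. All consumers start free.
#' @param N system size.
#' @param max_time,max_events stopping rule (at least one positive). The
#'   event count is the Gillespie step count.
#' @param seed integer seed.
#' @return A `feeding_record` object: list with `event_times`, `event`
#'   (factor: which reaction fired), `nA_path` (free consumers after each
#'   event), `cumulative_n` (feeding events so far), `end_time`, `theta`,
#'   and the run metadata (`mode`, `nR0`, `nA0`, `N`, rates, `seed`).
#' @seealso [estimate_feeding_rate()], [holling2()], [generalized_bd()]
#' @examples
#' fr <- simulate_chemostat("holling2", alpha = 2.5, nu = 1, nR0 = 50,
#'                          nA0 = 20, N = 100, max_events = 2000, seed = 1)
#' estimate_feeding_rate(fr, transient_fraction = 0.5)
#' @export
simulate_chemostat <- function(mode = c("holling2", "holling3", "triplets"),
                               alpha, nu, chi = 0, eta = 0, hill_order = 1,
                               nR0, nA0, N, max_time = 0, max_events = 0,
                               seed = NULL) {
  mode <- match.arg(mode)
  if (nR0 < 0 || nR0 > N) stop("need 0 <= nR0 <= N")
  if (nA0 < 1) stop("need nA0 >= 1")
  if (alpha < 0 || nu <= 0) stop("need alpha >= 0 and nu > 0")
  if (max_time <= 0 && max_events <= 0)
    stop("one of max_time or max_events must be positive")
  if (mode == "holling3") {
    if (hill_order < 1 || hill_order != round(hill_order))
      stop("hill_order must be an integer >= 1")
  } else hill_order <- 1
  if (mode == "triplets") {
    if (chi < 0 || eta <= 0)
      stop("triplets mode needs chi >= 0 and eta > 0")
  } else { chi <- 0; eta <- 0 }
  if (!is.null(seed)) { seed <- as.integer(seed); set.seed(seed) }
  res <- .ssa_chemostat_cpp(alpha, nu, chi, eta, as.integer(hill_order),
                            nR0, nA0, N, max_time, max_events)
  ev <- factor(res$event, levels = 1:4,
               labels = c("feed", "pair_release",
                          "triplet_formation", "triplet_release"))
  structure(list(event_times = res$times, event = ev,
                 nA_path = res$nA, cumulative_n = res$cumulative_n,
                 end_time = res$end_time, theta = res$theta,
                 mode = mode, hill_order = hill_order,
                 alpha = alpha, nu = nu, chi = chi, eta = eta,
                 nR0 = nR0, nA0 = nA0, N = N, seed = seed),
            class = "feeding_record")
}

#' @export
print.feeding_record <- function(x, ...) {
  cat("Chemostatic feeding record (", x$mode, "): ",
      length(x$event_times), " events, t in [0, ", format(x$end_time),
      "]\n", sep = "")
  cat("nR0 =", x$nR0, " nA0 =", x$nA0, " N =", x$N,
      " theta =", format(x$theta), "\n")
  n <- length(x$cumulative_n)
  cat("cumulative feeding events:", if (n) x$cumulative_n[n] else 0, "\n")
  invisible(x)
}

#' @export
as.data.frame.feeding_record <- function(x, ...) {
  data.frame(time = x$event_times, event = x$event, nA = x$nA_path,
             cumulative_n = x$cumulative_n)
}

#' Per-capita feeding rate from a chemostatic run
#'
#' Estimates the stationary per-capita feeding rate as (feeding events after
#' the transient) / (elapsed time after the transient x `nA0`), with a
#' batch-means Monte-Carlo standard error (the post-transient window is
#' split into `batches` equal time intervals; the SE is the standard
#' deviation of the per-batch rates divided by `sqrt(batches)`).
#'
#' The transient can be given as a fraction of the Gillespie steps
#' (`transient_fraction`, matching step-count reporting) or as simulated
#' time (`transient_time`); elapsed *time*, never step count, enters the
#' rate denominator.
#'
#' @param record a `feeding_record` from [simulate_chemostat()].
#' @param transient_fraction fraction (in `[0, 1)`) of Gillespie steps
#'   discarded as transient.
#' @param transient_time alternatively, simulated time to discard
#'   (overrides `transient_fraction` if not `NULL`).
#' @param batches number of batch-means batches.
#' @return List with `rate`, `se`, `events`, `elapsed`.
#' @export
estimate_feeding_rate <- function(record, transient_fraction = 0.5,
                                  transient_time = NULL, batches = 20) {
  if (!inherits(record, "feeding_record")) stop("not a feeding_record")
  nev <- length(record$event_times)
  t0 <- if (!is.null(transient_time)) {
    transient_time
  } else {
    if (transient_fraction < 0 || transient_fraction >= 1)
      stop("transient_fraction must be in [0, 1)")
    if (nev == 0) 0 else {
      k <- floor(transient_fraction * nev)
      if (k == 0) 0 else record$event_times[k]
    }
  }
  T1 <- record$end_time
  if (T1 <= t0) stop("no post-transient window: end_time <= transient")
  feeds <- record$event_times[record$event == "feed"]
  feeds <- feeds[feeds > t0]
  rate <- length(feeds) / ((T1 - t0) * record$nA0)
  edges <- seq(t0, T1, length.out = batches + 1)
  per_batch <- tabulate(findInterval(feeds, edges,
                                     rightmost.closed = TRUE),
                        nbins = batches)
  bw <- (T1 - t0) / batches
  brates <- per_batch / (bw * record$nA0)
  se <- stats::sd(brates) / sqrt(batches)
  list(rate = rate, se = se, events = length(feeds), elapsed = T1 - t0)
}
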