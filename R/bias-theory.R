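#' Expected short-trial bias of the one-step coefficient
#'
#' When the regression means are estimated within a single short trial of
#' length `T`, the one-step slope (and hence the branching-parameter
#' estimate of the trial-separated method) is biased downward. To leading
#' order in `1/T` the expectation is
#' \deqn{\hat m \approx m\left(1 - \frac{1}{T}\left[3 +
#'   \frac{1}{m}\right]\right),}
#' always below the true `m`; the bias vanishes as `T` grows.
#'
#' @param m true branching parameter, in (0, 1).
#' @param T_ trial length in steps (>= 2).
#' @return the expected biased estimate, `< m`.
#' @examples
#' expected_mhat(0.5, 100)  # 0.475
#' @export
expected_mhat <- function(m, T_) {
  if (any(m <= 0) || any(m >= 1)) stop("`m` must be in (0, 1)", call. = FALSE)
  if (any(T_ < 2)) stop("`T_` must be >= 2", call. = FALSE)
  m * (1 - (3 + 1 / m) / T_)
}

#' Expected ratio of estimated to true timescale for short trials
#'
#' Propagating the one-step bias through `tau = -dt / log(m)` gives the full
#' closed form
#' \deqn{\frac{\hat\tau}{\tau} = \frac{1}
#'   {1 + \frac{\tau}{T\Delta t}\left[3 + e^{\Delta t/\tau}\right]},}
#' which lies in (0, 1] and tends to 1 as `T` grows.
#'
#' @param tau true intrinsic timescale (> 0, in `dtunit`s).
#' @param T_ trial length in steps (> 0).
#' @param dt bin size (> 0).
#' @return the expected ratio `tau_hat / tau`.
#' @examples
#' expected_tau_ratio(100, 1000, dt = 1)  # ~0.7136
#' @export
expected_tau_ratio <- function(tau, T_, dt = 1) {
  if (any(tau <= 0) || any(T_ <= 0) || any(dt <= 0)) {
    stop("`tau`, `T_` and `dt` must be > 0", call. = FALSE)
  }
  1 / (1 + tau / (T_ * dt) * (3 + exp(dt / tau)))
}

#' Leading-order short-trial bias in normalized trial length
#'
#' For timescales well above the bin size the ratio collapses onto the
#' universal curve
#' \deqn{y = \frac{1}{1 + 4/x}, \qquad x = T/\tau,}
#' monotone increasing in the normalized trial length `x`.
#'
#' @param x normalized trial length `T / tau` (> 0).
#' @return the expected ratio `tau_hat / tau`.
#' @examples
#' tau_ratio_leading_order(4)  # 0.5
#' @export
tau_ratio_leading_order <- function(x) {
  if (any(x <= 0)) stop("`x` must be > 0", call. = FALSE)
  1 / (1 + 4 / x)
}

#' Simulation study of the short-trial bias
#'
#' Repeats, for each normalized trial length `x = T/tau`, the experiment:
#' simulate `numtrials` fully sampled branching-process trials of length
#' `x * tau` with `m = exp(-dt/tau)` and target activity `a`, estimate the
#' coefficients with the requested method(s) over steps `1 .. min(20 tau,
#' T - 2)`, fit the exponential-with-offset model, and record
#' `tau_hat / tau`. The trial-separated method tracks the analytic bias
#' curve [tau_ratio_leading_order()]; the stationary-mean method stays close
#' to 1 already for `x` around 10.
#'
#' @param tau true timescale in steps.
#' @param ratios normalized trial lengths `T/tau` to probe.
#' @param numtrials trials per simulated dataset.
#' @param repetitions independent simulations per grid point.
#' @param a target stationary activity of the simulated process.
#' @param methods coefficient methods to run (default both).
#' @param numboot bootstrap replicates inside each estimate (0: none needed
#'   for the bias curve itself).
#' @param seed master seed; every repetition derives its own substream.
#' @return a tibble with one row per `(ratio, method)`: the grid value `x`,
#'   trial length `T`, mean and standard error of `tau_hat / tau` across
#'   repetitions, and the repetition count.
#' @export
bias_study <- function(tau = 100, ratios = c(1, 3, 10, 30, 100),
                       numtrials = 50, repetitions = 20, a = 1000,
                       methods = c("trialseparated", "stationarymean"),
                       numboot = 0, seed = NULL) {
  methods <- vapply(methods, match_method, character(1), USE.NAMES = FALSE)
  seed <- resolve_seed(seed)
  m <- m_from_tau(tau, 1)
  grid <- tidyr::expand_grid(ratio = ratios, rep = seq_len(repetitions))
  sim_seeds <- matrix(derive_seeds(seed, 2L * nrow(grid)), ncol = 2)
  ratio_hat <- purrr::map(seq_len(nrow(grid)), function(j) {
    T_ <- max(as.integer(round(grid$ratio[j] * tau)), 4L)
    bp <- simulate_branching(m = m, a = a, length = T_,
                             numtrials = numtrials, seed = sim_seeds[j, 1])
    # keep at least 5 point pairs in every per-trial regression: at k close
    # to T - 2 the slope is estimated from 2-3 samples and degenerates
    kmax <- min(as.integer(20 * tau), T_ - 5L)
    purrr::map_dbl(methods, function(meth) {
      rk <- coefficients(bp, steps = c(1L, kmax), method = meth,
                         numboot = numboot, seed = sim_seeds[j, 2])
      ft <- fit(rk, fitfunc = "exponential_offset", numboot = 0)
      ft$tau / tau
    })
  })
  grid$ratio_hat <- ratio_hat
  tidyr::unnest_longer(grid, "ratio_hat", indices_to = "method_id") |>
    dplyr::mutate(method = methods[.data$method_id]) |>
    dplyr::group_by(.data$ratio, .data$method) |>
    dplyr::summarise(
      trial_length = as.integer(round(.data$ratio[1] * tau)),
      mean_ratio = mean(.data$ratio_hat),
      se_ratio = stats::sd(.data$ratio_hat) / sqrt(dplyr::n()),
      repetitions = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$method, .data$ratio)
}
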