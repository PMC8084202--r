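#' Simulate a driven branching process
#'
#' Generates trial-structured activity from a subcritical, critical or
#' supercritical branching process with stationary Poisson drive. At each
#' step every active unit triggers on average `m` new events and the drive
#' contributes `h * dt` further events, so the next activity is drawn as
#' \deqn{A_{t+1} \sim \mathrm{Poisson}(m A_t + h\Delta t),}
#' which keeps the conditional-mean law
#' \eqn{\langle A_{t+1} | A_t \rangle = m A_t + h\Delta t} exact (a sum of
#' independent Poisson offspring and Poisson drive is Poisson).
#'
#' Exactly one of `h` and `a` may be omitted. For subcritical dynamics
#' (`m < 1`) a target stationary activity `a` determines the drive via
#' `h = a (1 - m) / dt`, so the long-run mean activity
#' \eqn{\langle A \rangle = h\Delta t / (1 - m)} equals `a`. For `m >= 1` no
#' finite stationary mean exists and `h` must be given explicitly.
#'
#' Each trial draws from its own independent RNG substream of `seed`, so
#' increasing `numtrials` reproduces the earlier trials bit-identically.
#' Trials start deterministically at the stationary mean (rounded), making
#' the process stationary from the first bin for the linear statistics used
#' here; a burn-in can be requested but defaults to 0.
#'
#' @param m branching parameter (mean events triggered per event), `>= 0`.
#' @param h external drive rate in events per `dtunit` (optional if `a` given
#'   and `m < 1`).
#' @param a target stationary mean activity in events per bin (optional if
#'   `h` given).
#' @param dt bin size in `dtunit`s.
#' @param length number of time steps per trial (>= 2).
#' @param numtrials number of trials.
#' @param subp sampling fraction `alpha` in (0, 1]; if `< 1` the returned
#'   array is the binomially subsampled activity and the fully sampled array
#'   is kept in the `"fullsample"` attribute.
#' @param seed integer seed; `NULL` draws one from the session RNG.
#' @param burnin steps simulated and discarded before recording (default 0).
#' @param dtunit unit label attached to the result.
#' @return a [trial_array()] of non-negative integer counts
#'   (`numtrials` x `length`).
#' @examples
#' bp <- simulate_branching(m = 0.98, a = 100, length = 2000, numtrials = 4,
#'                          seed = 1)
#' glance(bp)
#' @export
simulate_branching <- function(m, h = NULL, a = NULL, dt = 1, length,
                               numtrials = 1, subp = 1, seed = NULL,
                               burnin = 0, dtunit = "steps") {
  if (!is.numeric(m) || length(m) != 1 || m < 0) {
    stop("`m` must be a single number >= 0", call. = FALSE)
  }
  if (is.null(h) && is.null(a)) {
    stop("one of `h` (drive rate) or `a` (target activity) must be given",
         call. = FALSE)
  }
  if (!is.null(h) && !is.null(a)) {
    stop("give either `h` or `a`, not both", call. = FALSE)
  }
  if (!is.null(a) && (a <= 0)) stop("`a` must be > 0", call. = FALSE)
  if (!is.null(a) && m >= 1) {
    stop("for m >= 1 no finite stationary mean exists; give the drive `h` ",
         "explicitly instead of a target activity `a`", call. = FALSE)
  }
  if (!is.null(h) && h < 0) stop("`h` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  length <- as.integer(length)
  if (is.na(length) || length < 2) stop("`length` must be >= 2", call. = FALSE)
  numtrials <- as.integer(numtrials)
  if (is.na(numtrials) || numtrials < 1) {
    stop("`numtrials` must be >= 1", call. = FALSE)
  }
  if (subp <= 0 || subp > 1) stop("`subp` must be in (0, 1]", call. = FALSE)
  burnin <- as.integer(burnin)
  if (is.na(burnin) || burnin < 0) stop("`burnin` must be >= 0", call. = FALSE)

  if (is.null(h)) h <- a * (1 - m) / dt
  hdt <- h * dt
  a0 <- if (!is.null(a)) {
    round(a)
  } else if (m < 1) {
    round(hdt / (1 - m))
  } else {
    round(hdt)
  }

  seed <- resolve_seed(seed)
  streams <- rng_substreams(seed, numtrials)
  total <- length + burnin
  full <- matrix(0, nrow = numtrials, ncol = length)
  sub <- if (subp < 1) matrix(0, nrow = numtrials, ncol = length) else NULL
  for (i in seq_len(numtrials)) {
    with_rng_stream(streams[[i]], {
      A <- numeric(total)
      A[1] <- a0
      for (t in seq_len(total - 1L)) {
        A[t + 1L] <- stats::rpois(1L, m * A[t] + hdt)
      }
      A <- A[(burnin + 1L):total]
      full[i, ] <- A
      if (!is.null(sub)) sub[i, ] <- stats::rbinom(length, size = A, prob = subp)
    })
  }

  out <- trial_array(if (is.null(sub)) full else sub, dt = dt, dtunit = dtunit)
  if (!is.null(sub)) {
    attr(out, "fullsample") <- trial_array(full, dt = dt, dtunit = dtunit)
  }
  attr(out, "config") <- list(m = m, h = h, a = a, dt = dt, length = length,
                              numtrials = numtrials, subp = subp, seed = seed,
                              burnin = burnin)
  out
}

#' Fully sampled counterpart of a subsampled simulation
#'
#' @param x a [trial_array()] produced by [simulate_branching()] with
#'   `subp < 1`.
#' @return the fully sampled [trial_array()], or `x` itself when no
#'   subsampling was applied.
#' @export
fullsample_of <- function(x) {
  fs <- attr(x, "fullsample")
  if (is.null(fs)) x else fs
}

#' Binomial subsampling of activity counts
#'
#' Models spatial subsampling: each of the `A_t` events in a bin is observed
#' independently with probability `prob` (the sampling fraction `alpha`), so
#' the recorded activity is `a_t ~ Binomial(A_t, prob)`. Subsampling scales
#' the amplitude of the autocorrelation function but leaves the intrinsic
#' timescale untouched, which is what the multi-step regression estimator
#' exploits.
#'
#' @param trials a [trial_array()] (or matrix/vector) of non-negative
#'   integer counts.
#' @param prob sampling fraction in (0, 1].
#' @param seed integer seed; `NULL` draws one from the session RNG.
#' @return a [trial_array()] of the same shape; elementwise `a_t <= A_t`.
#' @examples
#' bp <- simulate_branching(m = 0.9, a = 50, length = 500, numtrials = 2,
#'                          seed = 7)
#' sub <- simulate_subsampling(bp, prob = 0.1, seed = 8)
#' all(sub <= bp)
#' @export
simulate_subsampling <- function(trials, prob, seed = NULL) {
  if (!is_trial_array(trials)) trials <- trial_array(trials)
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob > 1) {
    stop("`prob` must be a single sampling fraction in (0, 1]", call. = FALSE)
  }
  assert_counts(trials, "subsampling input")
  if (prob == 1) return(trials)
  seed <- resolve_seed(seed)
  streams <- rng_substreams(seed, nrow(trials))
  out <- matrix(0, nrow = nrow(trials), ncol = ncol(trials))
  for (i in seq_len(nrow(trials))) {
    out[i, ] <- with_rng_stream(
      streams[[i]],
      stats::rbinom(ncol(trials), size = as.integer(trials[i, ]), prob = prob)
    )
  }
  trial_array(out, dt = attr(trials, "dt"), dtunit = attr(trials, "dtunit"))
}
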