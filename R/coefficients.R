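#' Lagged correlation coefficient of a single trial
#'
#' The slope of the regression of activity at time `t + k` on activity at
#' time `t`: with `x` the first `T - k` samples, `y` the samples shifted by
#' `k`, and per-series means `x_bar`, `y_bar`,
#' \deqn{r_k = \frac{\sum_t (x_t - \bar x)(y_t - \bar y)}
#'                  {\sum_t (x_t - \bar x)^2}.}
#' For a fully sampled stationary first-order autoregressive process
#' `r_k = m^k`; under subsampling only the amplitude shrinks, not the decay.
#'
#' @param trial numeric activity vector (one trial).
#' @param k positive integer lag, `k <= length(trial) - 2`.
#' @return the scalar slope `r_k`.
#' @examples
#' rk_naive(c(0, 1, 2, 3), k = 1)   # 1
#' rk_naive(c(1, 0, 1, 0), k = 1)   # -1
#' @export
rk_naive <- function(trial, k) {
  trial <- as.numeric(trial)
  k <- check_step(k, length(trial))
  n <- length(trial) - k
  x <- trial[seq_len(n)]
  y <- trial[seq_len(n) + k]
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) {
    stop(sprintf(paste0("degenerate data: the first %d samples are constant, ",
                        "the regression slope r_%d is undefined"), n, k),
         call. = FALSE)
  }
  sum(xc * (y - mean(y))) / den
}

#' Trial-separated correlation coefficient
#'
#' Computes [rk_naive()] within each trial and averages:
#' \eqn{r_k = \frac{1}{N}\sum_i r_{i,k}}. Because each trial supplies its own
#' mean estimate, the method is robust to activity drifting from trial to
#' trial, at the price of a downward bias when trials are short
#' (see [expected_mhat()]).
#'
#' @param trials a [trial_array()] (or anything [input_handler()] accepts).
#' @param k positive integer lag.
#' @return a list with `r` (the across-trial mean) and `trial_r` (the
#'   per-trial slopes `r_{i,k}`).
#' @export
rk_trialseparated <- function(trials, k) {
  trials <- input_handler(trials)
  per <- vapply(seq_len(nrow(trials)), function(i) {
    tryCatch(rk_naive(trials[i, ], k),
             error = function(e) {
               stop(sprintf("trial %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  }, numeric(1))
  list(r = mean(per), trial_r = per)
}

#' Stationary-mean correlation coefficient
#'
#' Pools all trials around common lag-dependent means, assuming the activity
#' is stationary across trials:
#' \deqn{r_k = \frac{\sum_i \frac{1}{T-k}\sum_{t=1}^{T-k}
#'      (x_{i,t} - \bar x_{\cdot,k})(y_{i,t} - \bar y_{\cdot,k})}
#'      {\sum_i \frac{1}{T}\sum_{t=1}^{T} (x_{i,t} - \bar x_{\cdot,k})^2}}
#' with the pooled means
#' \eqn{\bar x_{\cdot,k} = \frac{1}{N(T-k)}\sum_i\sum_{t=1}^{T-k} a_{i,t}}
#' (and analogously for the shifted series). Pooling corrects the short-trial
#' bias of the trial-separated method when the stationarity assumption holds.
#' The denominator's inner sum runs over the full trial length `T`, as in the
#' method's defining formula; the difference from truncating at `T - k` is of
#' order `k/T`.
#'
#' @inheritParams rk_trialseparated
#' @return the scalar pooled slope `r_k`.
#' @export
rk_stationarymean <- function(trials, k) {
  trials <- input_handler(trials)
  T_ <- ncol(trials)
  k <- check_step(k, T_)
  n <- T_ - k
  x <- trials[, seq_len(n), drop = FALSE]
  y <- trials[, seq_len(n) + k, drop = FALSE]
  xbar <- mean(x)
  ybar <- mean(y)
  num <- sum(rowSums((x - xbar) * (y - ybar))) / n
  den <- sum(rowSums((trials - xbar)^2)) / T_
  if (den == 0) {
    stop("degenerate data: pooled variance is zero", call. = FALSE)
  }
  num / den
}

check_step <- function(k, T_) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("lag `k` must be a positive integer",
                              call. = FALSE)
  if (k > T_ - 2) {
    stop(sprintf("lag k = %d needs trials longer than %d samples (T >= k + 2)",
                 k, T_), call. = FALSE)
  }
  k
}

#' Multi-step regression coefficients of trial-structured activity
#'
#' Estimates the lagged correlation coefficients `r_k` for a set of steps
#' `k`, using either the trial-separated method (`"ts"`: regression within
#' each trial, then averaged — robust to trial-to-trial drift, biased for
#' short trials) or the stationary-mean method (`"sm"`: one regression on
#' the pooled trials — bias-corrected, assumes stationarity across trials).
#' When `numboot > 0` and at least two trials are available, trial-level
#' bootstrap resamples are drawn and per-step standard errors attached.
#'
#' @param object trial-structured activity: a [trial_array()] or anything
#'   [input_handler()] accepts. (For model objects the default method falls
#'   back to [stats::coefficients()].)
#' @param steps either `c(kmin, kmax)` (a length-2 vector is read as an
#'   inclusive range) or an explicit integer vector of lags (any other
#'   length). Lags beyond `T - 2` are dropped with a warning. Default:
#'   `1 .. min(T - 2, 1000)`.
#' @param method `"trialseparated"`/`"ts"` or `"stationarymean"`/`"sm"`.
#' @param dt,dtunit bin size and unit; default to the metadata carried by
#'   the input array.
#' @param numboot number of trial-level bootstrap resamples (0 disables).
#' @param seed integer seed for the bootstrap; `NULL` draws one.
#' @param ... passed between methods.
#' @return an object of class `mr_coefficients`: steps, coefficients,
#'   per-trial coefficients (trial-separated only), bootstrap samples and
#'   standard errors, and the time metadata. Use [tidy()] for a tibble view.
#' @examples
#' bp <- simulate_branching(m = 0.9, a = 100, length = 2000, numtrials = 5,
#'                          seed = 1)
#' rk <- coefficients(bp, steps = c(1, 30), method = "ts", numboot = 50,
#'                    seed = 2)
#' tidy(rk)
#' @export
coefficients <- function(object, ...) UseMethod("coefficients")

#' @export
coefficients.default <- function(object, ...) {
  if (is.numeric(object) || is.list(object) || is.data.frame(object)) {
    coefficients.trial_array(input_handler(object), ...)
  } else {
    stats::coefficients(object, ...)
  }
}

#' @rdname coefficients
#' @export
coefficients.trial_array <- function(object, steps = NULL,
                                     method = c("trialseparated", "ts",
                                                "stationarymean", "sm"),
                                     dt = NULL, dtunit = NULL, numboot = 100,
                                     seed = NULL, ...) {
  trials <- object
  method <- match_method(match.arg(method))
  T_ <- ncol(trials)
  N <- nrow(trials)
  steps <- resolve_steps(steps, T_)
  if (is.null(dt)) dt <- attr(trials, "dt")
  if (is.null(dtunit)) dtunit <- attr(trials, "dtunit")
  numboot <- as.integer(numboot)

  stats_ <- trial_sufficient_stats(trials, steps)
  est <- estimate_from_stats(stats_, seq_len(N), method)
  if (anyNA(est$r) || any(!is.finite(est$r))) {
    bad <- steps[which(!is.finite(est$r))[1]]
    stop(sprintf("degenerate data: r_%d is undefined (zero variance)", bad),
         call. = FALSE)
  }

  res <- structure(
    list(steps = steps, coefficients = est$r,
         trial_coefficients = est$trial_r,
         method = method, dt = dt, dtunit = dtunit,
         stderrs = NULL, bootstrap_samples = NULL,
         num_trials = N, trial_length = T_,
         numboot = 0L, seed = NULL),
    class = "mr_coefficients")
  attr(res, "trial_stats") <- stats_

  if (numboot > 0) {
    if (N < 2) {
      warning("bootstrap needs at least 2 trials; consider chunk_into_trials()",
              call. = FALSE)
    } else {
      seed <- resolve_seed(seed)
      bs <- bootstrap_coefficient_samples(stats_, method, numboot, seed)
      res$bootstrap_samples <- bs
      res$stderrs <- apply(bs, 2, stats::sd)
      res$numboot <- numboot
      res$seed <- seed
    }
  }
  res
}

match_method <- function(label) {
  switch(label,
         ts = , trialseparated = "trialseparated",
         sm = , stationarymean = "stationarymean",
         stop(sprintf("unknown coefficient method '%s'", label),
              call. = FALSE))
}

resolve_steps <- function(steps, T_) {
  kmax_allowed <- T_ - 2L
  if (kmax_allowed < 1) stop("trials must have at least 3 time bins",
                             call. = FALSE)
  if (is.null(steps)) {
    return(seq_len(min(kmax_allowed, 1000L)))
  }
  steps <- as.integer(steps)
  if (anyNA(steps)) stop("`steps` must be integer lags", call. = FALSE)
  if (length(steps) == 2) {
    if (steps[1] < 1) stop("`steps`: kmin must be >= 1", call. = FALSE)
    if (steps[2] < steps[1]) stop("`steps`: kmax < kmin", call. = FALSE)
    if (steps[1] > kmax_allowed) {
      stop("no valid steps remain below T - 2", call. = FALSE)
    }
    if (steps[2] > kmax_allowed) {
      warning(sprintf("kmax = %d exceeds T - 2 = %d; clipping",
                      steps[2], kmax_allowed), call. = FALSE)
      steps[2] <- kmax_allowed
    }
    return(seq.int(steps[1], steps[2]))
  }
  if (any(steps < 1)) stop("all steps must be >= 1", call. = FALSE)
  drop <- steps > kmax_allowed
  if (any(drop)) {
    warning(sprintf("dropping %d step(s) beyond T - 2 = %d",
                    sum(drop), kmax_allowed), call. = FALSE)
    steps <- steps[!drop]
  }
  if (length(steps) == 0) stop("no valid steps remain below T - 2",
                               call. = FALSE)
  sort(unique(steps))
}

# ---- sufficient statistics -------------------------------------------------
# Per trial i and lag k (with T the trial length, n = T - k):
#   S1[i,k]  = sum_{t<=n} a_t          S2[i,k] = sum_{t>k} a_t
#   Sxx[i,k] = sum_{t<=n} a_t^2        Sxy[i,k] = sum_{t<=n} a_t a_{t+k}
#   SxT[i]   = sum_{t<=T} a_t          SxxT[i] = sum_{t<=T} a_t^2
# Both estimators — and every trial-level bootstrap replicate — are linear
# combinations of these, so resampling costs O(N K) instead of O(N K T).
trial_sufficient_stats <- function(trials, steps) {
  N <- nrow(trials)
  T_ <- ncol(trials)
  K <- length(steps)
  S1 <- S2 <- Sxx <- Sxy <- matrix(0, nrow = N, ncol = K)
  SxT <- SxxT <- numeric(N)
  use_fft <- (as.double(K) * T_) > 2e6
  # both estimators are invariant under a common shift; centring on the
  # grand mean keeps the raw sums small and avoids cancellation error
  shift <- mean(trials)
  for (i in seq_len(N)) {
    a <- as.numeric(trials[i, ]) - shift
    cs <- cumsum(a)
    cs2 <- cumsum(a^2)
    SxT[i] <- cs[T_]
    SxxT[i] <- cs2[T_]
    S1[i, ] <- cs[T_ - steps]
    S2[i, ] <- cs[T_] - cs[steps]
    Sxx[i, ] <- cs2[T_ - steps]
    Sxy[i, ] <- lagged_cross_sums(a, steps, use_fft)
  }
  list(steps = steps, T = T_, N = N, S1 = S1, S2 = S2, Sxx = Sxx,
       Sxy = Sxy, SxT = SxT, SxxT = SxxT)
}

# sum_{t=1}^{T-k} a_t a_{t+k} for each k in `steps`
lagged_cross_sums <- function(a, steps, use_fft = FALSE) {
  T_ <- length(a)
  if (!use_fft) {
    return(vapply(steps, function(k) {
      sum(a[seq_len(T_ - k)] * a[seq_len(T_ - k) + k])
    }, numeric(1)))
  }
  L <- stats::nextn(2L * T_, 2)
  f <- stats::fft(c(a, rep(0, L - T_)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / L
  ac[steps + 1L]
}

# Point estimate (and per-trial slopes for ts) from sufficient statistics,
# for the multiset of trial indices `idx` (bootstrap resamples repeat rows).
estimate_from_stats <- function(st, idx, method) {
  n <- st$T - st$steps  # vector over k
  if (method == "trialseparated") {
    num <- st$Sxy - st$S1 * st$S2 / rep(n, each = st$N)
    den <- st$Sxx - st$S1^2 / rep(n, each = st$N)
    trial_r <- num / den
    list(r = colMeans(trial_r[idx, , drop = FALSE]),
         trial_r = trial_r)
  } else {
    m <- length(idx)
    S1 <- colSums(st$S1[idx, , drop = FALSE])
    S2 <- colSums(st$S2[idx, , drop = FALSE])
    Sxy <- colSums(st$Sxy[idx, , drop = FALSE])
    SxT <- sum(st$SxT[idx])
    SxxT <- sum(st$SxxT[idx])
    xbar <- S1 / (m * n)
    ybar <- S2 / (m * n)
    num <- (Sxy - xbar * S2 - ybar * S1 + m * n * xbar * ybar) / n
    den <- (SxxT - 2 * xbar * SxT + m * st$T * xbar^2) / st$T
    list(r = num / den, trial_r = NULL)
  }
}

bootstrap_coefficient_samples <- function(st, method, numboot, seed) {
  streams <- rng_substreams(seed, numboot)
  out <- matrix(0, nrow = numboot, ncol = length(st$steps))
  for (b in seq_len(numboot)) {
    idx <- with_rng_stream(streams[[b]],
                           sample.int(st$N, st$N, replace = TRUE))
    out[b, ] <- estimate_from_stats(st, idx, method)$r
  }
  out
}

#' @export
print.mr_coefficients <- function(x, ...) {
  cat(sprintf("<mr_coefficients> %s method, %d steps (k = %d..%d), dt = %g %s\n",
              x$method, length(x$steps), min(x$steps), max(x$steps),
              x$dt, x$dtunit))
  cat(sprintf("  %d trials x %d bins; r_1 = %.4g%s\n",
              x$num_trials, x$trial_length, x$coefficients[1],
              if (!is.null(x$stderrs))
                sprintf(" (bootstrap se %.2g, %d resamples)",
                        x$stderrs[1], x$numboot) else ""))
  invisible(x)
}

#' Tidy view of estimated correlation coefficients
#'
#' @param x an `mr_coefficients` object.
#' @param ... unused.
#' @return a tibble with columns `step` (k), `lag` (k * dt, in `dtunit`s),
#'   `coefficient` (r_k) and, when bootstrapped, `stderr`.
#' @export
#' @exportS3Method generics::tidy
tidy.mr_coefficients <- function(x, ...) {
  out <- tibble::tibble(step = x$steps, lag = x$steps * x$dt,
                        coefficient = x$coefficients)
  if (!is.null(x$stderrs)) out$stderr <- x$stderrs
  out
}

#' @export
#' @exportS3Method generics::glance
glance.mr_coefficients <- function(x, ...) {
  tibble::tibble(method = x$method, num_steps = length(x$steps),
                 kmin = min(x$steps), kmax = max(x$steps),
                 num_trials = x$num_trials, trial_length = x$trial_length,
                 dt = x$dt, dtunit = x$dtunit, numboot = x$numboot)
}
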