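#' Trial-level bootstrap resampling
#'
#' Each trial is one resampling unit: a bootstrap sample draws `N` trials
#' with replacement and applies `statistic` to the resampled set. This keeps
#' within-trial temporal correlations intact and is the construction behind
#' every confidence interval in the package. With a single trial no
#' resampling is possible — cut the series into chunks first
#' ([chunk_into_trials()]).
#'
#' @param x either a [trial_array()] (the statistic receives a resampled
#'   trial array) or a vector / matrix of per-trial values (the statistic
#'   receives the resampled subset; rows index trials for a matrix).
#' @param statistic a function of one argument returning a numeric scalar or
#'   vector of fixed length.
#' @param numboot number of bootstrap samples (>= 1).
#' @param seed integer seed; `NULL` draws one. Each replicate uses its own
#'   RNG substream, so results for replicate `b` do not depend on `numboot`.
#' @return a numeric vector (scalar statistic) or matrix with `numboot` rows.
#' @examples
#' means <- c(0, 10)
#' bootstrap_trials(means, mean, numboot = 8, seed = 1)
#' @export
bootstrap_trials <- function(x, statistic, numboot, seed = NULL) {
  numboot <- as.integer(numboot)
  if (is.na(numboot) || numboot < 1) stop("`numboot` must be >= 1",
                                          call. = FALSE)
  n <- if (is_trial_array(x) || is.matrix(x)) nrow(x) else length(x)
  if (n < 2) {
    stop("bootstrap resampling needs at least 2 trials; for a single long ",
         "recording, create an artificial trial structure with ",
         "chunk_into_trials() first", call. = FALSE)
  }
  seed <- resolve_seed(seed)
  streams <- rng_substreams(seed, numboot)
  take <- function(idx) {
    if (is_trial_array(x)) {
      trial_array(as.matrix(x)[idx, , drop = FALSE], dt = attr(x, "dt"),
                  dtunit = attr(x, "dtunit"))
    } else if (is.matrix(x)) {
      x[idx, , drop = FALSE]
    } else {
      x[idx]
    }
  }
  out <- vector("list", numboot)
  for (b in seq_len(numboot)) {
    idx <- with_rng_stream(streams[[b]], sample.int(n, n, replace = TRUE))
    val <- tryCatch(statistic(take(idx)), error = function(e) {
      stop(sprintf("statistic failed on bootstrap resample %d: %s",
                   b, conditionMessage(e)), call. = FALSE)
    })
    out[[b]] <- as.numeric(val)
  }
  lens <- lengths(out)
  if (any(lens != lens[1])) {
    stop("statistic returned values of varying length across resamples",
         call. = FALSE)
  }
  if (lens[1] == 1) unlist(out) else do.call(rbind, out)
}

#' Percentile bootstrap confidence interval
#'
#' Empirical quantiles of the bootstrap distribution at `(1 - level)/2` and
#' `1 - (1 - level)/2` (linear-interpolation quantiles, [stats::quantile()]
#' type 7). The package default level is 0.75, i.e. the 12.5% and 87.5%
#' quantiles.
#'
#' @param samples numeric vector of bootstrap values (>= 2).
#' @param level confidence level in (0, 1).
#' @return named numeric `c(lower, upper)`, with `lower <= upper`.
#' @examples
#' percentile_ci(1:1000, level = 0.75)  # c(125.875, 875.125)
#' @export
percentile_ci <- function(samples, level = 0.75) {
  if (length(samples) < 2) {
    stop("need at least 2 bootstrap samples for a confidence interval",
         call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(samples, probs = c(alpha, 1 - alpha), names = FALSE,
                       type = 7)
  stats::setNames(q, c("lower", "upper"))
}
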