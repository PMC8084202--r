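#' Trial-structured activity array
#'
#' The canonical exchange format of mrtau: a numeric matrix whose first index
#' labels the trial and whose second index labels the time bin, together with
#' the bin size `dt` and a free-text unit label `dtunit`. All trials share the
#' same length and the same `dt`. Counts produced by the simulator or by spike
#' binning are non-negative integers; imported data may be any finite numeric.
#'
#' @param values numeric matrix, trials in rows, time bins in columns. A plain
#'   vector is promoted to a single-trial matrix.
#' @param dt bin size in `dtunit`s (> 0).
#' @param dtunit free-text unit label, e.g. `"ms"` or `"steps"`.
#' @return an object of class `trial_array` (a matrix with `dt`/`dtunit`
#'   attributes).
#' @examples
#' ta <- trial_array(matrix(rpois(40, 5), nrow = 4), dt = 4, dtunit = "ms")
#' ntrials(ta)
#' @export
trial_array <- function(values, dt = 1, dtunit = "steps") {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), nrow = 1)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (trials x time bins)",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("trial values must be finite and non-missing", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  structure(values, dt = as.numeric(dt), dtunit = as.character(dtunit)[1],
            class = c("trial_array", class(matrix())))
}

#' @export
is_trial_array <- function(x) inherits(x, "trial_array")

#' Number of trials / time bins of a trial array
#' @param x a [trial_array()].
#' @return integer count.
#' @export
ntrials <- function(x) nrow(x)

#' @rdname ntrials
#' @export
ntime <- function(x) ncol(x)

#' Bin size and unit of a trial array or result object
#' @param x a [trial_array()], coefficient result or fit result.
#' @return `dt_of()` the numeric bin size; `dtunit_of()` the unit label.
#' @export
dt_of <- function(x) {
  if (is_trial_array(x)) attr(x, "dt") else x$dt
}

#' @rdname dt_of
#' @export
dtunit_of <- function(x) {
  if (is_trial_array(x)) attr(x, "dtunit") else x$dtunit
}

#' @export
print.trial_array <- function(x, ...) {
  cat(sprintf("<trial_array> %d trial%s x %d time bins (dt = %g %s)\n",
              nrow(x), if (nrow(x) == 1) "" else "s", ncol(x),
              attr(x, "dt"), attr(x, "dtunit")))
  cat(sprintf("  activity: mean %.4g, range [%g, %g]\n",
              mean(x), min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.trial_array <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y), dimnames = dimnames(y))
  y
}

#' Long-format view of a trial array
#'
#' @param x a [trial_array()].
#' @param ... unused.
#' @return a tibble with columns `trial`, `step`, `time` (= step * dt) and
#'   `activity`, one row per trial and bin.
#' @export
#' @exportS3Method generics::tidy
tidy.trial_array <- function(x, ...) {
  dt <- attr(x, "dt")
  tibble::tibble(
    trial = rep(seq_len(nrow(x)), times = ncol(x)),
    step = rep(seq_len(ncol(x)), each = nrow(x)),
    time = rep(seq_len(ncol(x)), each = nrow(x)) * dt,
    activity = as.vector(x)
  ) |> dplyr::arrange(.data$trial, .data$step)
}

#' Per-trial activity summary
#'
#' Mean and standard deviation of the activity of each trial; systematic
#' drifts across trials show up here before they bias the stationary-mean
#' coefficient estimator.
#'
#' @param x a [trial_array()].
#' @param ... unused.
#' @return a tibble with one row per trial: `trial`, `mean`, `sd`, `length`.
#' @export
#' @exportS3Method generics::glance
glance.trial_array <- function(x, ...) {
  tibble::tibble(
    trial = seq_len(nrow(x)),
    mean = apply(x, 1, mean),
    sd = apply(x, 1, stats::sd),
    length = ncol(x)
  )
}

# Validate that values look like counts (simulation / binning outputs).
assert_counts <- function(x, what = "activity") {
  if (any(x < 0) || any(x != floor(x))) {
    stop(sprintf("%s must contain non-negative integer counts", what),
         call. = FALSE)
  }
  invisible(x)
}
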