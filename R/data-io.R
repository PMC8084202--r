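#' Coerce assorted inputs into a trial array
#'
#' Accepts the formats practitioners actually have at hand and converts them
#' to the canonical trials-x-time [trial_array()]:
#' \itemize{
#'   \item a plain numeric vector: one trial;
#'   \item a numeric matrix: taken as trials x time (first index = trial);
#'   \item a list of equal-length numeric vectors: one trial per element;
#'   \item a data frame: one trial per column (file-like layout);
#'   \item one or more file paths, wildcards allowed: whitespace- or
#'     comma-delimited numeric text, `#`-prefixed lines ignored, one trial
#'     per column, files concatenated as additional trials.
#' }
#'
#' @param source the input data (see above).
#' @param usecols optional 1-based column selection for file and data-frame
#'   input, e.g. `usecols = c(1, 2, 3)` keeps the first three columns.
#'   (Note: 1-based, following R convention.)
#' @param dt,dtunit time-bin metadata attached to the result; when `source`
#'   is already a [trial_array()] its own metadata wins unless overridden.
#' @return a [trial_array()].
#' @examples
#' input_handler(list(c(1, 2, 3), c(4, 5, 6)))
#' input_handler(1:4)
#' @export
input_handler <- function(source, usecols = NULL, dt = 1, dtunit = "steps") {
  if (is_trial_array(source)) {
    return(trial_array(as.matrix(source), dt = attr(source, "dt"),
                       dtunit = attr(source, "dtunit")))
  }
  if (is.character(source)) {
    return(read_trial_files(source, usecols = usecols, dt = dt,
                            dtunit = dtunit))
  }
  if (is.data.frame(source)) {
    m <- as.matrix(source)
    if (!is.numeric(m)) stop("data frame input must be all-numeric",
                             call. = FALSE)
    if (!is.null(usecols)) m <- m[, usecols, drop = FALSE]
    return(trial_array(t(m), dt = dt, dtunit = dtunit))
  }
  if (is.matrix(source)) {
    return(trial_array(source, dt = dt, dtunit = dtunit))
  }
  if (is.list(source)) {
    lens <- vapply(source, length, integer(1))
    if (length(unique(lens)) != 1) {
      bad <- which(lens != lens[1])[1]
      stop(sprintf(paste0("all trials must have the same length: trial %d ",
                          "has %d samples, trial 1 has %d"),
                   bad, lens[bad], lens[1]), call. = FALSE)
    }
    return(trial_array(do.call(rbind, lapply(source, as.numeric)),
                       dt = dt, dtunit = dtunit))
  }
  if (is.numeric(source)) {
    return(trial_array(matrix(as.numeric(source), nrow = 1),
                       dt = dt, dtunit = dtunit))
  }
  stop("cannot interpret `source` as trial-structured data", call. = FALSE)
}

read_trial_files <- function(paths, usecols = NULL, dt = 1,
                             dtunit = "steps") {
  files <- unlist(lapply(paths, function(p) {
    hits <- Sys.glob(p)
    if (length(hits) == 0 && file.exists(p)) hits <- p
    hits
  }))
  if (length(files) == 0) {
    stop(sprintf("no files match '%s'", paste(paths, collapse = "', '")),
         call. = FALSE)
  }
  trials <- list()
  for (f in files) {
    cols <- read_numeric_columns(f)
    if (!is.null(usecols)) cols <- cols[, usecols, drop = FALSE]
    for (j in seq_len(ncol(cols))) trials[[length(trials) + 1L]] <- cols[, j]
  }
  lens <- vapply(trials, length, integer(1))
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf("all trials must have the same length: trial %d has %d samples, trial 1 has %d",
                 bad, lens[bad], lens[1]), call. = FALSE)
  }
  trial_array(do.call(rbind, trials), dt = dt, dtunit = dtunit)
}

# Whitespace- or comma-delimited numeric text; '#' lines are comments.
read_numeric_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  if (length(body) == 0) {
    stop(sprintf("'%s' contains no data lines", path), call. = FALSE)
  }
  linenos <- which(keep)
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("'%s' line %d: expected %d columns, found %d",
                 path, linenos[bad], ncols[1], ncols[bad]), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(ncols[1])))
  vals <- if (ncols[1] == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop(sprintf("'%s' line %d: non-numeric content", path, linenos[bad]),
         call. = FALSE)
  }
  vals
}

#' Bin spike time stamps into an activity time series
#'
#' Converts a list of event time stamps (e.g. spike times from an
#' electrophysiology recording, in arbitrary time units) into binned
#' activity: bin `floor(t / bin_size) + 1` is incremented for each spike at
#' time `t`, and the vector has `ceiling(last_spike / bin_size)` bins. A
#' spike falling exactly on the upper edge of the final bin is clamped into
#' that bin so that the total spike count is conserved.
#'
#' @param spikes numeric vector of spike times, all `>= 0`.
#' @param bin_size width of a time bin, same units as `spikes` (> 0).
#' @return integer vector of per-bin spike counts.
#' @examples
#' bin_spike_times(c(0.1, 0.2, 5.5), bin_size = 1)
#' @export
bin_spike_times <- function(spikes, bin_size) {
  if (length(spikes) == 0) stop("no spike times given", call. = FALSE)
  if (!is.numeric(spikes) || anyNA(spikes)) {
    stop("spike times must be numeric and non-missing", call. = FALSE)
  }
  if (any(spikes < 0)) stop("spike times must be >= 0", call. = FALSE)
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    stop("`bin_size` must be a single positive number", call. = FALSE)
  }
  num_bins <- max(1L, as.integer(ceiling(max(spikes) / bin_size)))
  idx <- pmin(as.integer(floor(spikes / bin_size)), num_bins - 1L) + 1L
  as.integer(tabulate(idx, nbins = num_bins))
}

#' Cut one long recording into artificial trials
#'
#' Long continuous recordings (e.g. resting state) carry no trial structure,
#' which rules out trial-level bootstrapping. Splitting the series into
#' equal-length chunks creates an artificial trial structure: trial length is
#' `floor(length(series) / numtrials)` and any trailing remainder samples are
#' discarded.
#'
#' @param series numeric activity vector.
#' @param numtrials number of chunks (>= 1, <= `length(series)`).
#' @param dt,dtunit time-bin metadata for the result.
#' @return a [trial_array()] with `numtrials` rows.
#' @examples
#' chunk_into_trials(1:103, numtrials = 25)
#' @export
chunk_into_trials <- function(series, numtrials, dt = 1, dtunit = "steps") {
  series <- as.numeric(series)
  numtrials <- as.integer(numtrials)
  if (is.na(numtrials) || numtrials < 1) {
    stop("`numtrials` must be >= 1", call. = FALSE)
  }
  if (numtrials > length(series)) {
    stop(sprintf("cannot cut %d samples into %d trials",
                 length(series), numtrials), call. = FALSE)
  }
  len <- length(series) %/% numtrials
  kept <- series[seq_len(numtrials * len)]
  trial_array(matrix(kept, nrow = numtrials, ncol = len, byrow = TRUE),
              dt = dt, dtunit = dtunit)
}

#' Write a trial array to delimited text
#'
#' One column per trial, tab-separated, `#`-prefixed header lines carrying
#' `dt`, `dtunit` and the shape; full double precision so that
#' [input_handler()] round-trips the values exactly.
#'
#' @param trials a [trial_array()].
#' @param path output file path.
#' @param extra_header optional character vector of additional header lines
#'   (written `#`-prefixed).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, extra_header = NULL) {
  if (!is_trial_array(trials)) trials <- input_handler(trials)
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c(sprintf("mrtau trial array: %d trials x %d time bins",
                   nrow(trials), ncol(trials)),
           sprintf("dt = %.17g", attr(trials, "dt")),
           sprintf("dtunit = %s", attr(trials, "dtunit")),
           extra_header)
  writeLines(paste0("# ", hdr), con)
  body <- apply(t(trials), 1, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}
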