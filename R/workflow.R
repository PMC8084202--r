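#' One-call analysis: coefficients, fits, confidence intervals
#'
#' Runs the whole multi-step regression pipeline on trial-structured
#' activity: [input_handler()] to coerce the data, [coefficients()] for
#' steps `1..kmax`, one [fit()] per requested fit function, trial-level
#' bootstrap confidence intervals throughout, and (optionally) a report
#' written to `targetdir`. The coefficient method has no hidden default —
#' the choice between trial-separated and stationary-mean encodes an
#' assumption about the data (stationarity across trials) that the caller
#' must make; as a rule of thumb, use trials at least 10 times longer than
#' an a-priori timescale estimate before trusting the trial-separated
#' method, and compare both.
#'
#' @param data anything [input_handler()] accepts.
#' @param dt,dtunit bin size and unit of the time steps.
#' @param kmax largest lag; coefficients are estimated for `1..kmax`.
#' @param coefficientmethod `"trialseparated"`/`"ts"` or
#'   `"stationarymean"`/`"sm"` (required, no default).
#' @param fitfuncs character vector of fit-function labels
#'   (default `"exponential_offset"`).
#' @param numboot bootstrap replicates (default 100; needs >= 2 trials).
#' @param seed master seed; coefficient and fit stages derive independent
#'   substreams from it.
#' @param level confidence level for all intervals (default 0.75).
#' @param targetdir if given, [save_report()] writes the results there.
#' @param usecols optional 1-based column selection for file input.
#' @param overview_plot also write the four-panel overview figure when
#'   saving (needs a working graphics device; default `FALSE`).
#' @return an object of class `mr_report` bundling the coefficient result,
#'   the list of fit results, a per-trial activity summary, and the full
#'   provenance (all parameters and seeds needed to reproduce the numbers).
#' @examples
#' bp <- simulate_branching(m = 0.95, a = 100, length = 1000, numtrials = 5,
#'                          seed = 5)
#' rep <- full_analysis(bp, dt = 1, dtunit = "steps", kmax = 60,
#'                      coefficientmethod = "ts", numboot = 50, seed = 6)
#' glance(rep)
#' @export
full_analysis <- function(data, dt = 1, dtunit = "steps", kmax = 1000,
                          coefficientmethod, fitfuncs = "exponential_offset",
                          numboot = 100, seed = NULL, level = 0.75,
                          targetdir = NULL, usecols = NULL,
                          overview_plot = FALSE) {
  if (missing(coefficientmethod)) {
    stop("`coefficientmethod` must be given explicitly ('ts' or 'sm'): the ",
         "stationary-mean method assumes stationarity across trials, the ",
         "trial-separated method needs trials much longer than the timescale",
         call. = FALSE)
  }
  if (length(fitfuncs) == 0) stop("`fitfuncs` must not be empty",
                                  call. = FALSE)
  method <- match_method(coefficientmethod)
  fit_names <- vapply(fitfuncs, match_fitfunc, character(1),
                      USE.NAMES = FALSE)
  seed <- resolve_seed(seed)
  stage_seeds <- derive_seeds(seed, 2L)

  trials <- with_stage("input_handler",
                       input_handler(data, usecols = usecols, dt = dt,
                                     dtunit = dtunit))
  if (nrow(trials) < 2 && numboot > 0) {
    stop("full_analysis: a single trial supports no bootstrap error ",
         "estimate; cut the series into artificial trials with ",
         "chunk_into_trials() or pass numboot = 0", call. = FALSE)
  }
  rk <- with_stage("coefficients",
                   coefficients(trials, steps = c(1L, as.integer(kmax)),
                                method = method, dt = dt, dtunit = dtunit,
                                numboot = numboot, seed = stage_seeds[1]))
  fits <- stats::setNames(vector("list", length(fit_names)), fit_names)
  for (i in seq_along(fit_names)) {
    fits[[i]] <- with_stage(paste0("fit[", fit_names[i], "]"),
                            fit(rk, fitfunc = fit_names[i], level = level,
                                seed = stage_seeds[2]))
  }

  report <- structure(
    list(coefficients = rk, fits = fits,
         trial_summary = glance.trial_array(trials),
         provenance = list(
           package = "mrtau",
           version = as.character(utils::packageVersion("mrtau")),
           dt = dt, dtunit = dtunit, kmax = as.integer(kmax),
           coefficientmethod = method, fitfuncs = fit_names,
           numboot = numboot, seed = seed,
           coefficient_seed = rk$seed, level = level,
           num_trials = nrow(trials), trial_length = ncol(trials),
           input = describe_input(data))),
    class = "mr_report")
  if (!is.null(targetdir)) {
    dir.create(targetdir, recursive = TRUE, showWarnings = FALSE)
    save_report(report, file.path(targetdir, "mrtau_result"),
                overview = overview_plot)
  }
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

describe_input <- function(data) {
  if (is.character(data)) paste(data, collapse = ", ")
  else if (is_trial_array(data)) sprintf("trial_array %dx%d", nrow(data),
                                         ncol(data))
  else sprintf("in-memory %s", paste(class(data)[1], collapse = "/"))
}

#' Persist an analysis report as plain text
#'
#' Writes `<path_stub>.tsv` — a `#`-headed provenance block (every parameter
#' and seed needed to reproduce the run) followed by the columns `k`,
#' `k_dt`, `r_k`, `stderr` and one fitted-model column per fit — and
#' `<path_stub>_fits.tsv` with the per-parameter estimates and confidence
#' bounds. Values are written at full double precision so a re-read
#' reproduces them exactly. The only nondeterministic header line is the
#' timestamp.
#'
#' @param report an `mr_report` from [full_analysis()].
#' @param path_stub output path without extension.
#' @param overview also write a four-panel overview figure
#'   (`<path_stub>.pdf`): activity, per-trial means, coefficients with fit
#'   curves, and the estimates as text.
#' @return the paths written, invisibly.
#' @export
save_report <- function(report, path_stub, overview = FALSE) {
  dir <- dirname(path_stub)
  if (!dir.exists(dir)) {
    stop(sprintf("target directory '%s' does not exist", dir), call. = FALSE)
  }
  rk <- report$coefficients
  prov <- report$provenance
  data_path <- paste0(path_stub, ".tsv")
  fits_path <- paste0(path_stub, "_fits.tsv")

  hdr <- c("mrtau analysis report",
           sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           vapply(names(prov), function(nm) {
             sprintf("%s = %s", nm, paste(format(prov[[nm]], digits = 17),
                                          collapse = ", "))
           }, character(1)))

  fitted_cols <- lapply(report$fits, function(ft) {
    if (identical(ft$fitfunc, "log_slope")) {
      rep(NA_real_, length(rk$steps))
    } else {
      evaluate_fitfunc(ft$fitfunc, rk$steps * rk$dt, ft$params)
    }
  })
  tab <- cbind(k = rk$steps, k_dt = rk$steps * rk$dt, r_k = rk$coefficients,
               stderr = if (is.null(rk$stderrs)) NA_real_ else rk$stderrs)
  for (nm in names(fitted_cols)) {
    tab <- cbind(tab, fitted_cols[[nm]])
    colnames(tab)[ncol(tab)] <- paste0("fit_", nm)
  }

  con <- file(data_path, open = "wt")
  writeLines(paste0("# ", hdr), con)
  writeLines(paste0("# ", paste(colnames(tab), collapse = "\t")), con)
  writeLines(apply(tab, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  }), con)
  close(con)

  fit_tab <- purrr::map_dfr(names(report$fits), function(nm) {
    ft <- report$fits[[nm]]
    td <- tidy.mr_fit(ft)
    td$fitfunc <- nm
    extra <- tibble::tibble(
      term = c("tau", "mre"),
      estimate = c(ft$tau, ft$mre),
      fitfunc = nm)
    if (!is.null(ft$tau_ci)) {
      extra$ci_lower <- c(ft$tau_ci[1], ft$mre_ci[1])
      extra$ci_upper <- c(ft$tau_ci[2], ft$mre_ci[2])
    }
    extra$term <- c("tau_hat", "m_hat")
    dplyr::bind_rows(td, extra)
  })
  utils::write.table(
    format(as.data.frame(fit_tab), digits = 17),
    fits_path, sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- c(data_path, fits_path)
  if (overview) {
    fig_path <- paste0(path_stub, ".pdf")
    grDevices::pdf(fig_path, width = 9, height = 7)
    print(autoplot.mr_report(report))
    grDevices::dev.off()
    paths <- c(paths, fig_path)
  }
  invisible(paths)
}

#' Read back the data file written by [save_report()]
#'
#' @param path the `.tsv` file written by [save_report()].
#' @return a tibble with columns `k`, `k_dt`, `r_k`, `stderr` and the
#'   fitted-model columns.
#' @export
read_report_data <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  cols <- strsplit(sub("^#\\s*", "", hdr[length(hdr)]), "\t")[[1]]
  vals <- read_numeric_columns(path)
  colnames(vals) <- cols
  tibble::as_tibble(as.data.frame(vals))
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %s coefficients, k = %d..%d, %d trial(s) x %d bins\n",
              x$coefficients$method, min(x$coefficients$steps),
              max(x$coefficients$steps), x$provenance$num_trials,
              x$provenance$trial_length))
  for (nm in names(x$fits)) {
    ft <- x$fits[[nm]]
    if (identical(ft$fitfunc, "log_slope")) {
      cat(sprintf("  %s: supercritical, m_hat = %.4g\n", nm, ft$mre))
    } else {
      cat(sprintf("  %s: tau = %.4g %s, m = %.4g\n", nm, ft$tau, ft$dtunit,
                  ft$mre))
    }
  }
  invisible(x)
}

#' Summaries of an analysis report
#'
#' @param x an `mr_report`.
#' @param ... unused.
#' @return `glance()`: one row per fitted model (via [glance.mr_fit()]);
#'   `tidy()`: the coefficient table (via [tidy.mr_coefficients()]).
#' @export
#' @exportS3Method generics::glance
glance.mr_report <- function(x, ...) {
  purrr::map_dfr(x$fits, glance.mr_fit)
}

#' @rdname glance.mr_report
#' @export
#' @exportS3Method generics::tidy
tidy.mr_report <- function(x, ...) {
  tidy.mr_coefficients(x$coefficients)
}
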