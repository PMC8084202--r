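test_that("full_analysis equals the manually chained pipeline", {
  bp <- simulate_branching(m = 0.95, a = 100, length = 1500, numtrials = 5,
                           seed = 61)
  rep_ <- full_analysis(bp, dt = 1, dtunit = "steps", kmax = 80,
                        coefficientmethod = "ts",
                        fitfuncs = c("exp", "exp_offset"),
                        numboot = 50, seed = 62)
  # replay by hand with the stage seed recorded in the provenance
  rk <- coefficients(input_handler(bp), steps = c(1, 80), method = "ts",
                     numboot = 50, seed = rep_$provenance$coefficient_seed)
  expect_identical(rk$coefficients, rep_$coefficients$coefficients)
  expect_identical(rk$bootstrap_samples,
                   rep_$coefficients$bootstrap_samples)
  ft <- fit(rk, "exponential_offset", level = 0.75)
  expect_identical(ft$params, rep_$fits$exponential_offset$params)
  expect_identical(ft$tau_ci, rep_$fits$exponential_offset$tau_ci)
  # fits are keyed by canonical names, in request order
  expect_identical(names(rep_$fits), c("exponential", "exponential_offset"))
})

test_that("the coefficient method must be chosen explicitly", {
  bp <- simulate_branching(m = 0.9, a = 50, length = 200, numtrials = 3,
                           seed = 9)
  expect_error(full_analysis(bp, kmax = 20), "coefficientmethod")
  expect_error(full_analysis(bp, kmax = 20, coefficientmethod = "ts",
                             fitfuncs = character(0)), "empty")
})

test_that("a single trial with bootstrapping requested is refused with advice", {
  expect_error(
    full_analysis(rpois(500, 20), kmax = 20, coefficientmethod = "ts",
                  numboot = 50),
    "chunk_into_trials")
  # but runs fine with numboot = 0 (uncorrelated noise: tau hits its bound,
  # which the fit flags)
  suppressWarnings(
    rep_ <- full_analysis(rpois(500, 20), kmax = 5, coefficientmethod = "ts",
                          numboot = 0, seed = 3))
  expect_s3_class(rep_, "mr_report")
})

test_that("stage failures are labelled with the failing stage", {
  expect_error(
    full_analysis(list(1:10, 1:11), kmax = 3, coefficientmethod = "ts",
                  numboot = 0),
    "\\[input_handler\\]")
})

test_that("saved reports round-trip coefficients exactly and carry provenance", {
  dir <- withr::local_tempdir()
  bp <- simulate_branching(m = 0.9, a = 100, length = 600, numtrials = 4,
                           seed = 81)
  rep_ <- full_analysis(bp, dt = 4, dtunit = "ms", kmax = 40,
                        coefficientmethod = "sm", numboot = 30, seed = 82,
                        targetdir = dir)
  data_path <- file.path(dir, "mrtau_result.tsv")
  expect_true(file.exists(data_path))
  expect_true(file.exists(file.path(dir, "mrtau_result_fits.tsv")))

  back <- read_report_data(data_path)
  expect_identical(back$r_k, unname(rep_$coefficients$coefficients))
  expect_identical(back$k_dt, rep_$coefficients$steps * 4)
  expect_identical(back$stderr, unname(rep_$coefficients$stderrs))
  # fitted-model column evaluates the stored parameters
  ft <- rep_$fits$exponential_offset
  expect_equal(back$fit_exponential_offset,
               evaluate_fitfunc("eo", back$k_dt, ft$params))

  hdr <- readLines(data_path)
  hdr <- hdr[grepl("^#", hdr)]
  for (key in c("dt", "dtunit", "kmax", "coefficientmethod", "fitfuncs",
                "numboot", "seed", "coefficient_seed", "level",
                "num_trials", "trial_length", "version")) {
    expect_true(any(grepl(paste0("^# ", key, " = "), hdr)),
                info = key)
  }

  # determinism: a re-run with the same seed writes identical numbers
  dir2 <- withr::local_tempdir()
  full_analysis(bp, dt = 4, dtunit = "ms", kmax = 40,
                coefficientmethod = "sm", numboot = 30, seed = 82,
                targetdir = dir2)
  strip_ts <- function(p) {
    l <- readLines(p)
    l[!grepl("^# timestamp", l)]
  }
  expect_identical(strip_ts(data_path),
                   strip_ts(file.path(dir2, "mrtau_result.tsv")))
})

test_that("report accessors and plots are well-formed", {
  bp <- simulate_branching(m = 0.9, a = 100, length = 500, numtrials = 4,
                           seed = 91)
  rep_ <- full_analysis(bp, kmax = 30, coefficientmethod = "ts",
                        numboot = 20, seed = 92)
  gl <- glance(rep_)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$fitfunc, "exponential_offset")
  td <- tidy(rep_)
  expect_identical(nrow(td), 30L)
  expect_identical(nrow(rep_$trial_summary), 4L)

  expect_s3_class(autoplot(bp), "ggplot")
  expect_s3_class(autoplot(rep_$coefficients, fits = rep_$fits), "ggplot")
  expect_no_error(autoplot(rep_, trials = bp))
})

test_that("binned oscillating spike data resolves the oscillation frequency", {
  # synthetic theta-like modulation: an AR(1) population rate multiplied by
  # a sinusoid; the complex fit must pick up the frequency that the plain
  # exponential cannot represent
  set.seed(123)
  nu_true <- 0.02   # cycles per bin
  T_ <- 12000
  drive <- as.vector(simulate_branching(m = 0.9, a = 40, length = T_,
                                        seed = 7))
  rate <- drive * (1 + 0.6 * sin(2 * pi * nu_true * seq_len(T_)))
  act <- rpois(T_, rate)
  trials <- chunk_into_trials(act, 12)
  rep_ <- full_analysis(trials, dt = 1, dtunit = "steps", kmax = 250,
                        coefficientmethod = "ts",
                        fitfuncs = c("exponential_offset", "complex"),
                        numboot = 0, seed = 8)
  cx <- rep_$fits$complex
  expect_lt(rel_err(cx$params[["nu"]], nu_true), 0.1)
  expect_lt(cx$ssres, rep_$fits$exponential_offset$ssres)
})
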