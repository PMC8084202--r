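#' Convert between branching parameter and intrinsic timescale
#'
#' For a stationary first-order autoregressive (branching) process the
#' autocorrelation decays as `r_k = m^k = exp(-k dt / tau)`, giving
#' \deqn{\tau = -\Delta t / \ln m, \qquad m = e^{-\Delta t/\tau}.}
#' `tau` is the physical observable (independent of the bin size), `m` the
#' per-step causal interpretation (depends on `dt`): `m < 1` subcritical,
#' `m = 1` critical, `m > 1` supercritical.
#'
#' @param m branching parameter in (0, 1).
#' @param tau intrinsic timescale, > 0 (in `dtunit`s).
#' @param dt bin size (> 0), same unit as `tau`.
#' @return `tau_from_m()` the timescale; `m_from_tau()` the branching
#'   parameter. Exact inverses of each other on their domains.
#' @examples
#' tau_from_m(0.98, dt = 1)   # ~49.5 steps
#' m_from_tau(49.5, dt = 1)   # ~0.98
#' @export
tau_from_m <- function(m, dt = 1) {
  if (any(!is.finite(m)) || any(m <= 0) || any(m >= 1)) {
    stop("`m` must lie strictly in (0, 1): tau diverges at m = 1 and is ",
         "undefined for m >= 1 or m <= 0", call. = FALSE)
  }
  if (any(dt <= 0)) stop("`dt` must be > 0", call. = FALSE)
  -dt / log(m)
}

#' @rdname tau_from_m
#' @export
m_from_tau <- function(tau, dt = 1) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be > 0", call. = FALSE)
  }
  if (any(dt <= 0)) stop("`dt` must be > 0", call. = FALSE)
  exp(-dt / tau)
}

# ---- fit function registry -------------------------------------------------

FIT_LABELS <- list(
  exponential = c("exponential", "e", "exp"),
  exponential_offset = c("exponential_offset", "eo", "exp_offset", "exp_off"),
  complex = c("complex", "c", "cplx")
)

match_fitfunc <- function(label) {
  for (nm in names(FIT_LABELS)) {
    if (label %in% FIT_LABELS[[nm]]) return(nm)
  }
  stop(sprintf("unknown fit function '%s' (known: %s)", label,
               paste(unlist(FIT_LABELS), collapse = ", ")), call. = FALSE)
}

#' Fit-function specification
#'
#' Returns the definition of one of the built-in autocorrelation models, in
#' physical lag units `l = k * dt`:
#' \itemize{
#'   \item `exponential`: `A * exp(-l / tau)` — the pure subsampled
#'     branching-process form (amplitude `A` absorbs the subsampling bias).
#'   \item `exponential_offset`: `A * exp(-l / tau) + O` — the default; the
#'     offset `O` absorbs slow non-stationarities.
#'   \item `complex`: `D * exp(-l / tau) +
#'     E * exp(-(l / tau_osc)^gamma) * cos(2 * pi * nu * l) +
#'     F * exp(-(l / tau_gauss)^2) + O` — adds a stretched-exponentially
#'     damped cosine (neural oscillations, frequency `nu` in 1/`dtunit`)
#'     and a Gaussian term (refractory short-time dynamics).
#' }
#' Abbreviations accepted: `e`/`exp`, `eo`/`exp_offset`/`exp_off`,
#' `c`/`cplx`.
#'
#' @param label one of the names or abbreviations above.
#' @return a list with `name`, `params` (names in fixed order), `fn(lag,
#'   par)`, and bound/initial-guess rules used by [fit()].
#' @export
fitfunc_spec <- function(label) {
  name <- match_fitfunc(label)
  switch(name,
    exponential = list(
      name = name, params = c("tau", "A"),
      fn = function(lag, p) p[["A"]] * exp(-lag / p[["tau"]])),
    exponential_offset = list(
      name = name, params = c("tau", "A", "O"),
      fn = function(lag, p) p[["A"]] * exp(-lag / p[["tau"]]) + p[["O"]]),
    complex = list(
      name = name,
      params = c("tau", "D", "O", "tau_osc", "E", "gamma", "nu",
                 "tau_gauss", "F"),
      fn = function(lag, p) {
        p[["D"]] * exp(-lag / p[["tau"]]) +
          p[["E"]] * exp(-(lag / p[["tau_osc"]])^p[["gamma"]]) *
            cos(2 * pi * p[["nu"]] * lag) +
          p[["F"]] * exp(-(lag / p[["tau_gauss"]])^2) +
          p[["O"]]
      })
  )
}

#' Evaluate a fit-function at given lags
#'
#' @param spec a [fitfunc_spec()] or a label accepted by it.
#' @param lag numeric vector of physical lags (`k * dt`).
#' @param params named numeric vector/list, complete for the spec.
#' @return model values at `lag`.
#' @examples
#' evaluate_fitfunc("exp", lag = 49.5, params = c(tau = 49.5, A = 1))
#' @export
evaluate_fitfunc <- function(spec, lag, params) {
  if (is.character(spec)) spec <- fitfunc_spec(spec)
  params <- as.list(params)
  missing <- setdiff(spec$params, names(params))
  if (length(missing) > 0) {
    stop(sprintf("missing parameter(s) for %s fit: %s", spec$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  spec$fn(lag, params)
}

# Bounds, in physical lag units. kmaxdt = largest fitted lag.
fit_bounds <- function(spec, kmaxdt, dt) {
  lo <- hi <- stats::setNames(numeric(length(spec$params)), spec$params)
  tau_lo <- 1e-6 * dt
  tau_hi <- 10 * kmaxdt
  for (p in spec$params) {
    switch(p,
      tau = , tau_osc = , tau_gauss = { lo[p] <- tau_lo; hi[p] <- tau_hi },
      A = , D = , E = , F = { lo[p] <- 0; hi[p] <- Inf },
      O = { lo[p] <- -Inf; hi[p] <- Inf },
      gamma = { lo[p] <- 1e-3; hi[p] <- 5 },
      nu = { lo[p] <- 0; hi[p] <- 1 / (2 * dt) })
  }
  list(lower = lo, upper = hi)
}

# Multi-start initial guesses from the data: tau0 log-spaced over the fitted
# lag range, amplitude from the first coefficient, offset from the tail mean,
# oscillation frequency from the zero crossings of the centred coefficients.
fit_inits <- function(spec, lag, r, dt) {
  kmaxdt <- max(lag)
  tau0 <- exp(seq(log(max(dt, 1e-6)), log(kmaxdt), length.out = 6))
  amp0 <- max(r[1], 0.1)
  ntail <- max(1L, ceiling(0.1 * length(r)))
  off0 <- mean(utils::tail(r, ntail))
  starts <- list()
  if (spec$name == "exponential") {
    for (t0 in tau0) starts[[length(starts) + 1]] <- c(tau = t0, A = amp0)
  } else if (spec$name == "exponential_offset") {
    for (t0 in tau0) {
      starts[[length(starts) + 1]] <- c(tau = t0, A = amp0, O = off0)
    }
  } else {
    rc <- r - mean(r)
    crossings <- sum(diff(sign(rc[rc != 0])) != 0)
    span <- max(lag) - min(lag)
    nu0 <- if (crossings >= 2) crossings / (2 * span) else 1 / (4 * span)
    nu_grid <- unique(pmin(pmax(c(0.5, 1, 2) * nu0, 0), 1 / (2 * dt)))
    for (t0 in tau0) {
      for (n0 in nu_grid) {
        starts[[length(starts) + 1]] <- c(
          tau = t0, D = amp0 / 3, O = off0, tau_osc = t0,
          E = amp0 / 3, gamma = 1, nu = n0, tau_gauss = max(2 * dt, t0 / 10),
          F = amp0 / 3)
      }
    }
  }
  starts
}

#' Fit an autocorrelation model to estimated coefficients
#'
#' Nonlinear least squares of one of the built-in models (see
#' [fitfunc_spec()]) against the points `(k * dt, r_k)`. The optimiser
#' (Levenberg-Marquardt with box bounds) is started from a grid of initial
#' guesses and the converged fit with the smallest residual sum of squares
#' wins. The fitted decay time is the intrinsic-timescale estimate
#' `tau_hat`; the derived branching parameter is `m_hat = exp(-dt /
#' tau_hat)`.
#'
#' When the coefficients carry bootstrap samples (or `numboot > 0` is
#' requested here), each bootstrap replicate of the `r_k` is refitted
#' (started from the point estimate) and percentile confidence intervals at
#' `level` are attached for every parameter as well as for `tau` and `m`.
#'
#' If the coefficients grow with the lag — a supercritical process, `m > 1`,
#' for which no finite timescale exists — the exponential fit is not
#' attempted; a log-slope diagnostic reports `m_hat > 1` with `tau = NA` and
#' a warning instead.
#'
#' @param object an `mr_coefficients` object (see [coefficients()]).
#' @param fitfunc model label; default `"exponential_offset"`.
#' @param fitrange optional subset of steps to fit, either `c(kmin, kmax)`
#'   or an explicit vector; must be contained in `object$steps`.
#' @param numboot bootstrap replicates for CIs; `NULL` (default) reuses the
#'   samples already attached to `object`, 0 disables.
#' @param seed seed used only if new bootstrap samples must be drawn.
#' @param level confidence level of the percentile intervals (default 0.75).
#' @param ... unused.
#' @return an object of class `mr_fit` with elements `fitfunc`, `tau`,
#'   `mre` (derived branching parameter), `params`, `ssres`, `ci`,
#'   `tau_ci`, `mre_ci`, `fitrange`, `dt`, `dtunit`, `flags`. Use [tidy()] /
#'   [glance()] for tibble views.
#' @examples
#' bp <- simulate_branching(m = 0.9, a = 200, length = 4000, numtrials = 5,
#'                          seed = 11)
#' rk <- coefficients(bp, steps = c(1, 50), method = "sm", numboot = 50,
#'                    seed = 12)
#' ft <- fit(rk, fitfunc = "exp_offset")
#' glance(ft)
#' @name fit
NULL

#' @rdname fit
#' @export
#' @exportS3Method generics::fit
fit.mr_coefficients <- function(object, fitfunc = "exponential_offset",
                                fitrange = NULL, numboot = NULL, seed = NULL,
                                level = 0.75, ...) {
  spec <- fitfunc_spec(fitfunc)
  keep <- resolve_fitrange(fitrange, object$steps)
  lag <- object$steps[keep] * object$dt
  r <- object$coefficients[keep]
  if (length(r) < length(spec$params) + 1) {
    stop(sprintf("need at least %d coefficient points to fit '%s'",
                 length(spec$params) + 1, spec$name), call. = FALSE)
  }

  sup <- detect_supercritical(lag, r)
  if (!is.null(sup)) {
    warning(sprintf(paste0("coefficients grow with the lag: the process ",
                           "looks supercritical (log-slope m_hat = %.4g > 1); ",
                           "no finite timescale exists"), sup$mre),
            call. = FALSE)
    return(structure(
      list(fitfunc = "log_slope", tau = NA_real_, mre = sup$mre,
           params = c(log_slope = sup$slope), ssres = NA_real_,
           ci = NULL, tau_ci = NULL, mre_ci = NULL,
           fitrange = object$steps[keep], dt = object$dt,
           dtunit = object$dtunit, level = level,
           flags = "supercritical"),
      class = "mr_fit"))
  }

  bounds <- fit_bounds(spec, max(lag), object$dt)
  best <- fit_multistart(spec, lag, r, bounds,
                         fit_inits(spec, lag, r, object$dt))
  if (is.null(best$par)) {
    stop(sprintf(paste0("the %s fit did not converge from any of %d starts; ",
                        "best residual norm %.4g"),
                 spec$name, best$nstarts, best$ssres), call. = FALSE)
  }
  flags <- character(0)
  if (best$par[["tau"]] > 0.99 * bounds$upper[["tau"]]) {
    flags <- c(flags, "tau_at_bound")
    warning("fitted tau is pinned at its upper bound; the fit range likely ",
            "does not resolve the decay", call. = FALSE)
  }

  res <- structure(
    list(fitfunc = spec$name, tau = best$par[["tau"]],
         mre = m_from_tau(best$par[["tau"]], object$dt),
         params = best$par, ssres = best$ssres,
         ci = NULL, tau_ci = NULL, mre_ci = NULL,
         fitrange = object$steps[keep], dt = object$dt,
         dtunit = object$dtunit, level = level, flags = flags),
    class = "mr_fit")

  samples <- fit_bootstrap_samples(object, keep, numboot, seed)
  if (!is.null(samples)) {
    boot_par <- refit_bootstrap(spec, lag, samples, bounds, best$par)
    if (nrow(boot_par) >= 2) {
      res$ci <- t(apply(boot_par, 2, percentile_ci, level = level))
      colnames(res$ci) <- c("lower", "upper")
      tau_b <- boot_par[, "tau"]
      res$tau_ci <- percentile_ci(tau_b, level)
      res$mre_ci <- percentile_ci(m_from_tau(pmax(tau_b, 1e-12), object$dt),
                                  level)
      res$bootstrap_params <- boot_par
    }
  }
  res
}

resolve_fitrange <- function(fitrange, steps) {
  if (is.null(fitrange)) return(rep(TRUE, length(steps)))
  fitrange <- as.integer(fitrange)
  if (length(fitrange) == 2) {
    keep <- steps >= fitrange[1] & steps <= fitrange[2]
  } else {
    if (!all(fitrange %in% steps)) {
      stop("`fitrange` must be a subset of the estimated steps",
           call. = FALSE)
    }
    keep <- steps %in% fitrange
  }
  if (!any(keep)) stop("`fitrange` selects no steps", call. = FALSE)
  keep
}

# Growing coefficients mean m > 1: regress log r on lag; demand a clearly
# positive slope on predominantly positive coefficients.
detect_supercritical <- function(lag, r) {
  pos <- r > 0
  if (mean(pos) < 0.8 || sum(pos) < 4) return(NULL)
  fit <- stats::lm(log(r[pos]) ~ lag[pos])
  sl <- suppressWarnings(summary(fit))$coefficients
  if (nrow(sl) < 2) return(NULL)
  slope <- sl[2, 1]
  tval <- sl[2, 3]
  if (slope > 0 && is.finite(tval) && tval > 3) {
    dlag <- mean(diff(sort(unique(lag))))
    list(slope = slope, mre = exp(slope * dlag))
  } else NULL
}

fit_multistart <- function(spec, lag, r, bounds, starts) {
  best <- list(par = NULL, ssres = Inf, nstarts = length(starts))
  for (p0 in starts) {
    ans <- try_nlslm(spec, lag, r, p0, bounds)
    if (!is.null(ans) && ans$ssres < best$ssres) {
      best$par <- ans$par
      best$ssres <- ans$ssres
    }
  }
  best
}

try_nlslm <- function(spec, lag, r, p0, bounds) {
  p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)
  resid_fn <- function(p) {
    p <- stats::setNames(as.numeric(p), spec$params)
    r - spec$fn(lag, as.list(p))
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = bounds$lower, upper = bounds$upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(out) || !out$info %in% 1:4) return(NULL)
  par <- stats::setNames(as.numeric(out$par), spec$params)
  list(par = par, ssres = sum(resid_fn(par)^2))
}

# Bootstrap replicates of r_k over the fitted steps: reuse the samples on the
# coefficient object, or draw fresh ones from its cached trial statistics.
fit_bootstrap_samples <- function(coeffs, keep, numboot, seed) {
  if (is.null(numboot)) {
    if (!is.null(coeffs$bootstrap_samples)) {
      return(coeffs$bootstrap_samples[, keep, drop = FALSE])
    }
    return(NULL)
  }
  numboot <- as.integer(numboot)
  if (numboot <= 0) return(NULL)
  st <- attr(coeffs, "trial_stats")
  if (is.null(st) || coeffs$num_trials < 2) {
    stop("bootstrap CIs need a coefficient result computed from >= 2 trials",
         call. = FALSE)
  }
  bs <- bootstrap_coefficient_samples(st, coeffs$method, numboot,
                                      resolve_seed(seed))
  bs[, keep, drop = FALSE]
}

refit_bootstrap <- function(spec, lag, samples, bounds, par0) {
  rows <- lapply(seq_len(nrow(samples)), function(b) {
    ans <- try_nlslm(spec, lag, samples[b, ], p0 = par0, bounds = bounds)
    if (is.null(ans)) NULL else ans$par
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(matrix(numeric(0), ncol = length(spec$params),
                  dimnames = list(NULL, spec$params)))
  }
  do.call(rbind, rows)
}

#' @export
print.mr_fit <- function(x, ...) {
  if (identical(x$fitfunc, "log_slope")) {
    cat(sprintf("<mr_fit> supercritical diagnostic: m_hat = %.4g > 1, no finite tau\n",
                x$mre))
    return(invisible(x))
  }
  ci_str <- function(ci) {
    if (is.null(ci)) "" else sprintf(" [%.4g, %.4g]", ci[1], ci[2])
  }
  cat(sprintf("<mr_fit> %s fit over k = %d..%d (dt = %g %s)\n",
              x$fitfunc, min(x$fitrange), max(x$fitrange), x$dt, x$dtunit))
  cat(sprintf("  tau = %.4g %s%s\n", x$tau, x$dtunit, ci_str(x$tau_ci)))
  cat(sprintf("  m   = %.6g%s\n", x$mre, ci_str(x$mre_ci)))
  cat(sprintf("  ssres = %.4g%s\n", x$ssres,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}

#' Tidy view of a fitted autocorrelation model
#'
#' @param x an `mr_fit` object.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per parameter (`term`,
#'   `estimate`, and CI bounds when bootstrapped). `glance()`: a one-row
#'   tibble with `fitfunc`, `tau`, `mre`, `ssres`, the CI bounds and the
#'   fit range.
#' @export
#' @exportS3Method generics::tidy
tidy.mr_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$params),
                        estimate = as.numeric(x$params))
  if (!is.null(x$ci)) {
    out$ci_lower <- x$ci[, "lower"]
    out$ci_upper <- x$ci[, "upper"]
  }
  out
}

#' @rdname tidy.mr_fit
#' @export
#' @exportS3Method generics::glance
glance.mr_fit <- function(x, ...) {
  tibble::tibble(
    fitfunc = x$fitfunc, tau = x$tau, mre = x$mre, ssres = x$ssres,
    tau_ci_lower = if (is.null(x$tau_ci)) NA_real_ else x$tau_ci[1],
    tau_ci_upper = if (is.null(x$tau_ci)) NA_real_ else x$tau_ci[2],
    mre_ci_lower = if (is.null(x$mre_ci)) NA_real_ else x$mre_ci[1],
    mre_ci_upper = if (is.null(x$mre_ci)) NA_real_ else x$mre_ci[2],
    ci_level = x$level, kmin = min(x$fitrange), kmax = max(x$fitrange),
    dt = x$dt, dtunit = x$dtunit)
}
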