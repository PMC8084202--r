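# Independent brute-force oracles: literal double-loop evaluations of the
# defining formulas, kept free of any package internals so they can vouch
# for the vectorised/FFT production paths.

oracle_rk_naive <- function(trial, k) {
  T_ <- length(trial)
  n <- T_ - k
  x <- trial[1:n]
  y <- trial[(1 + k):T_]
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  num <- 0
  den <- 0
  for (t in 1:n) {
    num <- num + (x[t] - xbar) * (y[t] - ybar)
    den <- den + (x[t] - xbar)^2
  }
  num / den
}

oracle_rk_trialseparated <- function(mat, k) {
  mean(vapply(seq_len(nrow(mat)), function(i) oracle_rk_naive(mat[i, ], k),
              numeric(1)))
}

oracle_rk_stationarymean <- function(mat, k) {
  N <- nrow(mat)
  T_ <- ncol(mat)
  n <- T_ - k
  xbar <- 0
  ybar <- 0
  for (i in 1:N) for (t in 1:n) {
    xbar <- xbar + mat[i, t]
    ybar <- ybar + mat[i, t + k]
  }
  xbar <- xbar / (N * n)
  ybar <- ybar / (N * n)
  num <- 0
  for (i in 1:N) {
    s <- 0
    for (t in 1:n) s <- s + (mat[i, t] - xbar) * (mat[i, t + k] - ybar)
    num <- num + s / n
  }
  den <- 0
  for (i in 1:N) {
    s <- 0
    for (t in 1:T_) s <- s + (mat[i, t] - xbar)^2
    den <- den + s / T_
  }
  num / den
}

# Construct a coefficient result from given (steps, r_k) without touching
# data, for fitting noiseless model curves.
make_coeffs <- function(steps, r, dt = 1, dtunit = "steps") {
  structure(list(steps = as.integer(steps), coefficients = r,
                 trial_coefficients = NULL, method = "trialseparated",
                 dt = dt, dtunit = dtunit, stderrs = NULL,
                 bootstrap_samples = NULL, num_trials = 1L,
                 trial_length = max(steps) + 2L, numboot = 0L, seed = NULL),
            class = "mr_coefficients")
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
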