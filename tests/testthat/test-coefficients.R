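test_that("single-trial slopes match hand-computed values", {
  expect_equal(rk_naive(c(0, 1, 2, 3), 1), 1)
  expect_equal(rk_naive(c(1, 0, 1, 0), 1), -1)
  expect_error(rk_naive(c(5, 5, 5, 5), 1), "degenerate")
  expect_error(rk_naive(c(1, 2, 3), 2), "k \\+ 2")
})

test_that("trial-separated slope is the mean of per-trial slopes", {
  two <- rbind(c(0, 1, 2, 3), c(1, 0, 1, 0))
  res <- rk_trialseparated(two, 1)
  expect_equal(res$trial_r, c(1, -1))
  expect_equal(res$r, 0)
  same <- rk_trialseparated(rbind(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(same$r, rk_naive(c(0, 1, 2, 3), 1))
  expect_error(rk_trialseparated(rbind(c(0, 1, 2, 3), c(2, 2, 2, 2)), 1),
               "trial 2")
})

test_that("all three estimators agree with brute-force double loops", {
  set.seed(42)
  for (rep in 1:5) {
    mat <- matrix(sample.int(20, 100, replace = TRUE), nrow = 5, ncol = 20)
    for (k in c(1, 2, 5, 11)) {
      expect_lt(rel_err(rk_naive(mat[1, ], k), oracle_rk_naive(mat[1, ], k)),
                1e-12)
      expect_lt(rel_err(rk_trialseparated(mat, k)$r,
                        oracle_rk_trialseparated(mat, k)), 1e-12)
      expect_lt(rel_err(rk_stationarymean(mat, k),
                        oracle_rk_stationarymean(mat, k)), 1e-12)
    }
  }
})

test_that("the batch estimator equals the scalar entry points for both methods", {
  set.seed(17)
  mat <- matrix(rpois(8 * 300, 30), nrow = 8)
  steps <- c(1, 2, 3, 7, 20, 50)
  ts <- coefficients(mat, steps = steps, method = "ts", numboot = 0)
  sm <- coefficients(mat, steps = steps, method = "sm", numboot = 0)
  for (j in seq_along(steps)) {
    expect_lt(rel_err(ts$coefficients[j],
                      rk_trialseparated(mat, steps[j])$r), 1e-12)
    expect_lt(rel_err(sm$coefficients[j],
                      rk_stationarymean(mat, steps[j])), 1e-12)
  }
  expect_identical(ts$steps, as.integer(steps))
  # per-trial coefficients only for the trial-separated method
  expect_identical(dim(ts$trial_coefficients), c(8L, length(steps)))
  expect_null(sm$trial_coefficients)
})

test_that("the FFT-accelerated path agrees with the direct lag sums", {
  set.seed(91)
  a <- rpois(5000, 100)
  steps <- c(1L, 3L, 10L, 100L, 999L)
  direct <- mrtau:::lagged_cross_sums(a, steps, use_fft = FALSE)
  fast <- mrtau:::lagged_cross_sums(a, steps, use_fft = TRUE)
  expect_lt(max(rel_err(fast, direct)), 1e-12)
})

test_that("stationary-mean on one long trial approaches the naive slope", {
  set.seed(3)
  x <- as.vector(simulate_branching(m = 0.8, a = 50, length = 5000,
                                    seed = 12))
  for (k in c(1, 5)) {
    expect_lt(abs(rk_stationarymean(matrix(x, 1), k) - rk_naive(x, k)),
              5 * k / 5000)
  }
})

test_that("step specification: ranges, explicit arrays, clipping", {
  set.seed(8)
  mat <- matrix(rpois(4 * 60, 20), nrow = 4)
  explicit <- coefficients(mat, steps = c(1, 3, 5), method = "ts",
                           numboot = 0)
  expect_identical(explicit$steps, c(1L, 3L, 5L))
  expect_warning(
    clipped <- coefficients(mat, steps = c(1, 500), method = "ts",
                            numboot = 0),
    "clipping")
  expect_identical(max(clipped$steps), 58L)  # T - 2
  expect_error(coefficients(mat, steps = c(60, 70), method = "ts",
                            numboot = 0))
  expect_error(coefficients(mat, steps = c(1, 10), method = "nope"))
})

test_that("bootstrap attaches deterministic samples and stderrs", {
  bp <- simulate_branching(m = 0.9, a = 100, length = 800, numtrials = 6,
                           seed = 55)
  r1 <- coefficients(bp, steps = c(1, 20), method = "ts", numboot = 40,
                     seed = 99)
  r2 <- coefficients(bp, steps = c(1, 20), method = "ts", numboot = 40,
                     seed = 99)
  expect_identical(r1$bootstrap_samples, r2$bootstrap_samples)
  expect_identical(dim(r1$bootstrap_samples), c(40L, 20L))
  expect_length(r1$stderrs, 20)
  none <- coefficients(bp, steps = c(1, 20), method = "ts", numboot = 0)
  expect_null(none$stderrs)
  expect_null(none$bootstrap_samples)
})

test_that("tidy and glance views carry steps, lags and metadata", {
  bp <- simulate_branching(m = 0.9, a = 100, length = 300, numtrials = 3,
                           seed = 1)
  rk <- coefficients(bp, steps = c(1, 10), method = "sm", dt = 2,
                     dtunit = "ms", numboot = 10, seed = 2)
  td <- tidy(rk)
  expect_identical(td$lag, td$step * 2)
  expect_true(all(c("coefficient", "stderr") %in% names(td)))
  gl <- glance(rk)
  expect_identical(gl$method, "stationarymean")
  expect_identical(gl$dtunit, "ms")
})
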