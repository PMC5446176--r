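test_that("fit_single_exponential is exact on noiseless model data", {
  t <- seq(0.0015, 5, length.out = 300)
  for (a in c(0.8, -0.8)) {   # decaying and rising traces
    tr <- time_course(t, 1.0 + a * exp(-1.3 * t))
    fit <- fit_single_exponential(tr)
    expect_true(fit$converged)
    expect_lt(rel_err(fit$estimates[["k_app"]], 1.3), 1e-6)
    expect_lt(rel_err(fit$estimates[["A"]], a), 1e-6)
    expect_lt(rel_err(fit$estimates[["F_inf"]], 1.0), 1e-6)
  }
})

test_that("flat traces are reported as failures, not rates", {
  t <- seq(0, 3, length.out = 200)
  tr <- time_course(t, 0.5 + withr::with_seed(1, rnorm(200, 0, 0.01)))
  fit <- fit_single_exponential(tr)
  expect_false(fit$converged)
  expect_true(all(is.na(fit$estimates)))
})

test_that("too-short traces fail and truncated windows warn", {
  expect_false(fit_single_exponential(
    time_course(seq(0, 1, length.out = 5), rep(1, 5)))$converged)
  # window much shorter than 2 / k_app
  t <- seq(0, 0.5, length.out = 100)
  tr <- time_course(t, 1 + 0.8 * exp(-0.9 * t) +
                      withr::with_seed(2, rnorm(100, 0, 1e-4)))
  expect_warning(fit_single_exponential(tr), "poorly constrained")
})

test_that("reported rate SEs match Monte-Carlo scatter within 20 percent", {
  t <- seq(0.0015, 4, length.out = 200)
  clean <- 1.0 + 0.8 * exp(-1.5 * t)
  fits <- lapply(1:200, function(i) {
    fit_single_exponential(time_course(
      t, clean + withr::with_seed(5000 + i, rnorm(length(t), 0, 0.008))))
  })
  k <- vapply(fits, function(f) f$estimates[["k_app"]], numeric(1))
  se <- vapply(fits, function(f) f$se[["k_app"]], numeric(1))
  expect_lt(abs(mean(se) / sd(k) - 1), 0.2)
  expect_lt(abs(mean(k) - 1.5), 3 * sd(k) / sqrt(length(k)))
})

test_that("weighted_linear_fit recovers an exact line", {
  x <- c(1, 2, 3, 5, 8) * 1e-6
  y <- 2e6 * x + 0.5
  wf <- nexkin:::weighted_linear_fit(x, y, rep(0.01, 5))
  expect_equal(wf$slope, 2e6, tolerance = 1e-9)
  expect_equal(wf$intercept, 0.5, tolerance = 1e-9)
  expect_true(wf$weighted)
})

test_that("ts_titration_analysis enforces the minimum linear-regime points", {
  mk_fit <- function(ts, k) {
    structure(list(estimates = c(F_inf = 0, A = 1, k_app = k),
                   se = c(F_inf = 0.01, A = 0.01, k_app = 0.02 * k),
                   sigma = 0.01, converged = TRUE, message = "converged",
                   n = 100, short_span = FALSE, meta = list(ts_uM = ts)),
              class = "exp_fit")
  }
  fits <- unlist(lapply(c(0.1, 0.2, 0.3), function(ts) {
    lapply(1:3, function(r) mk_fit(ts, 13.4 * ts * (1 + 0.001 * r)))
  }), recursive = FALSE)
  expect_error(ts_titration_analysis(fits), ">= 4 EF-Ts concentrations")
})

test_that("identical reaction and background series give zero GTPase rate", {
  t <- c(100, 200, 300, 400)
  same <- time_course(t, c(0.2, 0.4, 0.6, 0.8),
                      meta = list(gtp_uM = 20, role = "reaction"))
  est <- gtpase_initial_rate(same, same)
  expect_equal(est$value, 0)
})

test_that("GTPase estimators validate their inputs", {
  t <- c(100, 200, 300, 400)
  a <- time_course(t, c(0.2, 0.4, 0.6, 0.8), meta = list(gtp_uM = 20))
  b <- time_course(t + 5, c(0.1, 0.2, 0.3, 0.4), meta = list(gtp_uM = 20))
  expect_error(gtpase_initial_rate(a, b), "share quench times")
  # all corrected points beyond 10 percent consumption
  big <- time_course(t, c(5, 9, 12, 15), meta = list(gtp_uM = 20))
  zero <- time_course(t, rep(0, 4), meta = list(gtp_uM = 20))
  expect_error(gtpase_initial_rate(big, zero), "fewer than 4 initial-phase")
  expect_error(gtpase_analysis(list(a)), "paired reaction and background")
})

test_that("protection_halflife matches the analytic identity", {
  t <- c(0.1, 0.5, 1, 2, 3, 4)           # minutes
  # an exact decay makes lm's residual summary degenerate; warning expected
  est <- suppressWarnings(protection_halflife(time_course(t, exp(-log(2) * t))))
  expect_equal(est$value, 1, tolerance = 1e-12)
  expect_equal(est$unit, "min")
})

test_that("protection_halflife rejects invalid series", {
  t <- c(1, 2, 3, 4, 5)
  expect_error(protection_halflife(time_course(t[1:4], exp(-t[1:4]))),
               ">= 5 time points")
  expect_error(protection_halflife(time_course(t, c(2, 0.5, 0.4, 0.3, 0.2))),
               "intact fraction")
  expect_error(protection_halflife(time_course(t, c(0.2, 0.3, 0.4, 0.5, 0.6))),
               "non-decaying")
})

test_that("compare_conditions implements the two-sided z-test", {
  a <- rate_estimate("k1", 2.1e6, 0.1e6, "/M/s")
  expect_equal(compare_conditions(a, a)$z, 0)
  expect_false(compare_conditions(a, a)$detected)
  b <- rate_estimate("k1", 2.1e6, 0.3e6, "/M/s")
  expect_false(compare_conditions(a, b)$detected)
  c2 <- rate_estimate("k1", 4.2e6, 0.1e6, "/M/s")
  cc <- compare_conditions(a, c2)
  expect_true(cc$detected)
  expect_lt(cc$p, 1e-10)
  d <- rate_estimate("k5", 2.1e6, 0.1e6, "/M/s")
  expect_error(compare_conditions(a, d), "same constant")
})

test_that("power_of_detection is calibrated at null and saturates", {
  expect_warning(
    power_of_detection("intrinsic", 1, n_sim = 10, seed = 3),
    "coarse")
  null <- power_of_detection("intrinsic", 1, n_sim = 200, seed = 5)
  expect_lt(abs(null$power - 0.05), 0.05)
  big <- power_of_detection("intrinsic", 2, n_sim = 50, seed = 5) |>
    suppressWarnings()
  expect_gt(big$power, 0.9)
})
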