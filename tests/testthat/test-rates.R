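test_that("rate_params validates its inputs", {
  p <- rate_params(k1 = 1, k1r = 0.1)
  expect_s3_class(p, "rate_params")
  expect_equal(p[["k1"]], 1)
  expect_equal(p[["k2"]], 0)
  expect_error(rate_params(k1 = -1), "finite and >= 0")
  expect_error(rate_params(k3 = NA_real_), "finite and >= 0")
  expect_error(rate_params(k5 = Inf), "finite and >= 0")
})

test_that("default constants reproduce the declared measured values", {
  p <- default_rate_params()
  expect_equal(p[["k1"]], 2.1e6)
  expect_equal(p[["k5"]], 3.9e5)
  expect_equal(p[["k1r"]], 1.4e-3)
  expect_equal(p[["k5r"]], 1.4e-2)
  cc <- combined_constants(p)
  expect_equal(cc[["gdp"]], 13.4e6)
  expect_equal(cc[["gtp"]], 21.9e6)
})

test_that("default constants satisfy detailed balance around both cycles", {
  p <- default_rate_params()
  K <- function(f, r) p[[f]] / p[[r]]
  kts_gdp <- K("k1", "k1r") * K("k3", "k3r") / K("k4", "k4r")
  kts_gtp <- K("k5", "k5r") * K("k6", "k6r") / K("k7", "k7r")
  kts_dir <- K("k2", "k2r")
  expect_lt(rel_err(kts_gdp, kts_dir), 1e-12)
  expect_lt(rel_err(kts_gtp, kts_dir), 1e-12)
})

test_that("predicted_kapp is kon*L + koff and validates", {
  expect_equal(predicted_kapp(2e6, 1e-3, 3e-6), 2e6 * 3e-6 + 1e-3)
  expect_equal(predicted_kapp(0, 0.5, 1e-6), 0.5)
  expect_error(predicted_kapp(-1, 0, 1e-6), ">= 0")
})

test_that("effective_stimulated_constant implements the flux partition", {
  # commitment probability k_release / (k_off + k_release)
  expect_equal(effective_stimulated_constant(1e7, 2000, 2000), 5e6)
  expect_equal(effective_stimulated_constant(1e7, 0, 5), 1e7)
  expect_error(effective_stimulated_constant(1e7, 0, 0), "flux partition")
  expect_error(effective_stimulated_constant(-1, 1, 1), ">= 0")
})

test_that("rate-parameter files round-trip losslessly past 12 digits", {
  p <- default_rate_params()
  path <- withr::local_tempfile(fileext = ".txt")
  write_rate_params(p, path)
  q <- read_rate_params(path)
  expect_s3_class(q, "rate_params")
  expect_true(all(rel_err(as.numeric(q), as.numeric(p)) < 1e-12))
  expect_identical(names(q), names(p))
})

test_that("malformed rate-parameter files are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("k1 2.1e6", "k1r not_a_number"), path)
  expect_error(read_rate_params(path), "malformed")
  writeLines("k1 2.1e6", path)
  expect_error(read_rate_params(path), "missing keys")
})
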