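test_that("generators emit the designed record counts with tagged metadata", {
  truth <- noiseless_truth()
  assoc <- suppressWarnings(
    generate_association_set(association_design("GDP", replicates = 2), truth))
  expect_length(assoc, 6 * 2)
  expect_equal(assoc[[1]]$meta$family, "association")

  chase <- generate_chase_set(chase_design("GDP", replicates = 3), truth)
  expect_length(chase, 3)

  ts <- generate_ts_titration_set(ts_titration_design("GDP", replicates = 1),
                                  truth)
  expect_length(ts, 8)
  expect_equal(ts[[1]]$meta$family, "ts_titration")

  gt <- generate_gtpase_timecourse(gtpase_design("intrinsic", replicates = 3),
                                   truth)
  expect_length(gt, 6)   # paired reaction + background per replicate
  expect_setequal(unique(vapply(gt, function(r) r$meta$role, "")),
                  c("reaction", "background"))

  prot <- generate_protection_decay(protection_design(FALSE), truth)
  expect_s3_class(prot, "time_course")
  expect_equal(prot$meta$time_unit, "min")
})

test_that("generators are pure functions of (design, truth, seed)", {
  d <- chase_design("GDP", replicates = 2)
  a <- generate_chase_set(d, default_truth(), seed = 11)
  b <- generate_chase_set(d, default_truth(), seed = 11)
  c2 <- generate_chase_set(d, default_truth(), seed = 12)
  expect_identical(a[[1]]$signal, b[[1]]$signal)
  expect_false(identical(a[[1]]$signal, c2[[1]]$signal))
})

test_that("noiseless truth makes generators seed-independent", {
  d <- chase_design("GDP", replicates = 1)
  a <- generate_chase_set(d, noiseless_truth(), seed = 1)
  b <- generate_chase_set(d, noiseless_truth(), seed = 999)
  expect_identical(a[[1]]$signal, b[[1]]$signal)
})

test_that("design violations raise the documented warnings and errors", {
  truth <- noiseless_truth()
  expect_warning(
    generate_association_set(
      association_design("GDP", tu_uM = 0.3, ligand_uM = c(1, 2), replicates = 1),
      truth),
    "pseudo-first-order margin")
  expect_warning(
    generate_chase_set(
      chase_design("GDP", mant_uM = 6, chase_uM = 20, replicates = 1), truth),
    "chase excess")
  expect_warning(
    generate_ts_titration_set(
      ts_titration_design("GDP", ts_uM = c(5, 10, 30, 80), replicates = 1),
      truth),
    "beyond the linear regime")
  expect_error(
    generate_gtpase_timecourse(
      gtpase_design("intrinsic", quench_times_s = c(2e4, 4e4, 6e4, 8e4)), truth),
    ">= 4 points")
  expect_error(
    generate_gtpase_timecourse(gtpase_design("bogus_condition"), truth),
    "unknown GTPase condition")
})

test_that("noiseless association titration recovers k1 within the PFO budget", {
  truth <- noiseless_truth()
  # all ligand levels at >= 100-fold excess, where the pseudo-first-order
  # approximation is good to better than 1 percent
  d <- suppressWarnings(association_design(
    "GDP", tu_uM = 0.02, ligand_uM = c(2, 3, 4, 5), replicates = 1))
  recs <- suppressWarnings(generate_association_set(d, truth))
  fits <- lapply(recs, fit_single_exponential)
  ana <- association_analysis(fits, constant = "k1")
  expect_lt(rel_err(ana$k_on$value, 2.1e6), 0.01)
})

test_that("noiseless chase recovers the dissociation constants within 2 percent", {
  truth <- noiseless_truth()
  for (nuc in c("GDP", "GTP")) {
    recs <- generate_chase_set(chase_design(nuc, replicates = 1), truth)
    fit <- fit_single_exponential(recs[[1]])
    ref <- if (nuc == "GDP") 1.4e-3 else 1.4e-2
    expect_lt(rel_err(fit$estimates[["k_app"]], ref), 0.02)
  }
})

test_that("noiseless EF-Ts titration slope matches the flux-partition constant", {
  truth <- noiseless_truth()
  cc <- combined_constants(truth$rates)
  for (nuc in c("GDP", "GTP")) {
    recs <- generate_ts_titration_set(
      ts_titration_design(nuc, replicates = 1), truth)
    fits <- lapply(recs, fit_single_exponential)
    ana <- ts_titration_analysis(fits,
                                 constant = paste0("comb_", tolower(nuc)))
    ref <- cc[[tolower(nuc)]]
    expect_lt(rel_err(ana$combined$value, ref), 0.05)
  }
})

test_that("noise-free protection decay reproduces the half-life exactly", {
  truth <- noiseless_truth()
  d <- protection_design(with_ef_tu = FALSE, noise_frac = 0)
  # an exact decay makes lm's residual summary degenerate; that warning is
  # expected here
  est <- suppressWarnings(
    protection_halflife(generate_protection_decay(d, truth)))
  expect_equal(est$value, 35, tolerance = 1e-10)
})

test_that("apply_effect scales exactly one ground-truth knob", {
  truth <- default_truth()
  t2 <- apply_effect(truth, "k1r", 5)
  expect_equal(t2$rates[["k1r"]], 5 * truth$rates[["k1r"]])
  expect_equal(t2$rates[["k1"]], truth$rates[["k1"]])
  t3 <- apply_effect(truth, "intrinsic", 2)
  expect_equal(t3$gtpase_rates[["intrinsic"]],
               2 * truth$gtpase_rates[["intrinsic"]])
  t4 <- apply_effect(truth, "ternary", 0.5)
  expect_equal(t4$halflife_min[["ternary"]], 191)
  expect_error(apply_effect(truth, "nonesuch", 2), "unknown constant")
})

test_that("true_value_of reports the generating values", {
  truth <- default_truth()
  expect_equal(true_value_of("k1", truth), 2.1e6)
  expect_equal(true_value_of("comb_gtp", truth), 21.9e6)
  expect_equal(true_value_of("ribo_70S", truth), 2.67e-3)
  expect_equal(true_value_of("halflife_ternary", truth), 382)
  expect_error(true_value_of("nonesuch", truth), "unknown constant")
})

test_that("the per-trace seed stream is deterministic and in range", {
  s <- vapply(1:1000, function(i) nexkin:::trace_seed(42, i), numeric(1))
  expect_identical(s, vapply(1:1000, function(i) nexkin:::trace_seed(42, i),
                             numeric(1)))
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(anyDuplicated(s), 0)
})
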