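#' Names of the constants the pipeline estimates
#' @return Character vector of estimable constant names.
#' @export
pipeline_constants <- function() {
  c("k1", "k5", "k1r", "k5r", "comb_gdp", "comb_gtp",
    "intrinsic", "efts_low", "efts_high", "ribo_70S", "ribo_50S",
    "halflife_free", "halflife_ternary")
}

default_design_for <- function(constant) {
  switch(constant,
    k1 = association_design("GDP"),
    k5 = association_design("GTP"),
    k1r = chase_design("GDP"),
    k5r = chase_design("GTP"),
    comb_gdp = ts_titration_design("GDP"),
    comb_gtp = ts_titration_design("GTP"),
    intrinsic = gtpase_design("intrinsic"),
    efts_low = gtpase_design("efts_low"),
    efts_high = gtpase_design("efts_high"),
    ribo_70S = gtpase_design("ribo_70S"),
    ribo_50S = gtpase_design("ribo_50S"),
    halflife_free = protection_design(with_ef_tu = FALSE),
    halflife_ternary = protection_design(with_ef_tu = TRUE),
    stop("unknown constant: ", constant, call. = FALSE))
}

#' Simulate one experiment and estimate one constant
#'
#' End-to-end generate-then-fit for a single named constant: dispatches to
#' the assay family that measures it (association titration, chase,
#' EF-Ts titration, GTPase quench series, or protection decay), runs the
#' generator under \code{truth} and the matching staged analysis, and returns
#' the resulting estimate.
#'
#' @param constant one of \code{\link{pipeline_constants}}.
#' @param truth a \code{ground_truth}.
#' @param seed master seed for the experiment.
#' @param design optional design override for the assay family.
#' @return A \code{\link{rate_estimate}}.
#' @export
estimate_constant <- function(constant, truth = default_truth(), seed = 1,
                              design = NULL) {
  if (is.null(design)) design <- default_design_for(constant)
  cond <- list(tet_uM = truth$tet_uM)
  if (constant %in% c("k1", "k5")) {
    recs <- suppressWarnings(generate_association_set(design, truth, seed))
    fits <- lapply(recs, fit_single_exponential)
    association_analysis(fits, constant = constant, condition = cond)$k_on
  } else if (constant %in% c("k1r", "k5r")) {
    recs <- generate_chase_set(design, truth, seed)
    fits <- lapply(recs, fit_single_exponential)
    chase_analysis(fits, constant = constant, condition = cond)
  } else if (constant %in% c("comb_gdp", "comb_gtp")) {
    recs <- generate_ts_titration_set(design, truth, seed)
    fits <- lapply(recs, fit_single_exponential)
    ts_titration_analysis(fits, constant = constant, condition = cond)$combined
  } else if (constant %in% names(truth$gtpase_rates)) {
    recs <- generate_gtpase_timecourse(design, truth, seed)
    gtpase_analysis(recs, constant = constant, condition = cond)
  } else if (constant %in% c("halflife_free", "halflife_ternary")) {
    rec <- generate_protection_decay(design, truth, seed)
    protection_halflife(rec, constant = constant, condition = cond)
  } else {
    stop("unknown constant: ", constant, call. = FALSE)
  }
}

#' Generating (ground-truth) value of a pipeline constant
#'
#' @param constant one of \code{\link{pipeline_constants}}.
#' @param truth a \code{ground_truth}.
#' @return The value the synthetic data were generated with, in the same base
#'   unit the corresponding estimator reports.
#' @export
true_value_of <- function(constant, truth = default_truth()) {
  p <- truth$rates
  switch(constant,
    k1 = p[["k1"]], k5 = p[["k5"]], k1r = p[["k1r"]], k5r = p[["k5r"]],
    comb_gdp = combined_constants(p)[["gdp"]],
    comb_gtp = combined_constants(p)[["gtp"]],
    intrinsic = truth$gtpase_rates[["intrinsic"]],
    efts_low = truth$gtpase_rates[["efts_low"]],
    efts_high = truth$gtpase_rates[["efts_high"]],
    ribo_70S = truth$gtpase_rates[["ribo_70S"]],
    ribo_50S = truth$gtpase_rates[["ribo_50S"]],
    halflife_free = truth$halflife_min[["free_trna"]],
    halflife_ternary = truth$halflife_min[["ternary"]],
    stop("unknown constant: ", constant, call. = FALSE))
}

#' Monte-Carlo power to detect a rate-constant effect
#'
#' Fraction of simulated experiment pairs, one under \code{truth} and one
#' under \code{truth} with \code{constant} multiplied by \code{effect}, in
#' which \code{\link{compare_conditions}} declares a difference at
#' \code{alpha}. The two members of each pair use independent noise; at
#' \code{effect = 1} the power therefore estimates the test's false-positive
#' rate (about \code{alpha}).
#'
#' @param constant constant to perturb and estimate (see
#'   \code{\link{pipeline_constants}}; for elementary rate constants the
#'   perturbed and estimated names may differ, e.g. effect on \code{"k1r"} is
#'   estimated by the chase assay for \code{"k1r"}).
#' @param effect multiplicative effect size (> 0).
#' @param truth baseline ground truth.
#' @param design optional design override.
#' @param n_sim number of simulated pairs (>= 100 recommended).
#' @param seed master seed; pair i uses seeds derived from (seed, i), so a
#'   common \code{seed} across an effect grid gives common random numbers.
#' @param alpha significance level.
#' @return List with \code{power}, binomial \code{se}, \code{n_sim}.
#' @export
power_of_detection <- function(constant, effect, truth = default_truth(),
                               design = NULL, n_sim = 100, seed = 1,
                               alpha = 0.05) {
  stopifnot(effect > 0, n_sim >= 1)
  if (n_sim < 100) {
    warning("n_sim < 100: power estimate will be coarse", call. = FALSE)
  }
  truth_b <- apply_effect(truth, effect_target_of(constant), effect)
  detected <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    ea <- suppressWarnings(estimate_constant(
      constant, truth, seed = trace_seed(seed, 2L * i - 1L) + 7L, design = design))
    eb <- suppressWarnings(estimate_constant(
      constant, truth_b, seed = trace_seed(seed, 2L * i) + 13L, design = design))
    detected[i] <- compare_conditions(ea, eb, alpha = alpha)$detected
  }
  power <- mean(detected)
  list(power = power, se = sqrt(power * (1 - power) / n_sim), n_sim = n_sim,
       effect = effect, constant = constant, alpha = alpha)
}

# map an estimable constant to the ground-truth knob the effect hook scales
effect_target_of <- function(constant) {
  switch(constant,
    halflife_free = "free_trna",
    halflife_ternary = "ternary",
    comb_gdp = "k3",   # scales the combined GDP constant proportionally
    comb_gtp = "k6",
    constant)
}
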