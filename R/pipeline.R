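report_scale_of <- function(constant) {
  # scale factor and printed unit, matching the conventional table layout
  switch(constant,
    k1 = list(scale = 1e6, unit = "x10^6 /M/s"),
    k5 = list(scale = 1e5, unit = "x10^5 /M/s"),
    k1r = list(scale = 1e-3, unit = "x10^-3 /s"),
    k5r = list(scale = 1e-2, unit = "x10^-2 /s"),
    comb_gdp = list(scale = 1e6, unit = "x10^6 /M/s"),
    comb_gtp = list(scale = 1e6, unit = "x10^6 /M/s"),
    intrinsic = list(scale = 1e-4, unit = "x10^-4 uM/s"),
    efts_low = list(scale = 1e-4, unit = "x10^-4 uM/s"),
    efts_high = list(scale = 1e-4, unit = "x10^-4 uM/s"),
    ribo_70S = list(scale = 1e-3, unit = "x10^-3 uM/s"),
    ribo_50S = list(scale = 1e-3, unit = "x10^-3 uM/s"),
    halflife_free = list(scale = 1, unit = "min"),
    halflife_ternary = list(scale = 1, unit = "min"),
    list(scale = 1, unit = ""))
}

#' Default pipeline run configuration
#'
#' @param seed master seed (all randomness derives from it; no silent
#'   time-based seeding anywhere).
#' @param tet_levels_uM tetracycline levels for the kinetic and GTPase
#'   batteries (the first level is the reference for comparisons).
#' @param protection_tet_levels_uM tetracycline levels for the protection
#'   assay with EF-Tu present (the no-EF-Tu control is run at the first
#'   level only).
#' @param out_dir output directory for artifacts (NULL = don't write).
#' @param constants which constants to estimate.
#' @param designs optional named list of design overrides per constant.
#' @param effect optional effect hook: list(constant =, multiplier =) applied
#'   to the ground truth of every non-reference tetracycline level.
#' @param alpha significance level for the cross-condition comparisons.
#' @return List of class \code{run_config}.
#' @export
default_run_config <- function(seed = 1, tet_levels_uM = c(0, 100),
                               protection_tet_levels_uM = c(0, 3, 30, 100),
                               out_dir = NULL,
                               constants = pipeline_constants(),
                               designs = list(), effect = NULL,
                               alpha = 0.05) {
  stopifnot(length(tet_levels_uM) >= 1, is.numeric(seed), length(seed) == 1)
  structure(list(seed = as.integer(seed), tet_levels_uM = tet_levels_uM,
                 protection_tet_levels_uM = protection_tet_levels_uM,
                 out_dir = out_dir, constants = constants, designs = designs,
                 effect = effect, alpha = alpha),
            class = "run_config")
}

#' Run the full simulate-fit-report pipeline
#'
#' For each tetracycline level, generates the complete synthetic experiment
#' battery under the (tetracycline-invariant) ground truth, runs the staged
#' analyses, and assembles a rate table in the conventional scaled units,
#' plus cross-level comparison verdicts per constant. Deterministic given the
#' configuration. When \code{config$out_dir} is set, writes
#' \code{rate_table.csv}, \code{comparisons.csv} and \code{summary.json}
#' there.
#'
#' @param config a \code{\link{default_run_config}}.
#' @return List with \code{rate_table} (data.frame), \code{comparisons}
#'   (data.frame) and \code{estimates} (nested list).
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  protection_constants <- intersect(config$constants,
                                    c("halflife_free", "halflife_ternary"))
  battery_constants <- setdiff(config$constants, protection_constants)
  estimates <- list()
  rows <- list()
  add_row <- function(est, tet) {
    sc <- report_scale_of(est$constant)
    rows[[length(rows) + 1L]] <<- data.frame(
      constant = est$constant, tet_uM = tet, value = est$value, se = est$se,
      n = est$n, unit_si = est$unit,
      value_scaled = est$value / sc$scale, se_scaled = est$se / sc$scale,
      unit_scaled = sc$unit, stringsAsFactors = FALSE)
  }
  ref_level <- config$tet_levels_uM[1L]
  for (tet in config$tet_levels_uM) {
    truth <- default_truth(tet_uM = tet)
    if (!is.null(config$effect) && tet != ref_level) {
      truth <- apply_effect(truth, config$effect$constant,
                            config$effect$multiplier)
    }
    for (const in battery_constants) {
      est <- suppressWarnings(estimate_constant(
        const, truth, seed = trace_seed(config$seed, 1000L * match(
          tet, config$tet_levels_uM) + match(const, config$constants)),
        design = config$designs[[const]]))
      estimates[[paste0(const, "@", tet)]] <- est
      add_row(est, tet)
    }
  }
  # protection: no-EF-Tu control at the reference level, ternary at each level
  if ("halflife_free" %in% protection_constants) {
    truth <- default_truth(tet_uM = config$protection_tet_levels_uM[1L])
    est <- estimate_constant("halflife_free", truth,
                             seed = trace_seed(config$seed, 5000L),
                             design = config$designs[["halflife_free"]])
    estimates[[paste0("halflife_free@", truth$tet_uM)]] <- est
    add_row(est, truth$tet_uM)
  }
  if ("halflife_ternary" %in% protection_constants) {
    for (tet in config$protection_tet_levels_uM) {
      truth <- default_truth(tet_uM = tet)
      if (!is.null(config$effect) && tet != config$protection_tet_levels_uM[1L]) {
        truth <- apply_effect(truth, config$effect$constant,
                              config$effect$multiplier)
      }
      est <- estimate_constant("halflife_ternary", truth,
                               seed = trace_seed(config$seed, 6000L + match(
                                 tet, config$protection_tet_levels_uM)),
                               design = config$designs[["halflife_ternary"]])
      estimates[[paste0("halflife_ternary@", tet)]] <- est
      add_row(est, tet)
    }
  }
  rate_table <- do.call(rbind, rows)

  comp_rows <- list()
  compare_pair <- function(name_a, name_b) {
    a <- estimates[[name_a]]; b <- estimates[[name_b]]
    if (is.null(a) || is.null(b)) return(NULL)
    cc <- compare_conditions(a, b, alpha = config$alpha)
    data.frame(constant = a$constant, tet_a = a$condition$tet_uM %||% NA,
               tet_b = b$condition$tet_uM %||% NA, z = cc$z, p = cc$p,
               detected = cc$detected, stringsAsFactors = FALSE)
  }
  for (const in battery_constants) {
    for (tet in config$tet_levels_uM[-1L]) {
      comp_rows[[length(comp_rows) + 1L]] <-
        compare_pair(paste0(const, "@", ref_level), paste0(const, "@", tet))
    }
  }
  if ("halflife_ternary" %in% protection_constants) {
    ref_p <- config$protection_tet_levels_uM[1L]
    for (tet in config$protection_tet_levels_uM[-1L]) {
      comp_rows[[length(comp_rows) + 1L]] <-
        compare_pair(paste0("halflife_ternary@", ref_p),
                     paste0("halflife_ternary@", tet))
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(constant = character(), tet_a = numeric(), tet_b = numeric(),
               z = numeric(), p = numeric(), detected = logical())

  result <- list(rate_table = rate_table, comparisons = comparisons,
                 estimates = estimates, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rate_table, file.path(config$out_dir, "rate_table.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, tet_levels_uM = config$tet_levels_uM,
           alpha = config$alpha,
           rate_table = rate_table, comparisons = comparisons),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  result
}
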