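#' Default ground truth for synthetic experiments
#'
#' The declared generating values for the full synthetic experiment battery:
#' the default rate-constant set, multiple-turnover GTPase rates per
#' condition, the background hydrolysis rate, aminoacyl-ester decay
#' half-lives with and without EF-Tu, and the observation parameters. The
#' kinetic and chemical truth is tetracycline-invariant (the drug is modeled
#' as a pure fluorescence nuisance); the only tetracycline-dependent default
#' is the additive observation background.
#'
#' Fluorescence-trace replicates additionally carry shot-to-shot experimental
#' variability: each replicate's apparent rates are scaled by a log-normal
#' factor with coefficient of variation \code{replicate_rate_cv} (mean 1,
#' truncated at 3 sigma), modeling mixing, temperature and concentration
#' variability between shots. The default 15 \% gives replicate scatter of
#' fitted apparent rates, and hence standard errors on the secondary-plot
#' constants, of the few-percent magnitude characteristic of stopped-flow
#' titrations; with additive trace noise alone the replicate scatter would be
#' unrealistically small (sub-0.5 \%).
#'
#' @param tet_uM tetracycline concentration (uM) carried into the observation
#'   model.
#' @param obs observation parameters.
#' @param replicate_rate_cv per-replicate apparent-rate variability (CV) for
#'   fluorescence traces; 0 disables it.
#' @return Object of class \code{ground_truth}.
#' @export
default_truth <- function(tet_uM = 0, obs = observation_params(),
                          replicate_rate_cv = 0.15) {
  stopifnot(tet_uM >= 0, replicate_rate_cv >= 0, replicate_rate_cv < 1)
  structure(list(
    rates = default_rate_params(),
    gtpase_rates = c(intrinsic = 7.67e-4,   # uM/s, EF-Tu alone
                     efts_low  = 5.33e-4,   # + 0.02 uM EF-Ts
                     efts_high = 5.33e-4,   # + 0.2 uM EF-Ts
                     ribo_70S  = 2.67e-3,   # + 70S ribosomes
                     ribo_50S  = 1.0e-3),   # + 50S subunits
    gtpase_background = 1e-4,               # uM/s, no-enzyme hydrolysis
    gtp_total_uM = 20,
    halflife_min = c(free_trna = 35,        # no EF-Tu
                     ternary   = 382),      # 1.5 uM EF-Tu present
    obs = obs,
    tet_uM = tet_uM,
    replicate_rate_cv = replicate_rate_cv
  ), class = "ground_truth")
}

#' Variability-free ground truth
#'
#' \code{\link{default_truth}} with all stochastic components disabled (no
#' trace noise, no replicate-level rate variability); generators become
#' deterministic in the design, which is the setting for oracle checks of
#' the noiseless pipeline identities.
#'
#' @inheritParams default_truth
#' @export
noiseless_truth <- function(tet_uM = 0) {
  default_truth(tet_uM = tet_uM, obs = observation_params(noise_frac = 0),
                replicate_rate_cv = 0)
}

is_ground_truth <- function(x) inherits(x, "ground_truth")

# per-replicate apparent-rate factor: log-normal, mean ~1, truncated +/- 3 sd
replicate_rate_factor <- function(truth, seed) {
  cv <- truth$replicate_rate_cv
  if (is.null(cv) || cv <= 0) return(1)
  z <- withr::with_seed(seed, stats::rnorm(1))
  exp(cv * max(min(z, 3), -3) - cv^2 / 2)
}

# horizon headroom so rate_scale-compressed traces stay on the simulated grid
rate_headroom <- function(truth) {
  cv <- truth$replicate_rate_cv
  if (is.null(cv) || cv <= 0) 1 else exp(3 * cv)
}

#' Multiply one ground-truth constant by an effect factor
#'
#' The effect hook used for power analysis: scales a single named constant
#' (an elementary rate constant, a GTPase condition rate, or a protection
#' half-life) leaving everything else untouched.
#'
#' @param truth a \code{ground_truth}.
#' @param constant one of the \code{rate_params} names, a GTPase condition
#'   name (e.g. \code{"intrinsic"}), or \code{"free_trna"}/\code{"ternary"}.
#' @param multiplier positive scale factor.
#' @return Modified \code{ground_truth}.
#' @export
apply_effect <- function(truth, constant, multiplier) {
  stopifnot(is_ground_truth(truth), multiplier > 0)
  if (constant %in% rate_param_names()) {
    p <- as.list(unclass(truth$rates))
    p[[constant]] <- p[[constant]] * multiplier
    truth$rates <- do.call(rate_params, p)
  } else if (constant %in% names(truth$gtpase_rates)) {
    truth$gtpase_rates[[constant]] <- truth$gtpase_rates[[constant]] * multiplier
  } else if (constant %in% names(truth$halflife_min)) {
    truth$halflife_min[[constant]] <- truth$halflife_min[[constant]] * multiplier
  } else {
    stop("unknown constant: ", constant, call. = FALSE)
  }
  truth
}

# -- experiment designs ------------------------------------------------------

#' Experiment designs for the synthetic assay families
#'
#' Concentrations are post-mix unless \code{syringe_concentrations = TRUE},
#' in which case the 1:1 stopped-flow mixing factor of 2 is applied.
#'
#' @param nucleotide \code{"GDP"} or \code{"GTP"}.
#' @param tu_uM EF-Tu concentration (uM).
#' @param ligand_uM mant-nucleotide concentrations titrated (uM).
#' @param replicates replicate traces per concentration.
#' @param syringe_concentrations interpret concentrations as syringe values?
#' @return A design object (list with class tag).
#' @export
association_design <- function(nucleotide = c("GDP", "GTP"), tu_uM = 0.3,
                               ligand_uM = NULL, replicates = 10,
                               syringe_concentrations = FALSE) {
  nucleotide <- match.arg(nucleotide)
  if (is.null(ligand_uM)) {
    ligand_uM <- if (nucleotide == "GDP") c(0.5, 1, 2, 3, 4, 5)
                 else c(1, 2, 4, 6, 8, 10)
  }
  stopifnot(tu_uM >= 0, all(ligand_uM > 0), replicates >= 1)
  f <- if (syringe_concentrations) 0.5 else 1
  structure(list(family = "association", nucleotide = nucleotide,
                 tu_uM = tu_uM * f, ligand_uM = ligand_uM * f,
                 replicates = as.integer(replicates)),
            class = "experiment_design")
}

#' @rdname association_design
#' @param mant_uM mant-nucleotide used to pre-form the labeled complex (uM).
#' @param chase_uM unlabeled chase nucleotide (uM).
#' @export
chase_design <- function(nucleotide = c("GDP", "GTP"), tu_uM = 0.6,
                         mant_uM = 6, chase_uM = 60, replicates = 10,
                         syringe_concentrations = TRUE) {
  nucleotide <- match.arg(nucleotide)
  stopifnot(tu_uM > 0, mant_uM > 0, chase_uM >= 0, replicates >= 1)
  f <- if (syringe_concentrations) 0.5 else 1
  structure(list(family = "chase", nucleotide = nucleotide, tu_uM = tu_uM * f,
                 mant_uM = mant_uM * f, chase_uM = chase_uM * f,
                 replicates = as.integer(replicates)),
            class = "experiment_design")
}

#' @rdname association_design
#' @param ts_uM EF-Ts concentration grid (uM), spanning the linear regime.
#' @export
ts_titration_design <- function(nucleotide = c("GDP", "GTP"), tu_uM = 0.3,
                                mant_uM = 1, chase_uM = 400, ts_uM = NULL,
                                replicates = 11,
                                syringe_concentrations = TRUE) {
  nucleotide <- match.arg(nucleotide)
  if (is.null(ts_uM)) {
    # syringe values; post-mix grid tops out near 2 % saturation of the
    # release step within the points the linear-phase selection keeps, with
    # visible curvature above that for the selection rule to trim
    ts_uM <- if (nucleotide == "GDP") c(0.04, 0.08, 0.12, 0.18, 0.26, 0.4, 0.7, 1.2)
             else c(0.024, 0.048, 0.08, 0.11, 0.16, 0.24, 0.4, 0.7)
    if (!syringe_concentrations) ts_uM <- ts_uM / 2
  }
  stopifnot(tu_uM > 0, mant_uM > 0, chase_uM >= 0, all(ts_uM >= 0),
            replicates >= 1)
  f <- if (syringe_concentrations) 0.5 else 1
  structure(list(family = "ts_titration", nucleotide = nucleotide,
                 tu_uM = tu_uM * f, mant_uM = mant_uM * f,
                 chase_uM = chase_uM * f, ts_uM = ts_uM * f,
                 replicates = as.integer(replicates)),
            class = "experiment_design")
}

#' @rdname association_design
#' @param condition GTPase condition name (one of \code{"intrinsic"},
#'   \code{"efts_low"}, \code{"efts_high"}, \code{"ribo_70S"},
#'   \code{"ribo_50S"}, or \code{"none"} for a zero-enzyme control).
#' @param gtp_uM initial GTP (uM).
#' @param quench_times_s explicit quench times (s); when NULL they are placed
#'   from \code{expected_rate} at 1-6 \% substrate consumption (six
#'   linear-phase points) plus saturating points at 30 and 60 \%.
#' @param expected_rate expected total hydrolysis rate (uM/s) used to place
#'   default quench times; defaults to the package default truth for the
#'   condition plus background.
#' @export
gtpase_design <- function(condition = "intrinsic", gtp_uM = 20,
                          replicates = 3, quench_times_s = NULL,
                          expected_rate = NULL) {
  stopifnot(gtp_uM > 0, replicates >= 1)
  if (is.null(quench_times_s)) {
    if (is.null(expected_rate)) {
      tr <- default_truth()
      cond_rate <- if (condition %in% names(tr$gtpase_rates)) {
        tr$gtpase_rates[[condition]]
      } else 0
      expected_rate <- cond_rate + tr$gtpase_background
    }
    fracs <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.30, 0.60)
    quench_times_s <- -log(1 - fracs) * gtp_uM / expected_rate
  }
  stopifnot(all(quench_times_s > 0), !is.unsorted(quench_times_s, strictly = TRUE))
  structure(list(family = "gtpase", condition = condition, gtp_uM = gtp_uM,
                 replicates = as.integer(replicates),
                 quench_times_s = quench_times_s),
            class = "experiment_design")
}

#' @rdname association_design
#' @param with_ef_tu is the protecting 1.5 uM EF-Tu present?
#' @param n_times number of (log-spaced) sampling times.
#' @param span_halflives sampling window in units of the half-life.
#' @param noise_frac multiplicative (log-normal) noise sd.
#' @export
protection_design <- function(with_ef_tu = TRUE, n_times = 8,
                              span_halflives = 3, noise_frac = 0.02,
                              trna_uM = 1.08, tu_uM = if (with_ef_tu) 1.5 else 0) {
  stopifnot(n_times >= 5, span_halflives > 0, noise_frac >= 0)
  structure(list(family = "protection", with_ef_tu = isTRUE(with_ef_tu),
                 n_times = as.integer(n_times),
                 span_halflives = span_halflives, noise_frac = noise_frac,
                 trna_uM = trna_uM, tu_uM = tu_uM),
            class = "experiment_design")
}

#' @param trna_uM aminoacyl-tRNA concentration (uM), protection assay.
#' @name association_design
NULL

# deterministic per-trace seed stream from a master seed
trace_seed <- function(seed, index) {
  (as.integer(seed %% 1000003L) * 1009L + as.integer(index)) %% 2147483647L
}

branch_constants <- function(params, nucleotide) {
  if (nucleotide == "GDP") {
    list(kon = params[["k1"]], koff = params[["k1r"]],
         comb = effective_stimulated_constant(params[["k3"]], params[["k3r"]],
                                              params[["k4r"]]),
         k_release = params[["k4r"]])
  } else {
    list(kon = params[["k5"]], koff = params[["k5r"]],
         comb = effective_stimulated_constant(params[["k6"]], params[["k6r"]],
                                              params[["k7r"]]),
         k_release = params[["k7r"]])
  }
}

# -- generators --------------------------------------------------------------

#' Generate a pseudo-first-order association titration
#'
#' One noiseless full-scheme trajectory per ligand concentration, rendered
#' into \code{replicates} noisy fluorescence traces each. A warning is issued
#' when a concentration violates the pseudo-first-order margin
#' (ligand < 10 x EF-Tu).
#'
#' @param design an \code{\link{association_design}}.
#' @param truth a \code{\link{default_truth}}-style \code{ground_truth}.
#' @param seed master seed; the generator is a pure function of
#'   (design, truth, seed).
#' @return List of \code{\link{time_course}} records.
#' @export
generate_association_set <- function(design, truth = default_truth(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            design$family == "association", is_ground_truth(truth))
  low <- design$ligand_uM < 10 * design$tu_uM
  if (any(low)) {
    warning(sprintf(
      "pseudo-first-order margin violated at %s uM (< 10 x %.3g uM EF-Tu)",
      paste(design$ligand_uM[low], collapse = ", "), design$tu_uM),
      call. = FALSE)
  }
  system <- assemble_scheme(truth$rates)
  bc <- branch_constants(truth$rates, design$nucleotide)
  mant_sp <- if (design$nucleotide == "GDP") "GDPm" else "GTPm"
  records <- list()
  idx <- 0L
  for (ci in seq_along(design$ligand_uM)) {
    conc <- design$ligand_uM[ci]
    kapp <- predicted_kapp(bc$kon, bc$koff, conc * 1e-6)
    # record to plateau: window referenced to the terminal (post-depletion)
    # relaxation rate so the fitted exponential measures the tail rate, whose
    # depletion shift is nearly affine in concentration
    k_tail <- predicted_kapp(bc$kon, bc$koff,
                             max(conc - design$tu_uM, conc / 2) * 1e-6)
    t_end <- 8 / k_tail
    init <- species_state()
    init["Tu"] <- design$tu_uM * 1e-6
    init[mant_sp] <- conc * 1e-6
    traj <- simulate_trajectory(system, init,
                                t_end = t_end * rate_headroom(truth))
    for (r in seq_len(design$replicates)) {
      idx <- idx + 1L
      f <- replicate_rate_factor(truth, trace_seed(seed, 2L * idx - 1L))
      records[[idx]] <- trajectory_to_signal(
        traj, truth$obs, tet_uM = truth$tet_uM,
        seed = trace_seed(seed, 2L * idx), rate_scale = f, t_end = t_end,
        meta = list(family = "association", nucleotide = design$nucleotide,
                    ligand_uM = conc, tu_uM = design$tu_uM, replicate = r,
                    predicted_kapp = kapp))
    }
  }
  records
}

#' Generate a dissociation chase experiment
#'
#' The labeled complex is pre-equilibrated (equilibrium of EF-Tu with the
#' mant nucleotide), then mixed 1:1 with excess unlabeled nucleotide; the
#' labeled-complex decay is simulated on the full scheme. Warns when the
#' chase excess is below 10 x the labeled nucleotide.
#'
#' @inheritParams generate_association_set
#' @export
generate_chase_set <- function(design, truth = default_truth(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"), design$family == "chase",
            is_ground_truth(truth))
  if (design$chase_uM < 10 * design$mant_uM) {
    warning(sprintf(
      "chase excess %.3g uM < 10 x labeled nucleotide (%.3g uM); the fitted rate will underestimate the dissociation constant",
      design$chase_uM, design$mant_uM), call. = FALSE)
  }
  system <- assemble_scheme(truth$rates)
  bc <- branch_constants(truth$rates, design$nucleotide)
  mant_pool <- if (design$nucleotide == "GDP") "GDPm" else "GTPm"
  chase_pool <- design$nucleotide  # unlabeled species name
  pre <- equilibrium_state(system, stats::setNames(
    list(design$tu_uM * 1e-6 * 2, design$mant_uM * 1e-6 * 2),
    c("Tu", mant_pool)))
  init <- pre / 2                       # 1:1 mixing
  init[chase_pool] <- init[chase_pool] + design$chase_uM * 1e-6
  t_end <- 5 / bc$koff
  traj <- simulate_trajectory(system, init, t_end = t_end * rate_headroom(truth))
  lapply(seq_len(design$replicates), function(r) {
    f <- replicate_rate_factor(truth, trace_seed(seed, 2L * r - 1L))
    trajectory_to_signal(
      traj, truth$obs, tet_uM = truth$tet_uM, seed = trace_seed(seed, 2L * r),
      rate_scale = f, t_end = t_end,
      meta = list(family = "chase", nucleotide = design$nucleotide,
                  complex_uM = design$tu_uM, chase_uM = design$chase_uM,
                  mant_uM = design$mant_uM, replicate = r))
  })
}

#' Generate an EF-Ts titration of stimulated nucleotide dissociation
#'
#' Chase experiments at a grid of EF-Ts concentrations on the full scheme, so
#' saturation of the stimulated pathway is present in the data even though
#' the analysis uses only the linear initial phase. Warns when the grid
#' extends beyond the linear regime (predicted apparent rate above 20 \% of
#' the nucleotide-release constant).
#'
#' @inheritParams generate_association_set
#' @export
generate_ts_titration_set <- function(design, truth = default_truth(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            design$family == "ts_titration", is_ground_truth(truth))
  system <- assemble_scheme(truth$rates)
  bc <- branch_constants(truth$rates, design$nucleotide)
  high <- bc$comb * design$ts_uM * 1e-6 > 0.2 * bc$k_release
  if (any(high)) {
    warning(sprintf(
      "EF-Ts concentrations beyond the linear regime (predicted rate > 20%% of the release constant): %s uM",
      paste(design$ts_uM[high], collapse = ", ")), call. = FALSE)
  }
  mant_pool <- if (design$nucleotide == "GDP") "GDPm" else "GTPm"
  chase_pool <- design$nucleotide
  pre <- equilibrium_state(system, stats::setNames(
    list(design$tu_uM * 1e-6 * 2, design$mant_uM * 1e-6 * 2),
    c("Tu", mant_pool)))
  base_init <- pre / 2
  records <- list()
  idx <- 0L
  for (ci in seq_along(design$ts_uM)) {
    ts <- design$ts_uM[ci]
    init <- base_init
    init[chase_pool] <- init[chase_pool] + design$chase_uM * 1e-6
    init["Ts"] <- init["Ts"] + ts * 1e-6
    kapp <- bc$comb * ts * 1e-6 + bc$koff
    t_end <- 5 / kapp
    traj <- simulate_trajectory(system, init,
                                t_end = t_end * rate_headroom(truth))
    for (r in seq_len(design$replicates)) {
      idx <- idx + 1L
      f <- replicate_rate_factor(truth, trace_seed(seed, 2L * idx - 1L))
      records[[idx]] <- trajectory_to_signal(
        traj, truth$obs, tet_uM = truth$tet_uM,
        seed = trace_seed(seed, 2L * idx), rate_scale = f, t_end = t_end,
        meta = list(family = "ts_titration", nucleotide = design$nucleotide,
                    ts_uM = ts, complex_uM = design$tu_uM,
                    chase_uM = design$chase_uM, replicate = r,
                    predicted_kapp = kapp))
    }
  }
  records
}

#' Generate a multiple-turnover GTPase quench series
#'
#' Hydrolyzed GTP (uM) at discrete quench times, using a single-exponential
#' substrate-depletion approximation of the steady-state turnover:
#' \code{hyd(t) = S0 * (1 - exp(-(r_cond + r_bg) * t / S0))}, plus Gaussian
#' counting noise \code{sd = max(2\% of signal, 0.05 uM)}. A paired
#' no-enzyme background series (background rate only) is always emitted; the
#' returned list holds, per replicate, records with \code{meta$role} of
#' \code{"reaction"} and \code{"background"}.
#'
#' @inheritParams generate_association_set
#' @export
generate_gtpase_timecourse <- function(design, truth = default_truth(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"), design$family == "gtpase",
            is_ground_truth(truth))
  cond_rate <- if (design$condition %in% names(truth$gtpase_rates)) {
    truth$gtpase_rates[[design$condition]]
  } else if (design$condition == "none") 0
  else stop("unknown GTPase condition: ", design$condition, call. = FALSE)
  S0 <- design$gtp_uM
  tq <- design$quench_times_s
  if (sum((S0 * (1 - exp(-(cond_rate + truth$gtpase_background) * tq / S0))) <=
          0.1 * S0) < 4) {
    stop("quench design must include >= 4 points within 10% substrate consumption",
         call. = FALSE)
  }
  curve <- function(rate) S0 * (1 - exp(-rate * tq / S0))
  y_rxn <- curve(cond_rate + truth$gtpase_background)
  y_bg <- curve(truth$gtpase_background)
  noisy <- function(y, s) {
    sd <- pmax(0.02 * y, 0.05)
    y + withr::with_seed(s, stats::rnorm(length(y), 0, sd))
  }
  records <- list()
  for (r in seq_len(design$replicates)) {
    records[[length(records) + 1L]] <- time_course(
      tq, noisy(y_rxn, trace_seed(seed, 2L * r - 1L)),
      meta = list(family = "gtpase", kind = "hydrolyzed_gtp_uM",
                  condition = design$condition, role = "reaction",
                  gtp_uM = S0, tet_uM = truth$tet_uM, replicate = r,
                  time_unit = "s"))
    records[[length(records) + 1L]] <- time_course(
      tq, noisy(y_bg, trace_seed(seed, 2L * r)),
      meta = list(family = "gtpase", kind = "hydrolyzed_gtp_uM",
                  condition = design$condition, role = "background",
                  gtp_uM = S0, tet_uM = truth$tet_uM, replicate = r,
                  time_unit = "s"))
  }
  records
}

#' Generate an aminoacyl-ester protection decay
#'
#' Intact aminoacyl fraction versus time (minutes):
#' \code{intact(t) = exp(-ln 2 * t / t_half)} with multiplicative log-normal
#' noise. The half-life is the ground truth's \code{ternary} value when
#' EF-Tu is present, else \code{free_trna}.
#'
#' @inheritParams generate_association_set
#' @return A single \code{\link{time_course}} record (time in minutes).
#' @export
generate_protection_decay <- function(design, truth = default_truth(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            design$family == "protection", is_ground_truth(truth))
  th <- truth$halflife_min[[if (design$with_ef_tu) "ternary" else "free_trna"]]
  stopifnot(th > 0)
  times <- exp(seq(log(th / 20), log(design$span_halflives * th),
                   length.out = design$n_times))
  intact <- exp(-log(2) * times / th)
  if (design$noise_frac > 0) {
    intact <- intact * exp(withr::with_seed(
      seed, stats::rnorm(length(times), 0, design$noise_frac)))
  }
  time_course(times, intact,
              meta = list(family = "protection", kind = "intact_fraction",
                          with_ef_tu = design$with_ef_tu, tu_uM = design$tu_uM,
                          trna_uM = design$trna_uM, tet_uM = truth$tet_uM,
                          seed = seed, time_unit = "min"))
}
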