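#' Fit a single-exponential model to a time course
#'
#' Nonlinear least squares fit of \code{F(t) = F_inf + A * exp(-k_app * t)}
#' (Levenberg-Marquardt). Initialization: \code{F_inf} from the mean of the
#' final 10 \% of points, \code{A} from the first point, and \code{k_app}
#' from an ordinary linear fit of \code{log|F - F_inf|} over the first half
#' of the trace; up to 3 jittered restarts on non-convergence. The sign of
#' \code{A} is free, so rising (association) and decaying (dissociation)
#' traces are both supported. A trace whose fitted amplitude is
#' indistinguishable from the residual noise is reported as a failure rather
#' than silently returning a rate.
#'
#' @param trace a \code{\link{time_course}}.
#' @return Object of class \code{exp_fit}: \code{estimates} (named
#'   \code{F_inf}, \code{A}, \code{k_app}), \code{se}, residual \code{sigma},
#'   \code{converged} flag, \code{message}, \code{n}.
#' @export
fit_single_exponential <- function(trace) {
  stopifnot(inherits(trace, "time_course"))
  t <- trace$time; y <- trace$signal
  n <- length(t)
  if (n < 10) {
    return(exp_fit_failure(n, "fewer than 10 points"))
  }
  n_tail <- max(3L, ceiling(0.1 * n))
  f_inf0 <- mean(y[(n - n_tail + 1L):n])
  a0 <- y[1L] - f_inf0
  half <- seq_len(max(5L, floor(n / 2)))
  resid0 <- y[half] - f_inf0
  usable <- sign(resid0) == sign(a0) & abs(resid0) > 1e-12 * max(abs(y))
  k0 <- NA_real_
  if (sum(usable) >= 3 && abs(a0) > 0) {
    sl <- stats::coef(stats::lm(log(abs(resid0[usable])) ~ t[half][usable]))[2L]
    if (is.finite(sl) && sl < 0) k0 <- -sl
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- 2 / max(t)
  dat <- data.frame(t = t, y = y)
  attempt <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(y ~ F_inf + A * exp(-k_app * t), data = dat,
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  start <- list(F_inf = f_inf0, A = a0, k_app = k0)
  fit <- attempt(start)
  tries <- 0L
  while (inherits(fit, "error") && tries < 3L) {
    tries <- tries + 1L
    jit <- withr::with_seed(1000L + tries, stats::rnorm(3, 0, 0.3))
    fit <- attempt(list(F_inf = f_inf0 * (1 + 0.05 * jit[1]),
                        A = if (a0 != 0) a0 * exp(jit[2]) else diff(range(y)),
                        k_app = k0 * exp(jit[3])))
  }
  if (inherits(fit, "error")) {
    return(exp_fit_failure(n, paste("non-convergence:", conditionMessage(fit))))
  }
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  sigma <- stats::sigma(fit)
  names(est) <- names(se) <- c("F_inf", "A", "k_app")
  if (!is.finite(est[["k_app"]]) || est[["k_app"]] <= 0) {
    return(exp_fit_failure(n, "non-positive fitted rate"))
  }
  if (abs(est[["A"]]) < 3 * sigma / sqrt(n) * 2 ||
      (is.finite(se[["A"]]) && abs(est[["A"]]) < 2 * se[["A"]])) {
    return(exp_fit_failure(n, "amplitude indistinguishable from noise"))
  }
  span_warn <- diff(range(t)) < 2 / est[["k_app"]]
  if (span_warn) {
    warning(sprintf("trace spans %.3g s < 2/k_app = %.3g s; rate poorly constrained",
                    diff(range(t)), 2 / est[["k_app"]]), call. = FALSE)
  }
  structure(list(estimates = est, se = se, sigma = sigma, converged = TRUE,
                 message = "converged", n = n, short_span = span_warn,
                 meta = trace$meta),
            class = "exp_fit")
}

exp_fit_failure <- function(n, msg) {
  nav <- stats::setNames(rep(NA_real_, 3), c("F_inf", "A", "k_app"))
  structure(list(estimates = nav, se = nav, sigma = NA_real_, converged = FALSE,
                 message = msg, n = n, short_span = NA, meta = list()),
            class = "exp_fit")
}

#' Rate estimate container
#'
#' @param constant name of the estimated constant (e.g. \code{"k1"},
#'   \code{"comb_gdp"}, \code{"intrinsic"}, \code{"halflife_ternary"}).
#' @param value point estimate in SI-style base units (/M/s, /s, uM/s, or
#'   minutes for half-lives).
#' @param se standard error (same unit).
#' @param unit unit string.
#' @param condition named list describing the experimental condition.
#' @param n number of underlying traces/points.
#' @return Object of class \code{rate_estimate}.
#' @export
rate_estimate <- function(constant, value, se, unit, condition = list(), n = NA) {
  if (!is.na(se) && se < 0) stop("SE must be >= 0", call. = FALSE)
  structure(list(constant = constant, value = value, se = se, unit = unit,
                 condition = condition, n = n),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g +/- %.3g %s (n = %s)\n", x$constant, x$value,
              x$se, x$unit, x$n))
  invisible(x)
}

aggregate_kapp <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged exponential fits", call. = FALSE)
  k <- vapply(fits[ok], function(f) f$estimates[["k_app"]], numeric(1))
  list(mean = mean(k), se = if (length(k) > 1) stats::sd(k) / sqrt(length(k))
                            else NA_real_,
       n = length(k))
}

weighted_linear_fit <- function(x, y, se) {
  stopifnot(length(x) == length(y))
  use_weights <- !anyNA(se) && all(se > 0)
  fit <- if (use_weights) stats::lm(y ~ x, weights = 1 / se^2) else stats::lm(y ~ x)
  if (use_weights) {
    # point errors scale with the signal, so weighting by the observed values
    # attenuates the slope; one reweighting pass against the fitted line
    # (IRLS step) removes that correlation
    yhat <- stats::fitted(fit)
    se2 <- ifelse(is.finite(yhat / y) & yhat / y > 0, se * yhat / y, se)
    fit <- stats::lm(y ~ x, weights = 1 / se2^2)
    se <- se2
  }
  cf <- summary(fit)$coefficients
  slope_se <- cf["x", "Std. Error"]
  intercept_se <- cf["(Intercept)", "Std. Error"]
  if (use_weights) {
    # lm's SEs are residual-scaled with few degrees of freedom; also compute
    # the error-propagated SEs (point errors taken as known, sigma = 1) and
    # report the larger, so the SE is conservative against both lack of fit
    # and a lucky residual draw
    s <- max(abs(x))          # scale x to condition the normal equations
    X <- cbind(1, x / s)
    cov0 <- solve(t(X) %*% (X / se^2))
    slope_se <- max(slope_se, sqrt(cov0[2, 2]) / s)
    intercept_se <- max(intercept_se, sqrt(cov0[1, 1]))
  }
  list(slope = cf["x", "Estimate"], slope_se = slope_se,
       intercept = cf["(Intercept)", "Estimate"],
       intercept_se = intercept_se,
       n_points = length(x), weighted = use_weights, fit = fit)
}

group_mean_kapp <- function(fits, conc) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " non-converged fits dropped", call. = FALSE)
  }
  fits <- fits[ok]; conc <- conc[ok]
  k <- vapply(fits, function(f) f$estimates[["k_app"]], numeric(1))
  levels <- sort(unique(conc))
  agg <- t(vapply(levels, function(cc) {
    ki <- k[conc == cc]
    c(mean = mean(ki),
      sd = if (length(ki) > 1) stats::sd(ki) else NA_real_,
      n = length(ki))
  }, numeric(3)))
  # replicate scatter of stopped-flow rates is multiplicative, so the
  # relative spread is pooled across concentrations; this stabilizes the
  # per-point SEs (hence the fit weights) at modest replicate counts
  df_i <- agg[, "n"] - 1
  rel <- agg[, "sd"] / abs(agg[, "mean"])
  pooled_cv <- if (any(df_i > 0, na.rm = TRUE)) {
    sqrt(sum(df_i * rel^2, na.rm = TRUE) / sum(df_i[is.finite(rel)]))
  } else NA_real_
  data.frame(conc = levels, k_mean = agg[, "mean"],
             k_se = pooled_cv * abs(agg[, "mean"]) / sqrt(agg[, "n"]),
             k_sd = agg[, "sd"], n = agg[, "n"])
}

#' Secondary analysis of an association titration
#'
#' Replicate apparent rates are averaged per ligand concentration (SE of the
#' mean), then a weighted (1/SE^2) straight line of mean k_app versus molar
#' ligand concentration is fitted. The slope is the association rate
#' constant, the intercept estimates the dissociation rate constant.
#'
#' @param fits list of converged \code{\link{fit_single_exponential}} results.
#' @param ligand_uM ligand concentration (uM) per fit; taken from fit
#'   metadata when NULL.
#' @param constant name for the slope estimate (e.g. \code{"k1"}).
#' @param condition condition metadata attached to the estimates.
#' @return List with \code{k_on} and \code{intercept}
#'   (\code{\link{rate_estimate}}s) plus the per-concentration table.
#' @export
association_analysis <- function(fits, ligand_uM = NULL, constant = "k_on",
                                 condition = list()) {
  if (is.null(ligand_uM)) {
    ligand_uM <- vapply(fits, function(f) f$meta$ligand_uM, numeric(1))
  }
  tab <- group_mean_kapp(fits, ligand_uM)
  if (nrow(tab) < 3) stop("need >= 3 ligand concentrations", call. = FALSE)
  wf <- weighted_linear_fit(tab$conc * 1e-6, tab$k_mean, tab$k_se)
  list(k_on = rate_estimate(constant, wf$slope, wf$slope_se, "/M/s",
                            condition, n = sum(tab$n)),
       intercept = rate_estimate(paste0(constant, "_intercept"), wf$intercept,
                                 wf$intercept_se, "/s", condition,
                                 n = sum(tab$n)),
       table = tab)
}

#' Chase (dissociation) analysis
#'
#' Mean apparent rate across replicate chase traces with SE of the mean,
#' reported as the spontaneous dissociation constant.
#'
#' @param fits list of \code{exp_fit}s from chase traces.
#' @param constant name (e.g. \code{"k1r"} or \code{"k5r"}).
#' @param condition condition metadata.
#' @return A \code{\link{rate_estimate}}; with a single replicate the SE is
#'   NA and a warning is raised.
#' @export
chase_analysis <- function(fits, constant = "k_off", condition = list()) {
  agg <- aggregate_kapp(fits)
  if (is.na(agg$se)) {
    warning("single replicate: SE undefined", call. = FALSE)
  }
  rate_estimate(constant, agg$mean, agg$se, "/s", condition, n = agg$n)
}

#' EF-Ts titration analysis (combined stimulated-exchange constant)
#'
#' Apparent dissociation rates are averaged per EF-Ts concentration, the
#' linear initial regime is selected by a running quadratic-curvature F-test
#' (ascending concentrations retained while the quadratic term is
#' insignificant at \code{alpha}, minimum 4 points), and a weighted straight
#' line is fitted; its slope is the combined constant
#' \code{k_on_ts / (1 + k_off_ts / k_release)}.
#'
#' @param fits list of \code{exp_fit}s.
#' @param ts_uM EF-Ts concentration (uM) per fit; from metadata when NULL.
#' @param constant estimate name (\code{"comb_gdp"} / \code{"comb_gtp"}).
#' @param alpha significance level of the curvature test.
#' @param condition condition metadata.
#' @return List with \code{combined} (\code{\link{rate_estimate}}, /M/s),
#'   \code{intercept}, the per-concentration table and the retained points.
#' @export
ts_titration_analysis <- function(fits, ts_uM = NULL, constant = "comb",
                                  alpha = 0.05, condition = list()) {
  if (is.null(ts_uM)) {
    ts_uM <- vapply(fits, function(f) f$meta$ts_uM, numeric(1))
  }
  tab <- group_mean_kapp(fits, ts_uM)
  if (nrow(tab) < 4) {
    stop("need >= 4 EF-Ts concentrations in the linear regime", call. = FALSE)
  }
  keep <- 4L
  for (j in seq(5L, nrow(tab))) {
    if (j > nrow(tab)) break
    sub <- tab[seq_len(j), ]
    qfit <- stats::lm(k_mean ~ conc + I(conc^2), data = sub)
    pq <- summary(qfit)$coefficients
    p_curv <- if ("I(conc^2)" %in% rownames(pq)) pq["I(conc^2)", 4L] else 1
    if (is.finite(p_curv) && p_curv < alpha) break
    keep <- j
  }
  sub <- tab[seq_len(keep), ]
  if (nrow(sub) < 4) {
    stop("fewer than 4 points survive linear-regime selection; extend the low-EF-Ts grid",
         call. = FALSE)
  }
  wf <- weighted_linear_fit(sub$conc * 1e-6, sub$k_mean, sub$k_se)
  list(combined = rate_estimate(constant, wf$slope, wf$slope_se, "/M/s",
                                condition, n = sum(sub$n)),
       intercept = rate_estimate(paste0(constant, "_intercept"), wf$intercept,
                                 wf$intercept_se, "/s", condition,
                                 n = sum(sub$n)),
       table = tab, points_used = keep)
}

gtpase_initial_points <- function(series, background) {
  stopifnot(inherits(series, "time_course"), inherits(background, "time_course"))
  if (length(series$time) != length(background$time) ||
      max(abs(series$time - background$time)) > 1e-9 * max(series$time)) {
    stop("reaction and background series must share quench times", call. = FALSE)
  }
  s0 <- series$meta$gtp_uM
  if (is.null(s0)) stop("series metadata lacks gtp_uM", call. = FALSE)
  corrected <- series$signal - background$signal
  sel <- corrected <= 0.1 * s0
  if (sum(sel) < 4) {
    stop("fewer than 4 initial-phase points (<= 10% substrate consumed)",
         call. = FALSE)
  }
  data.frame(t = series$time[sel], y = corrected[sel])
}

#' Multiple-turnover GTPase initial rate
#'
#' Pointwise background subtraction, then an ordinary linear fit through the
#' initial-phase points (those with at most 10 \% of the substrate consumed
#' after correction, minimum 4); the slope is the turnover rate in uM/s.
#'
#' @param series reaction \code{time_course} (hydrolyzed GTP, uM).
#' @param background paired no-enzyme series on the same quench times.
#' @param constant estimate name.
#' @param condition condition metadata.
#' @return A \code{\link{rate_estimate}} (uM/s).
#' @export
gtpase_initial_rate <- function(series, background, constant = "k_gtpase",
                                condition = list()) {
  pts <- gtpase_initial_points(series, background)
  fit <- stats::lm(y ~ t, data = pts)
  cf <- summary(fit)$coefficients
  rate_estimate(constant, cf["t", "Estimate"], cf["t", "Std. Error"], "uM/s",
                condition, n = nrow(pts))
}

#' Pooled GTPase analysis over replicates
#'
#' Each replicate's background is subtracted pointwise, all initial-phase
#' points are pooled, and a single straight line is fitted (slope in uM/s,
#' SE from that fit). This mirrors fitting the linear phase of the plotted
#' time courses rather than averaging per-replicate slopes.
#'
#' @param records list of \code{time_course}s from
#'   \code{\link{generate_gtpase_timecourse}} (roles \code{"reaction"} and
#'   \code{"background"}).
#' @param constant estimate name (defaults to the condition in the metadata).
#' @param condition condition metadata.
#' @return A \code{\link{rate_estimate}} (uM/s).
#' @export
gtpase_analysis <- function(records, constant = NULL, condition = list()) {
  roles <- vapply(records, function(r) r$meta$role %||% "", character(1))
  reps <- vapply(records, function(r) r$meta$replicate %||% NA_integer_, numeric(1))
  rxn <- records[roles == "reaction"]
  bg <- records[roles == "background"]
  if (!length(rxn) || !length(bg)) {
    stop("records must contain paired reaction and background series", call. = FALSE)
  }
  bg_by_rep <- stats::setNames(bg, vapply(bg, function(r) as.character(r$meta$replicate),
                                          character(1)))
  pts <- do.call(rbind, lapply(rxn, function(s) {
    b <- bg_by_rep[[as.character(s$meta$replicate)]]
    if (is.null(b)) stop("missing background for replicate ", s$meta$replicate,
                         call. = FALSE)
    gtpase_initial_points(s, b)
  }))
  fit <- stats::lm(y ~ t, data = pts)
  cf <- summary(fit)$coefficients
  if (is.null(constant)) constant <- rxn[[1]]$meta$condition %||% "k_gtpase"
  rate_estimate(constant, cf["t", "Estimate"], cf["t", "Std. Error"], "uM/s",
                condition, n = length(rxn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First-order protection half-life
#'
#' Log-linear fit of the intact aminoacyl fraction versus time (the maximum-
#' likelihood fit under multiplicative noise); the half-life is
#' \code{ln 2 / k} with its SE by error propagation.
#'
#' @param series \code{time_course} of intact fraction versus minutes.
#' @param constant estimate name.
#' @param condition condition metadata.
#' @return A \code{\link{rate_estimate}} (minutes).
#' @export
protection_halflife <- function(series, constant = "halflife",
                                condition = list()) {
  stopifnot(inherits(series, "time_course"))
  t <- series$time; y <- series$signal
  if (length(t) < 5) stop("need >= 5 time points", call. = FALSE)
  if (any(y <= 0) || any(y > 1.25)) {
    stop("intact fraction must lie in (0, 1] (up to noise)", call. = FALSE)
  }
  fit <- stats::lm(log(y) ~ t)
  cf <- summary(fit)$coefficients
  k <- -cf["t", "Estimate"]; k_se <- cf["t", "Std. Error"]
  if (k <= 0) stop("non-decaying series: cannot report a half-life", call. = FALSE)
  rate_estimate(constant, log(2) / k, log(2) / k^2 * k_se, "min", condition,
                n = length(t))
}

#' Compare two rate estimates across conditions
#'
#' Two-sided z-test on the difference with pooled standard error:
#' \code{z = (a - b) / sqrt(SE_a^2 + SE_b^2)}; a difference is declared at
#' \code{alpha} (default 0.05, no multiplicity correction; apply
#' \code{\link[stats]{p.adjust}} externally if desired).
#'
#' @param a,b \code{\link{rate_estimate}}s of the same constant and unit.
#' @param alpha significance level.
#' @return List: \code{difference}, \code{pooled_se}, \code{z}, \code{p},
#'   \code{detected}.
#' @export
compare_conditions <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  if (a$constant != b$constant || a$unit != b$unit) {
    stop("estimates must be of the same constant and unit", call. = FALSE)
  }
  pooled <- sqrt(a$se^2 + b$se^2)
  z <- (a$value - b$value) / pooled
  p <- 2 * stats::pnorm(-abs(z))
  list(constant = a$constant, difference = a$value - b$value,
       pooled_se = pooled, z = z, p = p, detected = is.finite(p) && p < alpha,
       alpha = alpha)
}
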