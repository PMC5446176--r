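#' Stopped-flow observation parameters
#'
#' Maps species trajectories to the observed band-pass-filtered FRET signal.
#' The tetracycline autofluorescence enters only as an additive constant
#' offset: \code{alpha_tet = passband_fraction(tet_spectrum) * tet_brightness}
#' signal units per uM tetracycline. The absolute brightness scale of
#' tetracycline relative to mant under the FRET excitation is a free
#' calibration (\code{tet_brightness}).
#'
#' @param c0 baseline signal (signal units).
#' @param fret_amplitude signal units per uM of mant-nucleotide bound to EF-Tu.
#' @param tet_brightness signal units per uM tetracycline before band-pass
#'   attenuation.
#' @param tet_spectrum tetracycline emission spectrum (data.frame with
#'   \code{wavelength_nm}, \code{intensity}); defaults to the package's
#'   synthetic spectrum.
#' @param passband_center,passband_halfwidth band-pass filter (nm); default
#'   430 +/- 10 nm.
#' @param noise_frac Gaussian noise sd as a fraction of the noiseless trace's
#'   dynamic range (default 0.5 %).
#' @param noise_sd absolute Gaussian noise sd (signal units); overrides
#'   \code{noise_frac} when non-NULL.
#' @param dead_time instrument dead time (s): points before it are discarded.
#' @param sampling_hz sampling rate (points per second).
#' @param max_points cap on points per rendered trace.
#' @return Object of class \code{observation_params}.
#' @export
observation_params <- function(c0 = 0.2, fret_amplitude = 1.0,
                               tet_brightness = 0.02,
                               tet_spectrum = synthetic_tet_spectrum(),
                               passband_center = 430, passband_halfwidth = 10,
                               noise_frac = 0.005, noise_sd = NULL,
                               dead_time = 0.0015, sampling_hz = 1000,
                               max_points = 400) {
  stopifnot(noise_frac >= 0, is.null(noise_sd) || noise_sd >= 0,
            dead_time >= 0, passband_halfwidth > 0, sampling_hz > 0,
            max_points >= 10)
  alpha_tet <- passband_fraction(tet_spectrum, passband_center,
                                 passband_halfwidth) * tet_brightness
  structure(list(c0 = c0, fret_amplitude = fret_amplitude,
                 tet_brightness = tet_brightness, alpha_tet = alpha_tet,
                 passband_center = passband_center,
                 passband_halfwidth = passband_halfwidth,
                 noise_frac = noise_frac, noise_sd = noise_sd,
                 dead_time = dead_time, sampling_hz = sampling_hz,
                 max_points = max_points),
            class = "observation_params")
}

validate_spectrum <- function(spectrum) {
  if (!is.data.frame(spectrum) ||
      !all(c("wavelength_nm", "intensity") %in% names(spectrum))) {
    stop("spectrum must be a data.frame with wavelength_nm and intensity",
         call. = FALSE)
  }
  if (nrow(spectrum) < 2) stop("spectrum needs at least two points", call. = FALSE)
  if (is.unsorted(spectrum$wavelength_nm, strictly = TRUE)) {
    stop("spectrum wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(spectrum$intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  spectrum
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Fraction of an emission spectrum passed by a band-pass filter
#'
#' Trapezoidal integral of the spectrum over the passband divided by the
#' integral over the full support; the passband is clipped to the support,
#' and an empty overlap returns 0. This is the computation behind choosing a
#' filter that passes the mant emission peak (~440 nm) while rejecting
#' tetracycline autofluorescence (mostly > 450 nm).
#'
#' @param spectrum data.frame with \code{wavelength_nm}, \code{intensity}.
#' @param center,halfwidth passband center and half-width (nm).
#' @return Fraction in [0, 1].
#' @export
passband_fraction <- function(spectrum, center = 430, halfwidth = 10) {
  spectrum <- validate_spectrum(spectrum)
  stopifnot(halfwidth > 0)
  wl <- spectrum$wavelength_nm
  lo <- max(center - halfwidth, min(wl))
  hi <- min(center + halfwidth, max(wl))
  total <- trapz(wl, spectrum$intensity)
  if (lo >= hi || total <= 0) return(0)
  xs <- sort(unique(c(lo, hi, wl[wl > lo & wl < hi])))
  ys <- stats::approx(wl, spectrum$intensity, xout = xs)$y
  trapz(xs, ys) / total
}

#' Synthetic emission spectra (illustrative stand-ins)
#'
#' Smooth synthetic emission spectra with the qualitative features relevant
#' to the filter computation: tetracycline emitting mostly above 450 nm
#' (broad peak near 530 nm) and mant peaking near 440 nm. These are
#' constructed curves, not measured data; real spectra can be supplied as
#' two-column CSVs via \code{\link{read_spectrum}}.
#'
#' @return data.frame with \code{wavelength_nm} and \code{intensity}.
#' @export
synthetic_tet_spectrum <- function() {
  wl <- seq(380, 680, by = 4)
  data.frame(wavelength_nm = wl,
             intensity = exp(-((wl - 530) / 55)^2) + 0.05 * exp(-((wl - 440) / 40)^2))
}

#' @rdname synthetic_tet_spectrum
#' @export
synthetic_mant_spectrum <- function() {
  wl <- seq(380, 680, by = 4)
  data.frame(wavelength_nm = wl, intensity = exp(-((wl - 440) / 32)^2))
}

#' Time-course record
#'
#' The unit of data exchange: a time/signal table plus free-form metadata.
#'
#' @param time numeric time grid (units in \code{meta$time_unit}, default s).
#' @param signal numeric signal values (fluorescence, uM hydrolyzed GTP, or
#'   intact fraction, depending on the assay).
#' @param meta named list of experiment metadata.
#' @return Object of class \code{time_course}.
#' @export
time_course <- function(time, signal, meta = list()) {
  stopifnot(is.numeric(time), is.numeric(signal), length(time) == length(signal))
  if (any(time < 0)) stop("time values must be >= 0", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time values must be strictly increasing", call. = FALSE)
  }
  structure(list(time = time, signal = signal, meta = meta),
            class = "time_course")
}

#' Render a trajectory as an observed stopped-flow fluorescence trace
#'
#' \code{signal(t) = c0 + alpha_tet * tet_uM + fret_amplitude * bound_mant_uM(t)
#' + N(0, sd)}. Points before the instrument dead time are discarded; the
#' trace is resampled onto a uniform grid at the observation sampling rate
#' (capped at \code{max_points} points). Deterministic for a fixed seed.
#'
#' A per-replicate \code{rate_scale} factor models shot-to-shot experimental
#' variability (mixing, temperature, concentration errors) as a uniform
#' scaling of all apparent rates: the trace on the nominal window
#' \code{[dead_time, t_end]} reports the trajectory evaluated at
#' \code{rate_scale * t} (clamped to the simulated horizon, so the
#' trajectory should extend \code{rate_scale}-fold beyond \code{t_end}).
#'
#' @param traj a \code{trajectory} from \code{\link{simulate_trajectory}}.
#' @param obs an \code{\link{observation_params}} object.
#' @param tet_uM tetracycline concentration (uM).
#' @param seed integer seed for the noise realization.
#' @param meta extra metadata merged into the record.
#' @param rate_scale multiplicative apparent-rate factor for this replicate.
#' @param t_end nominal recording window end (s); defaults to the trajectory
#'   horizon divided by \code{rate_scale} headroom only when given.
#' @return A \code{\link{time_course}} record.
#' @export
trajectory_to_signal <- function(traj, obs, tet_uM = 0, seed = 1, meta = list(),
                                 rate_scale = 1, t_end = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(obs, "observation_params"),
            is.numeric(rate_scale), length(rate_scale) == 1, rate_scale > 0)
  missing <- setdiff(mant_bound_species(), colnames(traj$conc))
  if (length(missing)) {
    stop("trajectory lacks mant-labeled species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  t_max <- max(traj$time)
  if (is.null(t_end)) t_end <- t_max
  if (t_end <= obs$dead_time) {
    stop("trajectory does not extend beyond the dead time", call. = FALSE)
  }
  n <- min(max(floor(obs$sampling_hz * (t_end - obs$dead_time)), 10L),
           obs$max_points)
  grid <- seq(obs$dead_time, t_end, length.out = n)
  bound_uM <- rowSums(traj$conc[, mant_bound_species(), drop = FALSE]) * 1e6
  bound_grid <- stats::approx(traj$time, bound_uM,
                              xout = pmin(grid * rate_scale, t_max))$y
  noiseless <- obs$c0 + obs$alpha_tet * tet_uM + obs$fret_amplitude * bound_grid
  sd <- if (!is.null(obs$noise_sd)) obs$noise_sd
        else obs$noise_frac * diff(range(noiseless))
  noise <- if (sd > 0) withr::with_seed(seed, stats::rnorm(n, 0, sd)) else 0
  time_course(grid, noiseless + noise,
              meta = c(list(kind = "fluorescence", tet_uM = tet_uM, seed = seed,
                            rate_scale = rate_scale,
                            noise_sd = sd, dead_time = obs$dead_time,
                            c0 = obs$c0, alpha_tet = obs$alpha_tet,
                            fret_amplitude = obs$fret_amplitude,
                            time_unit = "s"),
                       meta))
}
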