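test_that("passband_fraction behaves like a clipped normalized integral", {
  sp <- synthetic_mant_spectrum()
  # passband covering the whole support -> all of the emission
  expect_equal(passband_fraction(sp, center = 530, halfwidth = 1000), 1)
  # empty overlap -> nothing
  expect_equal(passband_fraction(sp, center = 1000, halfwidth = 5), 0)
  # monotone in halfwidth
  f1 <- passband_fraction(sp, 430, 10)
  f2 <- passband_fraction(sp, 430, 30)
  expect_true(f1 > 0 && f1 < f2 && f2 <= 1)
})

test_that("the 430/10 filter passes mant but rejects tetracycline emission", {
  f_mant <- passband_fraction(synthetic_mant_spectrum(), 430, 10)
  f_tet <- passband_fraction(synthetic_tet_spectrum(), 430, 10)
  expect_gt(f_mant / f_tet, 10)
})

test_that("spectrum validation rejects malformed inputs", {
  expect_error(passband_fraction(data.frame(a = 1:3, b = 1:3)),
               "wavelength_nm and intensity")
  expect_error(
    passband_fraction(data.frame(wavelength_nm = c(2, 1),
                                 intensity = c(1, 1))),
    "strictly increasing")
  expect_error(
    passband_fraction(data.frame(wavelength_nm = c(1, 2),
                                 intensity = c(-1, 1))),
    ">= 0")
})

test_that("observation_params derives the tetracycline background coefficient", {
  obs <- observation_params(tet_brightness = 0.02)
  expect_equal(obs$alpha_tet,
               passband_fraction(synthetic_tet_spectrum(), 430, 10) * 0.02)
  expect_error(observation_params(noise_frac = -1))
})

test_that("time_course validates its grid", {
  expect_error(time_course(c(-1, 0, 1), c(1, 2, 3)), ">= 0")
  expect_error(time_course(c(0, 2, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(time_course(c(0, 1), c(1, 2, 3)))
})

make_traj <- function() {
  system <- assemble_scheme(default_rate_params())
  simulate_trajectory(system, species_state(Tu = 0.3e-6, GDPm = 2e-6),
                      t_end = 2)
}

test_that("trajectory_to_signal applies dead time, point cap and determinism", {
  traj <- make_traj()
  obs <- observation_params()
  s1 <- trajectory_to_signal(traj, obs, seed = 7)
  s2 <- trajectory_to_signal(traj, obs, seed = 7)
  s3 <- trajectory_to_signal(traj, obs, seed = 8)
  expect_identical(s1$signal, s2$signal)
  expect_false(identical(s1$signal, s3$signal))
  expect_gte(min(s1$time), obs$dead_time)
  expect_lte(length(s1$time), obs$max_points)
})

test_that("tetracycline enters as a pure additive offset", {
  traj <- make_traj()
  obs <- observation_params(noise_frac = 0)
  s0 <- trajectory_to_signal(traj, obs, tet_uM = 0)
  s100 <- trajectory_to_signal(traj, obs, tet_uM = 100)
  expect_equal(s100$signal - s0$signal,
               rep(obs$alpha_tet * 100, length(s0$signal)))
})

test_that("rate_scale compresses the time axis of the rendered trace", {
  traj <- make_traj()
  obs <- observation_params(noise_frac = 0)
  s2 <- trajectory_to_signal(traj, obs, rate_scale = 2, t_end = 1)
  bound_uM <- rowSums(traj$conc[, mant_bound_species(), drop = FALSE]) * 1e6
  ref <- obs$c0 + obs$fret_amplitude *
    stats::approx(traj$time, bound_uM, xout = s2$time * 2)$y
  expect_equal(s2$signal, ref, tolerance = 1e-12)
  expect_equal(s2$meta$rate_scale, 2)
})

test_that("trajectories shorter than the dead time are rejected", {
  traj <- make_traj()
  obs <- observation_params(dead_time = 0.0015)
  expect_error(trajectory_to_signal(traj, obs, t_end = 0.001), "dead time")
})
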