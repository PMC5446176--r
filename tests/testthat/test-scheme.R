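test_that("the scheme has 15 species with labeled/unlabeled pools", {
  sp <- species_names()
  expect_length(sp, 15)
  expect_true(all(mant_bound_species() %in% sp))
  expect_setequal(mant_bound_species(),
                  c("TuGDPm", "TuGTPm", "TuGDPmTs", "TuGTPmTs"))
})

test_that("species_state builds full vectors and validates", {
  y <- species_state(Tu = 1e-6, GDPm = 2e-6)
  expect_length(y, 15)
  expect_equal(y[["Tu"]], 1e-6)
  expect_equal(sum(y), 3e-6)
  expect_error(species_state(Bogus = 1), "unknown species")
  expect_error(species_state(Tu = -1e-6), ">= 0")
})

test_that("assemble_scheme enumerates the reversible steps", {
  sys_full <- assemble_scheme(default_rate_params())
  sys_nodir <- assemble_scheme(default_rate_params(),
                               include_direct_ts_path = FALSE)
  # 6 reversible steps per nucleotide-label pool (12 pairs) + direct Tu+Ts
  expect_equal(nrow(sys_full$reactions), 26)
  expect_equal(nrow(sys_nodir$reactions), 24)
  expect_true("ts_direct.fwd" %in% sys_full$reactions$name)
  expect_false("ts_direct.fwd" %in% sys_nodir$reactions$name)
  # zero rate constants keep their reactions in place with zero flux;
  # k1 drives one forward step in each of the two label pools
  sys0 <- assemble_scheme(rate_params(k1 = 1e6))
  expect_equal(nrow(sys0$reactions), 26)
  expect_equal(sum(sys0$reactions$k > 0), 2)
})

test_that("conserved pools hold to better than 1e-9 over a full trajectory", {
  system <- assemble_scheme(default_rate_params())
  init <- species_state(TuGDPm = 0.3e-6, GDP = 30e-6, Ts = 0.1e-6,
                        GTPm = 1e-6)
  traj <- simulate_trajectory(system, init, t_end = 2000)
  expect_lt(conservation_error(traj), 1e-9)
})

test_that("ODE solution matches the closed form for one binding step", {
  kon <- 2.1e6; koff <- 1.4e-3
  a0 <- 0.3e-6; b0 <- 1e-6
  system <- assemble_scheme(rate_params(k1 = kon, k1r = koff))
  traj <- simulate_trajectory(system,
                              species_state(Tu = a0, GDPm = b0),
                              t_end = 8 / (kon * (b0 - a0) + koff))
  ref <- reversible_binding_complex(traj$time, a0, b0, kon, koff)
  expect_lt(max(abs(traj$conc[, "TuGDPm"] - ref)) / max(ref), 1e-6)
})

test_that("equilibrium_state matches the quadratic isotherm", {
  p <- default_rate_params()
  system <- assemble_scheme(p)
  eq <- equilibrium_state(system, list(Tu = 1e-6, GDP = 1e-6))
  ref <- quadratic_isotherm_complex(1e-6, 1e-6, p[["k1r"]] / p[["k1"]])
  expect_lt(rel_err(eq[["TuGDP"]], ref), 1e-9)
})

test_that("equilibrium_state agrees with the long-time ODE limit", {
  system <- assemble_scheme(default_rate_params())
  totals <- list(Tu = 0.6e-6, GDPm = 1.2e-6, Ts = 0.2e-6, GTP = 0.5e-6)
  eq <- equilibrium_state(system, totals)
  init <- species_state(Tu = 0.6e-6, GDPm = 1.2e-6, Ts = 0.2e-6,
                        GTP = 0.5e-6)
  traj <- simulate_trajectory(system, init, t_end = 2e4)
  final <- traj$conc[nrow(traj$conc), ]
  big <- eq > 1e-12
  expect_lt(max(abs(final[big] - eq[big]) / eq[big]), 1e-5)
})

test_that("labeled and unlabeled pools are kinetically identical", {
  system <- assemble_scheme(default_rate_params())
  t_end <- 10
  tm <- simulate_trajectory(system, species_state(Tu = 0.3e-6, GDPm = 2e-6),
                            t_end = t_end)
  tu <- simulate_trajectory(system, species_state(Tu = 0.3e-6, GDP = 2e-6),
                            t_end = t_end)
  expect_equal(tm$conc[, "TuGDPm"], tu$conc[, "TuGDP"], tolerance = 1e-10)
  expect_equal(tm$conc[, "GDPm"], tu$conc[, "GDP"], tolerance = 1e-10)
})

test_that("simulate_trajectory validates inputs", {
  system <- assemble_scheme(default_rate_params())
  expect_error(simulate_trajectory(system, species_state(), t_end = NULL),
               "t_end")
  expect_error(simulate_trajectory(system, species_state(), grid = c(1, 2)),
               "start at 0")
  expect_error(simulate_trajectory(system, species_state(), grid = c(0, 2, 1)),
               "strictly increasing")
  expect_error(simulate_trajectory(system, c(Tu = -1e-6), t_end = 1), ">= 0")
})

test_that("pool_totals accepts single state vectors", {
  y <- species_state(TuGDPm = 1e-6, GDPm = 2e-6, TuTs = 5e-7)
  tot <- pool_totals(y)
  expect_equal(unname(tot[1, "Tu"]), 1.5e-6)
  expect_equal(unname(tot[1, "GDPm"]), 3e-6)
  expect_equal(unname(tot[1, "Ts"]), 5e-7)
})

test_that("thermodynamically inconsistent constants are rejected at equilibrium", {
  p <- as.list(unclass(default_rate_params()))
  p$k2r <- p$k2r * 10     # breaks Wegscheider consistency on the direct path
  bad <- do.call(rate_params, p)
  system <- assemble_scheme(bad)
  expect_error(equilibrium_state(system, list(Tu = 1e-6, Ts = 1e-6)),
               "thermodynamic consistency")
})
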