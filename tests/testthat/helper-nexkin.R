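# Closed-form bound-complex time course for one reversible bimolecular step
# A + B <-> C with C(0) = 0:
#   dx/dt = kon (a0 - x)(b0 - x) - koff x = kon (x - x_lo)(x - x_hi)
#   x(t)  = x_lo x_hi (1 - e^{-kt}) / (x_hi - x_lo e^{-kt}),  k = kon (x_hi - x_lo)
reversible_binding_complex <- function(t, a0, b0, kon, koff) {
  b <- kon * (a0 + b0) + koff
  disc <- sqrt(b^2 - 4 * kon^2 * a0 * b0)
  x_lo <- (b - disc) / (2 * kon)
  x_hi <- (b + disc) / (2 * kon)
  k <- kon * (x_hi - x_lo)
  x_lo * x_hi * (1 - exp(-k * t)) / (x_hi - x_lo * exp(-k * t))
}

# Closed-form equilibrium complex for A + B <-> C (quadratic isotherm)
quadratic_isotherm_complex <- function(a_tot, b_tot, kd) {
  s <- a_tot + b_tot + kd
  (s - sqrt(s^2 - 4 * a_tot * b_tot)) / 2
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
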