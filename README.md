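# nexkin

Simulation and inference for EF-Tu guanine-nucleotide exchange kinetics,
built to interrogate one question: **if tetracycline were only a fluorescent
nuisance — not a kinetic actor — would the standard stopped-flow analysis
pipeline correctly report "no effect"?**

EF-Tu delivers aminoacyl-tRNA to the ribosome, cycling between active
(GTP) and inactive (GDP) states; its exchange factor EF-Ts accelerates
nucleotide release. The classic characterization of this cycle rests on a
handful of assays:

* **pseudo-first-order association titrations** of mant-labeled GDP/GTP
  binding to EF-Tu (slope of apparent rate vs concentration → `k1`, `k5`),
* **chase experiments** (preformed labeled complex + excess unlabeled
  nucleotide → spontaneous dissociation rates `k1r`, `k5r`),
* **EF-Ts titrations** of stimulated release (linear-phase slope → the
  combined flux-partition constants `comb_gdp`, `comb_gtp`),
* **multiple-turnover GTPase** initial rates with background subtraction,
* **aminoacyl-ester protection** half-lives (ternary complex ~10× more
  stable than free aminoacyl-tRNA).

`nexkin` implements all of this twice over: a mass-action ODE model of the
full 15-species exchange scheme with a stopped-flow FRET observation model
(band-pass filter, dead time, noise, additive tetracycline
autofluorescence, shot-to-shot replicate variability), and the staged
estimators that turn the synthetic traces back into rate constants, with
honest standard errors, z-test condition comparisons, and Monte-Carlo power
analysis. The generating truth is tetracycline-invariant by construction,
so the pipeline's job is to reproduce the null cleanly — and to quantify
what effect sizes it *could* have detected.

## Worked example

Estimate the GDP association rate constant from a full synthetic titration
(6 concentrations × 10 replicate traces, simulated on the full ODE scheme
and fitted trace by trace), at 0 and 100 µM tetracycline, and compare:

```r
library(nexkin)

k1_0   <- estimate_constant("k1", default_truth(tet_uM = 0),   seed = 1)
k1_100 <- estimate_constant("k1", default_truth(tet_uM = 100), seed = 2)
print(k1_0)
#> k1 = 2.187e+06 +/- 6.31e+04 /M/s (n = 60)
print(k1_100)
#> k1 = 2.162e+06 +/- 5.68e+04 /M/s (n = 60)

str(compare_conditions(k1_0, k1_100))
#> List of 7
#>  $ constant  : chr "k1"
#>  $ difference: num 25353
#>  $ pooled_se : num 84936
#>  $ z         : num 0.298
#>  $ p         : num 0.765
#>  $ detected  : logi FALSE
#>  $ alpha     : num 0.05
```

The generating value is `2.1e6` /M/s; the estimate recovers it within 2
standard errors and the cross-condition z-test reports no difference.
`run_pipeline(default_run_config())` runs the same loop for all 13
constants across tetracycline levels and assembles the rate table and
comparison verdicts; `power_of_detection()` gives the detectable-effect
curve (with the default designs, a 1.5× change in the intrinsic GTPase rate
is detected with ~88 % power, a 2× change with ~100 %).

## Repository layout

```
R/                 package code (scheme, observation model, generators,
                   estimators, pipeline)
tests/testthat/    unit/property tests + test-acceptance.R (one block per
                   acceptance criterion)
scripts/acceptance.R   acceptance-target evaluation (JSON output)
analysis/          numbered reproduction drivers (run in order)
results/           small CSV outputs of the analysis stages
vignettes/         methods vignette (modeling & statistical choices)
```

## Reproduction

With the package installed, from the repository root:

```sh
Rscript analysis/01_simulate_experiments.R   # raw records -> results/data (~0.7 MB)
Rscript analysis/02_kinetic_constants.R      # Table 1 analogue -> results/table1.csv
Rscript analysis/03_gtpase_protection.R      # Tables 2-3 -> results/table{2,3}.csv
Rscript analysis/04_null_comparisons_power.R # null z-tests + power curve

Rscript scripts/acceptance.R --seed 1 --out acceptance.json
Rscript -e 'testthat::test_dir("tests/testthat", package = "nexkin",
                               load_package = "installed")'
```

Everything is deterministic given the seeds; `results/` checked in here was
produced by exactly these commands (stage 1's raw trace files are
regenerable and not kept in the tree).

Representative stage-2/3 output (seed 1, tetracycline 0; truth in the last
column):

```
 constant tet_uM value_scaled se_scaled unit_scaled true_scaled
       k1      0        2.154   0.05997  x10^6 /M/s         2.1
       k5      0        3.955   0.12537  x10^5 /M/s         3.9
      k1r      0        1.423   0.08069   x10^-3 /s         1.4
      k5r      0        1.338   0.06437   x10^-2 /s         1.4
 comb_gdp      0       13.405   0.38614  x10^6 /M/s        13.4
 comb_gtp      0       21.223   0.59973  x10^6 /M/s        21.9
```

with the protection ratio `10.93 ± 0.10` against a generating ratio of
`382/35 = 10.91`.

## Honest notes on acceptance status

The acceptance test suite (`tests/testthat/test-acceptance.R`) has five
blocks; four pass. The failing one is the strictest reading of the null
criterion — "no detected difference between tetracycline 0 and 100 µM in
≥95 % of seeded runs, for *every* constant". The generating truth is
exactly tetracycline-invariant, so failures are pure test-calibration
artifacts: the GTPase/protection standard errors come from linear fits with
few degrees of freedom, making the normal z-test slightly anti-conservative
(measured per-constant no-detection rates are 85–95 % over 20 seeds, versus
the nominal 95 %). The vignette's final section analyzes this in detail. We
chose to report the miss rather than inflate SEs or swap in a t-test, since
the z-test definition and the SE calibration (validated against Monte-Carlo
scatter) are both part of the package contract.
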