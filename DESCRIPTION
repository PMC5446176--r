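Package: nexkin
Title: Simulation and Inference for EF-Tu Guanine-Nucleotide Exchange Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mass-action simulation of the EF-Tu/EF-Ts guanine-nucleotide
    exchange scheme and the staged kinetic analysis used in stopped-flow
    FRET studies of nucleotide binding: pseudo-first-order association
    titrations, chase dissociation experiments, EF-Ts titrations of
    stimulated nucleotide release (flux-partitioned combined rate
    constants), multiple-turnover GTPase initial rates with background
    subtraction, and aminoacyl-ester protection half-lives. Includes
    synthetic-data generators with a stopped-flow observation model
    (band-pass filtered fluorescence, additive tetracycline
    autofluorescence background, dead time, Gaussian noise), single
    exponential and secondary linear fitting, condition comparison by
    z-test, and Monte-Carlo power analysis for rate-constant effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
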