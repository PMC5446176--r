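#!/usr/bin/env Rscript
# Stage 1: generate a representative synthetic data set for every assay
# family at tetracycline 0 and 100 uM and write the raw time-course records
# (CSV + JSON sidecars) under results/data/. Later stages re-generate data
# internally from seeds; this stage exists to materialize inspectable raw
# records in the exchange format.

suppressMessages(library(nexkin))

seed <- 1
out_root <- file.path("results", "data")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

write_set <- function(records, prefix) {
  if (inherits(records, "time_course")) records <- list(records)
  for (i in seq_along(records)) {
    write_timecourse(records[[i]],
                     file.path(out_root, sprintf("%s_%03d.csv", prefix, i)))
  }
  message(sprintf("%-28s %3d records", prefix, length(records)))
}

for (tet in c(0, 100)) {
  truth <- default_truth(tet_uM = tet)
  tag <- sprintf("tet%03d", tet)
  # one replicate per condition keeps the materialized set small; the
  # statistical stages use the full replicate counts internally
  write_set(suppressWarnings(generate_association_set(
    association_design("GDP", replicates = 1), truth, seed)),
    paste0("assoc_gdp_", tag))
  write_set(generate_chase_set(chase_design("GDP", replicates = 1), truth, seed),
            paste0("chase_gdp_", tag))
  write_set(generate_ts_titration_set(
    ts_titration_design("GDP", replicates = 1), truth, seed),
    paste0("ts_gdp_", tag))
  write_set(generate_gtpase_timecourse(
    gtpase_design("intrinsic", replicates = 1), truth, seed),
    paste0("gtpase_intrinsic_", tag))
  write_set(generate_protection_decay(protection_design(TRUE), truth, seed),
            paste0("protection_ternary_", tag))
}

message("raw records in ", out_root)
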