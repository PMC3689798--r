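# Shared paths for the analysis drivers. Run every driver from the
# repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_call_genotypes.R
#   ...
# Large intermediates go to scratch/ (not committed), small summary
# tables to results/ (not committed either; regenerate at will).

panel_dir <- "scratch/panel"
derived_dir <- "scratch/derived"
results_dir <- "results"
for (d in c(derived_dir, results_dir)) {
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
}

panel_seed <- 20260101L
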