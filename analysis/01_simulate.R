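#!/usr/bin/env Rscript
# Simulate the default synthetic diversity panel (2,000 SNPs x 100 lines:
# six cultivated market classes, genetic stocks, wild diploids) and write
# every pipeline input plus ground truth to scratch/panel/.

library(polypanel)
source("analysis/00_paths.R")

spec <- simulation_spec(seed = panel_seed)
paths <- emit_fixture_bundle(spec, panel_dir)
cat("wrote", length(paths), "files to", panel_dir, "\n")
cat(paste(" -", paths), sep = "\n")
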