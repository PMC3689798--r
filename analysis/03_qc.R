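#!/usr/bin/env Rscript
# Marker QC: missing-data filter (> 20%), multi-mapping removal
# (hit_count >= 2), flagged-boundary removal, and the boundary
# completeness census.

library(polypanel)
source("analysis/00_paths.R")

calls <- read_genotype_matrix(file.path(derived_dir, "calls.tsv"), "tetraploid")
report <- read_multimap_report(file.path(panel_dir, "multimap_report.tsv"))
bounds <- read_boundary_table(file.path(derived_dir, "boundaries.tsv"))

s1 <- filter_missing(calls)
s2 <- filter_multimapped(s1$retained, report)
s3 <- filter_flagged(s2$retained, bounds)

write_genotype_matrix(s3$retained, file.path(derived_dir, "calls_qc.tsv"))
removed <- rbind(s1$removed, s2$removed, s3$removed)
utils::write.table(removed, file.path(results_dir, "qc_removed_snps.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

census <- boundary_completeness_census(bounds)
summary <- data.frame(
  stage = c("input", "removed_missing", "removed_multimapped",
            "removed_flagged", "retained",
            paste0("census_defined_", names(census$counts)),
            "census_unusable"),
  n_snps = c(nrow(calls), nrow(s1$removed), nrow(s2$removed),
             nrow(s3$removed), nrow(s3$retained),
             unname(census$counts), census$unusable))
utils::write.table(summary, file.path(results_dir, "qc_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(summary)
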