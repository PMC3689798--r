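#!/usr/bin/env Rscript
# Diversity statistics on the QC-passed calls: per-line percent
# heterozygosity, group summaries, the n = 12 subsampling correction for
# unequal group sizes, and the allele-dosage frequency spectrum.

library(polypanel)
source("analysis/00_paths.R")

g <- read_genotype_matrix(file.path(derived_dir, "calls_qc.tsv"), "tetraploid")
metadata <- read_sample_metadata(file.path(panel_dir, "metadata.tsv"))

het <- percent_heterozygosity(g)
utils::write.table(het, file.path(results_dir, "heterozygosity_per_line.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (grouping in c("group", "market_class")) {
  tab <- group_summary(het, metadata, grouping)
  utils::write.table(tab,
                     file.path(results_dir,
                               paste0("heterozygosity_by_", grouping, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  print(tab)
}

# compare the 86 cultivated lines against the 4 wild accessions on equal
# footing: 10,000 subsamples of 12 cultivated lines
cult <- metadata$line_name[metadata$group == "cultivated"]
subs <- subsample_heterozygosity(het[het$line_name %in% cult, ],
                                 subsample_size = 12L, replicates = 10000L,
                                 seed = panel_seed)
sub_tab <- data.frame(statistic = c("mean", "min", "max",
                                    names(subs$percentiles)),
                      subsample_mean_het_pct = c(subs$mean, subs$min, subs$max,
                                                 unname(subs$percentiles)))
utils::write.table(sub_tab, file.path(results_dir, "subsample_correction.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tet <- metadata$line_name[metadata$ploidy == 4L]
spectrum <- dosage_spectrum(g[, intersect(colnames(g), tet)], metadata)
utils::write.table(spectrum$per_group,
                   file.path(results_dir, "dosage_spectrum_by_class.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(spectrum$per_group)
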