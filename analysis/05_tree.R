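#!/usr/bin/env Rscript
# Rogers distances from within-individual allele frequencies, UPGMA
# clustering of the tetraploid lines, Newick export, and the
# market-class concentration summary.

library(polypanel)
source("analysis/00_paths.R")

g <- read_genotype_matrix(file.path(derived_dir, "calls_qc.tsv"), "tetraploid")
metadata <- read_sample_metadata(file.path(panel_dir, "metadata.tsv"))

tet <- intersect(colnames(g), metadata$line_name[metadata$ploidy == 4L])
freqs <- individual_allele_frequencies(g[, tet])
d <- rogers_distance_matrix(freqs)
utils::write.table(data.frame(line_name = rownames(d), d, check.names = FALSE),
                   file.path(derived_dir, "rogers_distances.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tree <- upgma_tree(d)
write_newick_tree(tree, file.path(results_dir, "upgma_tree.nwk"))

conc <- class_concentration(tree, metadata)
utils::write.table(conc, file.path(results_dir, "class_concentration.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(conc)
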