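#!/usr/bin/env Rscript
# Candidate-gene enrichment: allele- and genotype-frequency chi-square
# tests for the carotenoid (Yellow), carbohydrate (Chip and French Fry
# Processing) and glycoalkaloid (cultivated vs wild, diploid model)
# panels, each against a 200-SNP random baseline.

library(polypanel)
source("analysis/00_paths.R")

g <- read_genotype_matrix(file.path(derived_dir, "calls_qc.tsv"), "tetraploid")
metadata <- read_sample_metadata(file.path(panel_dir, "metadata.tsv"))

read_cands <- function(panel) {
  utils::read.delim(file.path(panel_dir,
                              paste0("candidates_", panel, ".tsv")))$snp_id
}
designs <- builtin_designs(
  carotenoid = intersect(read_cands("carotenoid"), rownames(g)),
  carbohydrate = intersect(read_cands("carbohydrate"), rownames(g)),
  glycoalkaloid = intersect(read_cands("glycoalkaloid"), rownames(g)))

rows <- list()
results <- list()
for (nm in names(designs)) {
  des <- designs[[nm]]
  gg <- if (des$model == "diploid") collapse_to_diploid(g) else g
  pan <- run_panel(gg, des, metadata)
  base <- random_snp_baseline(gg, des, metadata, n_random = 200L,
                              seed = panel_seed)
  rows[[nm]] <- rbind(pan$summary, base$summary)
  results[[nm]] <- pan$results
}
summary <- do.call(rbind, c(rows, make.row.names = FALSE))
utils::write.table(summary, file.path(results_dir, "enrichment_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(do.call(rbind, c(results, make.row.names = FALSE)),
                   file.path(results_dir, "enrichment_per_snp.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(summary)
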