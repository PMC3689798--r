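# polypanel

Dosage genotyping and diversity analysis for autotetraploid SNP-array
panels.

A biallelic SNP in an autotetraploid crop such as cultivated potato
carries 0–4 copies of the B allele. On a two-channel genotyping array
this dosage is encoded in the normalized intensity angle theta: lines
cluster at up to five positions between 0 (`AAAA`) and 1 (`BBBB`).
`polypanel` turns theta matrices into genotype calls and carries them
through a complete diversity workflow:

* **Dosage calling** — per-SNP Gaussian-mixture cluster boundaries,
  with class identities anchored by F1 mapping families through
  expected autotetraploid segregation ratios (random chromosomal
  segregation, no double reduction), and a 3-class diploid model for
  mixed-ploidy comparisons.
* **Marker QC** — strict >20% missing-data filter, multi-mapped marker
  removal (`hit_count >= 2`), low-quality boundary flags, and a
  boundary completeness census.
* **Diversity** — per-line percent heterozygosity, unweighted group
  summaries, a subsampling correction for unequal group sizes, and the
  allele-dosage frequency spectrum (homozygous / single-dose / duplex).
* **Distances and trees** — Rogers distances from within-individual
  allele frequencies (pairwise deletion), deterministic UPGMA trees,
  Newick export, and a market-class concentration statistic.
* **Enrichment** — chi-square allele- and genotype-frequency tests of
  candidate-gene SNPs between market classes, with random-SNP
  baselines and built-in comparison designs.
* **Synthetic data** — a structured panel generator with exact ground
  truth (true dosages, planted selected loci, planted multi-mappers)
  for end-to-end validation.

See `vignettes/methods.Rmd` for the statistical details, parameter
rationales, and limitations.

## Worked example

Simulate a small structured panel (six cultivated market classes,
genetic stocks, wild diploids), call dosages, run QC, and summarize
diversity:

```r
library(polypanel)

spec <- simulation_spec(n_snps = 500L, seed = 42L)
sim  <- simulate_panel(spec)

bounds <- estimate_boundaries(sim$theta, sim$metadata, "tetraploid")
calls  <- call_genotypes(sim$theta, bounds)
calls
#> genotype_matrix: 500 SNPs x 100 samples (tetraploid model), 2.1% missing

qc <- filter_missing(calls)
qc <- filter_multimapped(qc$retained, sim$multimap_report)
qc <- filter_flagged(qc$retained, bounds)
g  <- qc$retained
g
#> genotype_matrix: 475 SNPs x 100 samples (tetraploid model), 2.1% missing

het <- percent_heterozygosity(g)
group_summary(het, sim$metadata, "group")
#>           group n_lines     mean      min      max
#> 1    cultivated      86 62.40326 58.45824 66.80851
#> 2 genetic_stock      10 41.28509 39.65885 43.37607
#> 3          wild       4 31.40525 30.23758 32.25806
```

Cultivated tetraploids are far more heterozygous than the wild
diploid relatives — partly real, partly array ascertainment bias,
which the generator reproduces on purpose. Cluster the tetraploid
lines and check that each market class lands on a single branch:

```r
tet  <- sim$metadata$line_name[sim$metadata$ploidy == 4L]
tree <- upgma_tree(rogers_distance_matrix(individual_allele_frequencies(g[, tet])))
class_concentration(tree, sim$metadata)
#>          market_class n_lines n_subtrees
#> 1      ChipProcessing      28          1
#> 2 FrenchFryProcessing      14          1
#> 3           Pigmented      13          1
#> 4     RoundWhiteTable      15          1
#> 5         TableRusset       5          1
#> 6              Yellow      11          1
```

Test the planted carotenoid candidate panel for enrichment in Yellow
lines:

```r
des <- builtin_designs(carotenoid = sim$candidates$carotenoid$snp_id)$carotenoid_yellow
run_panel(g, des, sim$metadata)$summary
#>              design alpha n_candidates n_allele_testable n_genotype_testable
#> 1 carotenoid_yellow  0.05           10                10                   9
#>   allele_significant_fraction genotype_significant_fraction
#> 1                         0.6                     0.4444444
```

Five of the ten candidates were planted with a 0.4 frequency shift in
Yellow lines; compare the significant fraction against
`random_snp_baseline()` rather than against alpha alone (see the
vignette for why the raw test is anti-conservative between groups of
comparable size).

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline on the
default 2,000-SNP panel, writing intermediates to `scratch/` and
summary tables to `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_genotypes.R
Rscript analysis/03_qc.R
Rscript analysis/04_diversity.R
Rscript analysis/05_tree.R
Rscript analysis/06_enrichment.R
```

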