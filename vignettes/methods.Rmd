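---
title: "Methods: dosage genotyping and diversity analysis for autotetraploid SNP-array panels"
output: rmarkdown::html_document
---

<!-- Source-form methods document; not built at install time. -->

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypanel)
```

# Scope

`polypanel` converts normalized two-channel SNP-array intensities
("theta" values in [0, 1]) into genotype calls for autotetraploid crop
panels, and carries those calls through marker quality control,
diversity statistics, distance-based clustering, and candidate-gene
enrichment tests. A synthetic-panel generator with full ground truth
closes the loop for end-to-end validation.

# The calling models

A biallelic SNP in an autotetraploid can be scored two ways:

* **diploid model** — three classes `AA`, `AB`, `BB`, ignoring how many
  of the four homologous copies carry the B allele;
* **tetraploid (dosage) model** — five classes `AAAA` … `BBBB`, the
  count of B alleles (0–4).

Theta encodes dosage: lines homozygous AAAA sit near 0, BBBB near 1,
and the three heterozygous classes form intermediate clusters. The
package convention is ascending theta ↔ ascending B dosage
(`orientation = "descending"` flips it for the opposite strand
convention).

# Boundary estimation

`estimate_boundaries()` fits, per SNP, a one-dimensional Gaussian
mixture to the non-missing theta values of the *ploidy-matched* lines:

* **Fixed component count** equal to the model's class count (5 or 3),
  initialized at the prior cluster centers (`run_config()` defaults
  0.05, 0.275, 0.50, 0.725, 0.95 tetraploid; 0.10, 0.50, 0.90 diploid)
  with initial SD `noise_sd = 0.03`. A floor of 0.005 on component SDs
  prevents degenerate spikes.
* **Component pruning.** After EM convergence, components holding
  posterior mass below 2/n (fewer than two expected samples) are
  dropped: dosage classes absent from the panel get no interval, so
  they can never be called.
* **Component merging.** Adjacent components merge when their means sit
  closer than half the `min_separation` (0.02), or when their
  two-component density has no real valley between the means (internal
  minimum above half the lower peak, roughly a 3.3-sigma separation
  requirement). The second rule removes a classic EM artifact: a
  spurious floor-SD component latched onto the tail of one genuine
  cluster.
* **Boundaries** between adjacent retained components are placed at the
  equal-posterior point (root of the log-posterior-odds, found with
  `uniroot`), falling back to the midpoint of the means when the
  densities barely overlap. Calling intervals are left-closed,
  right-open; a value exactly on a boundary goes to the
  higher-dosage side.
* **Flags.** SNPs whose retained clusters sit closer than
  `min_separation = 0.04` or spread wider than `max_spread = 0.10` are
  flagged `low_quality`; SNPs with fewer than two scored samples are
  `all_missing`. Flagged SNPs are removed by `filter_flagged()`.

Mixed-ploidy panels matter here: wild diploid relatives cluster at the
*diploid* centers (0.1, 0.5, 0.9), which fall between tetraploid
dosage clusters. Boundary estimation therefore defaults to the lines
whose ploidy matches the model; diploid accessions are either called
under the diploid model or compared through `collapse_to_diploid()`.

## F1 anchoring

With a mapping family in the metadata (`parent1`, `parent2`,
`f1_progeny` sharing a `family_id`), cluster *identities* are chosen by
segregation evidence instead of proximity to the prior centers. For
every monotone assignment of the retained clusters to class labels, the
observed progeny cluster occupancies are scored by their multinomial
log-likelihood under the expected F1 segregation ratios given the
implied parental classes (probability floor 10^-6 guards classes the
assignment says should not appear). The best-scoring assignment wins;
prior-center proximity only breaks exact ties. This matters when a SNP
shows few clusters: two clusters near 0.30 and 0.52 look like
`AAAB`/`AABB` by position, but a clean 1:1 progeny split with one
parent per cluster is far more likely under `AAAA` x `AAAB`.

`expected_f1_segregation()` implements random chromosomal segregation
without double reduction: a tetraploid gamete carries any 2 of the 4
homologues with equal probability, so its B count is hypergeometric,
and offspring dosage is the convolution of the two parental gamete
distributions.

# Marker QC

* `filter_missing()` removes SNPs whose missing fraction is *strictly*
  greater than 20% (50 of 250 missing is retained; 51 is removed).
* `filter_multimapped()` removes SNPs whose genome `hit_count` is 2 or
  more; SNPs absent from the report are retained with a warning.
* `boundary_completeness_census()` reports how many SNPs resolved 5,
  4, 3, or 2 dosage clusters; fewer than 2 is unusable.

# Diversity statistics

* `percent_heterozygosity()`: a tetraploid call is heterozygous when it
  is simplex, duplex, or triplex (`AAAB`, `AABB`, `ABBB`); denominators
  are per-line non-missing counts.
* `group_summary()` reports *unweighted* group means, so a 28-line
  class and a 5-line class contribute equally interpretable rows.
* `subsample_heterozygosity()` corrects the comparison of a large group
  against a small one by repeatedly (default use: 10,000 times) drawing
  subsamples of the small group's size and recording the subsample
  mean.
* `dosage_spectrum()` splits heterozygous calls into single-dose
  (simplex/triplex) and duplex fractions; cultivated potato shows
  roughly a 2:2:1 homozygous : single-dose : duplex pattern.
* `individual_allele_frequencies()` returns within-individual B
  frequencies (dosage / ploidy), the input for distances.

# Distances and trees

The Rogers distance between two lines at one biallelic locus,
sqrt(0.5 * sum over alleles of (p - q)^2), reduces to |pB_i - pB_j|;
`rogers_distance_matrix()` averages it over the loci scored in both
lines (pairwise deletion) and errors if a pair shares no loci.
`upgma_tree()` wraps `stats::hclust(method = "average")` and
`ape::as.phylo()` (which halves merge heights, so cophenetic distances
on the tree equal the merge distances); labels are sorted
lexicographically first so tie-breaking is deterministic.
`class_concentration()` counts, per market class, the maximal
pure-class clades — 1 means the class sits on a single branch.

# Enrichment tests

`allele_freq_test()` and `genotype_freq_test()` are chi-square
goodness-of-fit tests with the *reference set as expectation*: observed
focal-line allele copies (each line contributes `ploidy` copies) or
class counts are compared to the focal total scaled by the reference
proportions. Degrees of freedom are 1 for the allele test and
(categories - 1), capped at 4 (tetraploid) or 2 (diploid), for the
genotype test. A SNP is not testable when either side has fewer than
two scored lines, the reference is fixed, or a focal genotype class is
absent from the reference.

Two caveats are inherent to this construction and should temper
interpretation:

1. **Reference-as-expectation inflation.** Treating reference
   proportions as known inflates the statistic by roughly
   1 + n_focal/n_reference; the acceptance calibration therefore uses a
   large reference (1,500 lines against 80 focal), where the type I
   rate lands at the nominal 5%. With groups of comparable size the
   test is anti-conservative — compare candidates against the
   `random_snp_baseline()` rather than against alpha alone.
2. **Pseudo-replication of allele copies.** Counting `ploidy` copies
   per line assumes the four homologues are independent draws; within
   structured germplasm they are not, which further inflates
   significance. Again, the random-SNP baseline carries the same
   inflation and is the fair comparator.

`builtin_designs()` encodes the standard comparisons: carotenoid
candidates in Yellow vs all other cultivated classes, carbohydrate
candidates in Chip Processing vs other classes and French Fry
Processing vs non-processing classes (tetraploid model), and
glycoalkaloid candidates in cultivated vs wild accessions (diploid
model, because wild lines are diploid).

# The synthetic generator

`simulate_panel()` draws a structured panel with full ground truth.
Defaults give a desk-scale panel of 2,000 SNPs x 100 lines whose
market-class proportions mirror a 250-line diversity panel: 86
cultivated tetraploids across six market classes, 10 tetraploid
genetic stocks, 4 wild diploids.

* Cultivated classes share a baseline B frequency (uniform on
  [0.05, 0.95]) perturbed per class by N(0, 0.10) divergence — enough
  for classes to separate on a 2,000-locus tree without making them
  trivially distinct.
* Wild accessions draw frequencies from Beta(0.2, 0.2) (skewed toward
  fixation — array SNPs are ascertained in cultivated germplasm, so
  wild lines look artificially homozygous); genetic stocks use
  Beta(0.4, 0.4).
* Dosage is Binomial(ploidy, frequency); theta is Normal around the
  dosage's cluster center (SD `noise_sd = 0.03`), truncated to [0, 1]
  by rejection sampling (no probability mass piles up at the ends);
  missingness is Bernoulli (2%) and 5% of SNPs are planted with
  hit_count >= 2.
* Three candidate panels are planted: carotenoid (5 of 10 SNPs shifted
  0.4 in Yellow), carbohydrate (6 of 12 shifted in Chip Processing),
  and glycoalkaloid (no selected loci — a null panel; against the wild
  reference its significant fraction matches the random baseline,
  which is itself high because cultivated and wild germplasm differ
  nearly everywhere).

Deliberate simplifications: loci are independent (no linkage
disequilibrium), meiosis has no double reduction, there is no pedigree
or breeding-history coalescent, and class divergence is a single
Gaussian perturbation rather than drift along a phylogeny. These keep
ground truth exact and the generator transparent; they also mean the
generator cannot probe LD-aware methods.

# Problem sizes

All defaults are desk-scale choices of this package (2,000 SNPs, 100
lines, 10,000 subsample replicates) so that the full pipeline runs in
well under a minute per step on one CPU; every size is a parameter.
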