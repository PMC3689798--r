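test_that("panel simulation is reproducible and respects its invariants", {
  spec <- simulation_spec(n_snps = 150, seed = 7)
  s1 <- simulate_panel(spec)
  s2 <- simulate_panel(spec)
  expect_identical(s1$theta, s2$theta)
  expect_identical(s1$truth$dosage, s2$truth$dosage)

  expect_true(all(s1$theta >= 0 & s1$theta <= 1, na.rm = TRUE))
  expect_true(all(s1$truth$freqs >= 0 & s1$truth$freqs <= 1))
  tet <- s1$metadata$ploidy == 4L
  expect_true(all(s1$truth$dosage[, tet] %in% 0:4))
  expect_true(all(s1$truth$dosage[, !tet] %in% 0:2))
})

test_that("noise-free simulation is recovered exactly from true boundaries", {
  spec <- simulation_spec(n_snps = 80, noise_sd = 1e-4, missing_rate = 0,
                          seed = 11)
  sim <- simulate_panel(spec)
  centers <- spec$theta_centers_tetraploid
  bt <- data.frame(snp_id = rownames(sim$theta), model = "tetraploid",
                   flag = "ok", stringsAsFactors = FALSE)
  bt$boundaries <- rep(list((centers[-1] + centers[-5]) / 2), nrow(bt))
  bt$defined_classes <- rep(list(genotype_classes("tetraploid")), nrow(bt))
  g <- call_genotypes(sim$theta, bt)
  tet <- sim$metadata$line_name[sim$metadata$ploidy == 4L]
  expect_identical(unname(dosage_of(g[, tet])),
                   unname(sim$truth$dosage[, tet]))
})

test_that("heterozygosity structure matches closed-form and ordering expectations", {
  # all-cultivated panel at B frequency ~ 0.5: expected heterozygous
  # fraction per line is 1 - 2 * 0.5^4 = 0.875
  spec <- simulation_spec(
    n_snps = 2000,
    class_sizes = c(Yellow = 10L), n_genetic_stock = 0L, n_wild = 0L,
    cultivated_freq_range = c(0.5, 0.5), class_divergence_sd = 1e-9,
    candidate_panels = list(), seed = 13)
  sim <- simulate_panel(spec)
  het <- colMeans(sim$truth$dosage > 0 & sim$truth$dosage < 4)
  expect_equal(mean(het), 0.875, tolerance = 0.01)

  # wild frequencies near fixation push heterozygosity below cultivated
  p <- get_default_panel()
  md <- p$sim$metadata
  expect_lt(mean(p$sim$truth$het_true[md$group == "wild"]),
            mean(p$sim$truth$het_true[md$group == "cultivated"]))
  expect_lt(mean(p$sim$truth$het_true[md$group == "genetic_stock"]),
            mean(p$sim$truth$het_true[md$group == "cultivated"]))
})

test_that("F1 family simulation honors segregation and determinism", {
  fam <- simulate_f1_family(0L, 0L, 50, seed = 3)
  expect_true(all(fam$truth$dosage == 0L))

  fam1 <- simulate_f1_family(1L, 1L, 6000, seed = 4)
  fam2 <- simulate_f1_family(1L, 1L, 6000, seed = 4)
  expect_identical(fam1$truth$dosage, fam2$truth$dosage)
  counts <- tabulate(fam1$truth$dosage[1, -(1:2)] + 1L, nbins = 5)
  expected <- 6000 * c(1, 2, 1, 0, 0) / 4
  sigma <- sqrt(6000 * c(1, 2, 1, NA, NA) / 4 * (1 - c(1, 2, 1, NA, NA) / 4))
  expect_true(all(abs(counts[1:3] - expected[1:3]) < 3 * sigma[1:3]))
  expect_identical(counts[4:5], c(0L, 0L))
})

test_that("fixture bundles load end-to-end through the readers", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(n_snps = 120, seed = 21)
  paths <- emit_fixture_bundle(spec, dir)
  expect_true(all(file.exists(paths)))

  theta <- read_theta_matrix(paths[["theta"]])
  md <- read_sample_metadata(paths[["metadata"]])
  mm <- read_multimap_report(paths[["multimap"]])
  cand <- read_candidate_list(paths[["candidates_carotenoid"]])
  expect_identical(dim(theta), dim(attr(paths, "panel")$theta))
  expect_identical(md$line_name, attr(paths, "panel")$metadata$line_name)
  expect_identical(nrow(cand), 10L)

  # planted multi-mapped SNPs are exactly the qc removals
  bounds <- estimate_boundaries(theta, md, "tetraploid")
  g <- call_genotypes(theta, bounds)
  fm <- filter_multimapped(g, mm)
  expect_setequal(fm$removed$snp_id, attr(paths, "panel")$truth$multimapped)
})

test_that("planted high-missingness SNPs are exactly the missing-filter removals", {
  spec <- simulation_spec(n_snps = 120, missing_rate = 0, seed = 22)
  sim <- simulate_panel(spec)
  # plant 30% missingness into a known subset
  set.seed(22)
  planted <- sample(rownames(sim$theta), 15)
  for (s in planted) {
    sim$theta[s, sample(ncol(sim$theta), ceiling(0.3 * ncol(sim$theta)))] <- NA
  }
  bounds <- estimate_boundaries(sim$theta, sim$metadata, "tetraploid")
  g <- call_genotypes(sim$theta, bounds)
  fm <- filter_missing(g, 0.2)
  expect_setequal(fm$removed$snp_id, planted)
})

test_that("pipeline recovers per-line true heterozygosity within 2 points", {
  p <- get_default_panel()
  tet <- p$sim$metadata$line_name[p$sim$metadata$ploidy == 4L]
  prof <- percent_heterozygosity(p$calls[, tet])
  truth <- 100 * p$sim$truth$het_true[tet]
  expect_lt(max(abs(prof$pct_heterozygous - truth)), 2)
})

test_that("enrichment ranks planted selected loci above null decoys", {
  p <- get_default_panel()
  cand <- rbind(p$sim$candidates$carotenoid, p$sim$candidates$carbohydrate)
  md <- p$sim$metadata
  auc_for <- function(panel, design_name) {
    design <- builtin_designs(carotenoid = panel$snp_id,
                              carbohydrate = panel$snp_id)[[design_name]]
    out <- run_panel(p$calls, design, md)
    res <- merge(out$results, panel, by = "snp_id")
    pos <- res$allele_p[res$planted_selected]
    neg <- res$allele_p[!res$planted_selected]
    mean(outer(pos, neg, "<") + 0.5 * outer(pos, neg, "=="))
  }
  expect_gt(auc_for(p$sim$candidates$carotenoid, "carotenoid_yellow"), 0.9)
  expect_gt(auc_for(p$sim$candidates$carbohydrate, "carbohydrate_chip"), 0.9)
})
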