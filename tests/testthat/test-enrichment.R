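# Small two-class panel: `nf` focal lines with calls `fc`, `nr` reference
# lines with calls `rc` (character vectors recycled across lines).
two_group_panel <- function(fc, rc, focal_class = "Yellow",
                            ref_class = "Pigmented", model = "tetraploid") {
  nf <- length(fc); nr <- length(rc)
  lines <- c(sprintf("F%02d", seq_len(nf)), sprintf("R%02d", seq_len(nr)))
  calls <- matrix(c(fc, rc), 1, dimnames = list("s1", lines))
  list(g = genotype_matrix(calls, model),
       md = make_metadata(lines, market_class = rep(c(focal_class, ref_class),
                                                    c(nf, nr))),
       design = comparison_design("test", focal_class, ref_class, model))
}

test_that("allele test reproduces hand-computed chi-square values", {
  # identical focal and reference frequencies -> chi2 = 0, p = 1
  pn <- two_group_panel(rep(c("AAAA", "BBBB"), 5), rep(c("AAAA", "BBBB"), 10))
  r0 <- allele_freq_test(pn$g, pn$design, "s1", pn$md)
  expect_equal(r0$allele_chi2, 0)
  expect_equal(r0$allele_p, 1)

  # 10 focal all BBBB (40 B copies) vs reference at pB = 0.5:
  # (40-20)^2/20 + (0-20)^2/20 = 40
  pn <- two_group_panel(rep("BBBB", 10), rep(c("AAAA", "BBBB"), 10))
  r <- allele_freq_test(pn$g, pn$design, "s1", pn$md)
  expect_equal(r$allele_chi2, 40)
  expect_identical(r$allele_df, 1L)
  expect_lt(r$allele_p, 1e-9)

  # fixed reference -> not testable, no exception
  pn <- two_group_panel(rep("AABB", 10), rep("AAAA", 10))
  expect_false(allele_freq_test(pn$g, pn$design, "s1", pn$md)$allele_testable)

  # fewer than two scored focal lines -> not testable
  pn <- two_group_panel("AABB", rep(c("AAAA", "BBBB"), 5))
  expect_false(allele_freq_test(pn$g, pn$design, "s1", pn$md)$allele_testable)
})

test_that("genotype test df tracks the classes present, capped at the model", {
  # two categories: focal 10 all AABB vs reference half AABB half AAAA:
  # (10-5)^2/5 + (0-5)^2/5 = 10 on 1 df
  pn <- two_group_panel(rep("AABB", 10), rep(c("AABB", "AAAA"), 5))
  r <- genotype_freq_test(pn$g, pn$design, "s1", pn$md)
  expect_equal(r$genotype_chi2, 10)
  expect_identical(r$genotype_df, 1L)

  # category in focal but absent from reference -> not testable
  pn <- two_group_panel(rep(c("AABB", "ABBB"), 5), rep(c("AABB", "AAAA"), 5))
  expect_false(genotype_freq_test(pn$g, pn$design, "s1", pn$md)$genotype_testable)

  # single shared category -> df 0 -> not testable
  pn <- two_group_panel(rep("AABB", 6), rep("AABB", 6))
  expect_false(genotype_freq_test(pn$g, pn$design, "s1", pn$md)$genotype_testable)

  # identical distributions give chi2 = 0 and matches chisq.test's statistic
  pn <- two_group_panel(rep(c("AAAA", "AABB", "BBBB"), 8),
                        rep(c("AAAA", "AABB", "BBBB"), 16))
  r <- genotype_freq_test(pn$g, pn$design, "s1", pn$md)
  expect_equal(r$genotype_chi2, 0)
  expect_identical(r$genotype_df, 2L)
})

test_that("genotype statistic equals the stats::chisq.test GOF construction", {
  set.seed(91)
  classes <- genotype_classes("tetraploid")
  fc <- sample(classes, 60, TRUE, prob = c(.1, .2, .4, .2, .1))
  rc <- sample(classes, 200, TRUE, prob = c(.15, .2, .3, .2, .15))
  pn <- two_group_panel(fc, rc)
  r <- genotype_freq_test(pn$g, pn$design, "s1", pn$md)
  ref_prop <- table(factor(rc, classes)) / length(rc)
  oracle <- suppressWarnings(
    stats::chisq.test(table(factor(fc, classes)), p = ref_prop))
  expect_equal(r$genotype_chi2, unname(oracle$statistic))
})

test_that("chi-square statistics are invariant under allele relabeling", {
  set.seed(92)
  classes <- genotype_classes("tetraploid")
  fc <- sample(classes, 40, TRUE)
  rc <- sample(classes, 80, TRUE, prob = c(.3, .2, .2, .2, .1))
  pn <- two_group_panel(fc, rc)
  swap <- setNames(rev(classes), classes)
  pn2 <- two_group_panel(unname(swap[fc]), unname(swap[rc]))
  a1 <- allele_freq_test(pn$g, pn$design, "s1", pn$md)
  a2 <- allele_freq_test(pn2$g, pn2$design, "s1", pn2$md)
  expect_equal(a1$allele_chi2, a2$allele_chi2)
  g1 <- genotype_freq_test(pn$g, pn$design, "s1", pn$md)
  g2 <- genotype_freq_test(pn2$g, pn2$design, "s1", pn2$md)
  expect_equal(g1$genotype_chi2, g2$genotype_chi2)
})

test_that("power rises with frequency shift and focal sample size", {
  set.seed(93)
  classes <- genotype_classes("tetraploid")
  power_at <- function(shift, nf, nsnp = 250, nr = 400) {
    hits <- 0; tested <- 0
    lines <- c(sprintf("F%03d", 1:nf), sprintf("R%03d", 1:nr))
    md <- make_metadata(lines, market_class = rep(c("Yellow", "Pigmented"),
                                                  c(nf, nr)))
    design <- comparison_design("pw", "Yellow", "Pigmented", "tetraploid")
    for (i in seq_len(nsnp)) {
      p0 <- 0.4
      calls <- classes[c(rbinom(nf, 4, p0 + shift), rbinom(nr, 4, p0)) + 1]
      g <- genotype_matrix(matrix(calls, 1, dimnames = list("s", lines)),
                           "tetraploid")
      r <- allele_freq_test(g, design, "s", md)
      if (r$allele_testable) {
        tested <- tested + 1
        hits <- hits + (r$allele_p < 0.05)
      }
    }
    hits / tested
  }
  pw <- c(power_at(0.05, 20), power_at(0.15, 20), power_at(0.30, 20),
          power_at(0.15, 60))
  expect_true(all(diff(pw[1:3]) > 0))   # monotone in shift
  expect_gt(pw[4], pw[2])               # monotone in focal sample size
})

test_that("panel summaries count significant fractions over testable SNPs", {
  p <- get_default_panel()
  cand <- p$sim$candidates$carbohydrate
  design <- builtin_designs(carbohydrate = cand$snp_id)$carbohydrate_chip
  out <- run_panel(p$calls, design, p$sim$metadata)
  expect_identical(nrow(out$results), nrow(cand))
  planted <- cand$snp_id[cand$planted_selected]
  res <- out$results
  # planted selected SNPs dominate the significant fraction
  expect_true(all(res$allele_p[res$snp_id %in% planted] < 0.05))
  expect_gte(out$summary$allele_significant_fraction,
             length(planted) / nrow(cand))

  # a SNP with no genotype data is reported not testable, off the denominator
  g2 <- unclass(p$calls)
  g2[cand$snp_id[1], ] <- NA
  out2 <- run_panel(genotype_matrix(g2, "tetraploid"), design, p$sim$metadata)
  r1 <- out2$results[out2$results$snp_id == cand$snp_id[1], ]
  expect_false(r1$allele_testable)
  expect_identical(out2$summary$n_allele_testable,
                   sum(out2$results$allele_testable))
})

test_that("random baselines draw reproducibly under a fixed seed", {
  p <- get_default_panel()
  cand <- p$sim$candidates$glycoalkaloid        # planted with no selection
  design <- builtin_designs(glycoalkaloid = cand$snp_id)$glycoalkaloid_cultivated
  gdip <- collapse_to_diploid(p$calls)
  b1 <- random_snp_baseline(gdip, design, p$sim$metadata, n_random = 150, seed = 7)
  b2 <- random_snp_baseline(gdip, design, p$sim$metadata, n_random = 150, seed = 7)
  expect_identical(b1$results$snp_id, b2$results$snp_id)
  expect_identical(b1$summary, b2$summary)
  expect_error(random_snp_baseline(gdip, design, p$sim$metadata, n_random = 0),
               "n_random")
})

test_that("built-in designs encode the market-class comparisons", {
  d <- builtin_designs()
  expect_identical(d$glycoalkaloid_cultivated$model, "diploid")
  expect_identical(d$glycoalkaloid_cultivated$focal, "cultivated")
  expect_identical(d$carotenoid_yellow$focal, "Yellow")
  expect_setequal(d$carotenoid_yellow$reference,
                  c("ChipProcessing", "FrenchFryProcessing", "Pigmented",
                    "RoundWhiteTable", "TableRusset"))
  # the French fry reference excludes the other processing class
  expect_false("ChipProcessing" %in% d$carbohydrate_frenchfry$reference)
  expect_setequal(d$carbohydrate_chip$reference,
                  c("FrenchFryProcessing", "Pigmented", "RoundWhiteTable",
                    "TableRusset", "Yellow"))
})
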