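test_that("boundaries recover well-separated synthetic clusters", {
  centers <- default_theta_centers("tetraploid")
  set.seed(31)
  # 60 samples spread over all five dosage clusters, tight noise
  dos <- rep(0:4, each = 12)
  theta <- matrix(pmin(pmax(rnorm(60, centers[dos + 1], 0.02), 0), 1), 1,
                  dimnames = list("snp1", sprintf("L%02d", 1:60)))
  b <- estimate_boundaries(theta, model = "tetraploid")
  expect_identical(b$flag, "ok")
  expect_length(b$boundaries[[1]], 4L)
  expect_identical(b$defined_classes[[1]], genotype_classes("tetraploid"))
  # each boundary lies between the adjacent true centers
  expect_true(all(b$boundaries[[1]] > centers[-5] & b$boundaries[[1]] < centers[-1]))
})

test_that("absent dosage classes get no interval and no calls", {
  centers <- default_theta_centers("tetraploid")
  set.seed(32)
  dos <- rep(c(0L, 1L, 2L, 4L), each = 15)  # no ABBB anywhere
  theta <- matrix(pmin(pmax(rnorm(60, centers[dos + 1], 0.02), 0), 1), 1,
                  dimnames = list("snp1", sprintf("L%02d", 1:60)))
  b <- estimate_boundaries(theta, model = "tetraploid")
  expect_lte(length(b$boundaries[[1]]), 3L)
  expect_false("ABBB" %in% b$defined_classes[[1]])
  g <- call_genotypes(theta, b)
  expect_false("ABBB" %in% g)
})

test_that("monomorphic and all-missing SNPs degrade as specified", {
  set.seed(33)
  theta <- rbind(
    mono = pmin(pmax(rnorm(40, 0.05, 0.02), 0), 1),
    gone = rep(NA_real_, 40))
  colnames(theta) <- sprintf("L%02d", 1:40)
  b <- estimate_boundaries(theta, model = "tetraploid")
  expect_length(b$boundaries[[1]], 0L)
  expect_length(b$defined_classes[[1]], 1L)
  expect_identical(b$flag[2], "all_missing")
  g <- call_genotypes(theta, b)
  expect_true(all(is.na(g["gone", ])))
  expect_true(all(g["mono", ] == b$defined_classes[[1]][1]))
})

test_that("interval convention is left-closed right-open with exact boundary ties", {
  bt <- data.frame(snp_id = "s", model = "diploid", flag = "ok",
                   stringsAsFactors = FALSE)
  bt$boundaries <- list(c(0.25, 0.75))
  bt$defined_classes <- list(c("AA", "AB", "BB"))
  theta <- matrix(c(0.10, 0.50, 0.90, 0.25, 0.75, 1.0), 1,
                  dimnames = list("s", paste0("L", 1:6)))
  g <- call_genotypes(theta, bt)
  expect_identical(as.vector(g), c("AA", "AB", "BB", "AB", "BB", "BB"))
})

test_that("calling is monotone in theta", {
  p <- get_default_panel()
  set.seed(34)
  for (r in sample(nrow(p$sim$theta), 25)) {
    x <- p$sim$theta[r, ]
    d <- dosage_of(p$calls[r, ])
    ok <- !is.na(x) & !is.na(d)
    ord <- order(x[ok])
    expect_true(all(diff(d[ok][ord]) >= 0), label = rownames(p$sim$theta)[r])
  }
})

test_that("F1 segregation evidence overrides prior-center proximity", {
  # Two clusters at 0.30 and 0.52 sit nearest the AAAB/AABB prior centers,
  # but a 1:1 F1 split with one parent per cluster fits AAAA x AAAB
  # (expected 1/2:1/2) better than AAAB x AABB (5/12:5/12 with mass lost
  # to unseen classes); anchoring must relabel the clusters.
  set.seed(40)
  n_prog <- 150
  d <- rbinom(n_prog, 1, 0.5)
  lows <- c(0.30, 0.52)
  theta <- matrix(c(rnorm(1, lows[1], 0.015), rnorm(1, lows[2], 0.015),
                    rnorm(n_prog, lows[d + 1], 0.015)), 1)
  dimnames(theta) <- list("s1", c("F_P1", "F_P2", sprintf("F_F1_%03d", 1:n_prog)))
  md <- make_metadata(colnames(theta), group = "genetic_stock",
                      family_role = c("parent1", "parent2",
                                      rep("f1_progeny", n_prog)),
                      family_id = "F")
  unanchored <- estimate_boundaries(theta, model = "tetraploid")
  expect_identical(unanchored$defined_classes[[1]], c("AAAB", "AABB"))
  anchored <- estimate_boundaries(theta, md, "tetraploid")
  expect_identical(anchored$defined_classes[[1]], c("AAAA", "AAAB"))
})

test_that("F1 anchoring labels clusters by segregation when classes are absent", {
  # AABB x AABB family: progeny span all five dosages; panel alone shows
  # only three clusters at one locus of a second SNP where parents are
  # AAAA x AABB (dosages 0..2), so labeling must come from segregation.
  fam <- simulate_f1_family(parent1_dosage = c(2L, 0L),
                            parent2_dosage = c(2L, 2L),
                            n_progeny = 150, model = "tetraploid",
                            noise_sd = 0.02, seed = 35)
  b <- estimate_boundaries(fam$theta, fam$metadata, "tetraploid")
  expect_identical(b$defined_classes[[1]], genotype_classes("tetraploid"))
  # second SNP: offspring dosages 0..2 only -> classes AAAA, AAAB, AABB
  expect_identical(b$defined_classes[[2]], c("AAAA", "AAAB", "AABB"))
  g <- call_genotypes(fam$theta, b)
  acc <- mean(dosage_of(g) == fam$truth$dosage, na.rm = TRUE)
  expect_gt(acc, 0.98)
})

test_that("called F1 families segregate as expected (chi-square GOF)", {
  set.seed(36)
  crosses <- list(c(1L, 1L), c(2L, 2L), c(1L, 2L), c(3L, 2L), c(2L, 0L))
  n_fam <- 0; n_ok <- 0
  for (rep in 1:4) {
    for (cr in crosses) {
      fam <- simulate_f1_family(cr[1], cr[2], n_progeny = 220,
                                model = "tetraploid", noise_sd = 0.02,
                                seed = 1000 + rep * 10 + cr[1] * 5 + cr[2])
      b <- estimate_boundaries(fam$theta, fam$metadata, "tetraploid")
      g <- call_genotypes(fam$theta, b)
      prog <- g[1, -(1:2)]
      classes <- genotype_classes("tetraploid")
      exp_dist <- expected_f1_segregation(classes[cr[1] + 1], classes[cr[2] + 1],
                                          "tetraploid")$offspring_distribution
      keep <- exp_dist > 0
      obs <- table(factor(prog, levels = classes))[keep]
      suppressWarnings(
        pval <- stats::chisq.test(obs, p = exp_dist[keep])$p.value)
      n_fam <- n_fam + 1
      if (pval > 0.01) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_fam, 0.95)
})

test_that("replicate concordance counts contradicting joint calls", {
  calls <- matrix("AABB", 1000, 2,
                  dimnames = list(sprintf("s%04d", 1:1000), c("R1", "R2")))
  g1 <- genotype_matrix(calls, "tetraploid")
  expect_equal(replicate_concordance(g1, g1)$mean, 0)

  calls2 <- calls
  calls2[c(10, 500), 2] <- "ABBB"           # two planted contradictions
  calls2[3, 2] <- NA                        # missing cells leave denominator
  g2 <- genotype_matrix(calls2, "tetraploid")
  rc <- replicate_concordance(g1, g2, pairs = data.frame(a = "R2", b = "R2"))
  expect_equal(rc$per_pair$n_joint, 999L)
  expect_equal(rc$mean, 2 / 999)

  empty <- genotype_matrix(matrix(NA_character_, 1000, 2,
                                  dimnames = dimnames(calls)), "tetraploid")
  rc0 <- replicate_concordance(g1, empty, pairs = data.frame(a = "R1", b = "R1"))
  expect_true(is.na(rc0$per_pair$discordance))
})

test_that("dosage model is more discordant than the collapsed diploid model", {
  p <- get_default_panel()
  sub <- p$sim$truth$dosage[1:600, p$sim$metadata$ploidy == 4L][, 1:40]
  reps <- lapply(c(91, 92), function(s) {
    th <- theta_from_dosage(sub, ploidy = 4L, noise_sd = 0.04, seed = s)
    call_genotypes(th, p$bounds[match(rownames(sub), p$bounds$snp_id), ])
  })
  tet <- replicate_concordance(reps[[1]], reps[[2]])
  dip <- replicate_concordance(collapse_to_diploid(reps[[1]]),
                               collapse_to_diploid(reps[[2]]))
  expect_lt(dip$mean, tet$mean)
  expect_lt(tet$mean, 0.054)  # dosage-model upper envelope
})
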