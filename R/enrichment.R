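#' Define a focal-vs-reference enrichment comparison
#'
#' An enrichment comparison tests whether candidate-gene SNPs show allele
#' or genotype frequencies in a focal set of lines (observed) that differ
#' from those expected under the frequencies of a reference set.
#'
#' @param name Label for the comparison.
#' @param focal,reference Character vectors of market classes (when
#'   `by = "market_class"`) or germplasm groups (`by = "group"`); must be
#'   disjoint.
#' @param model Calling model whose allele dosages feed the test.
#' @param candidate_snps SNP ids of the candidate-gene panel.
#' @param alpha Significance level for panel summaries.
#' @param by Whether focal/reference select on market class (cultivated
#'   tetraploid lines) or on germplasm group.
#' @return A list with class `comparison_design`.
#' @export
comparison_design <- function(name, focal, reference, model,
                              candidate_snps = character(0), alpha = 0.05,
                              by = c("market_class", "group")) {
  by <- match.arg(by)
  if (length(intersect(focal, reference))) {
    stop("focal and reference sets must be disjoint")
  }
  structure(list(name = name, focal = focal, reference = reference,
                 model = match_model(model),
                 candidate_snps = candidate_snps, alpha = alpha, by = by),
            class = "comparison_design")
}

# Resolve the focal and reference line names for a design. Market-class
# designs operate on cultivated tetraploid lines, matching the use of the
# dosage model within cultivated potato.
design_lines <- function(design, metadata) {
  if (design$by == "market_class") {
    pool <- metadata[metadata$group == "cultivated" & metadata$ploidy == 4L, ]
    list(focal = pool$line_name[pool$market_class %in% design$focal],
         reference = pool$line_name[pool$market_class %in% design$reference])
  } else {
    list(focal = metadata$line_name[metadata$group %in% design$focal],
         reference = metadata$line_name[metadata$group %in% design$reference])
  }
}

chi_gof <- function(observed, expected) {
  keep <- expected > 0
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  stat
}

#' Allele-frequency enrichment test at one SNP
#'
#' Observed counts are the focal lines' allele copies (each line
#' contributes `ploidy` copies, i.e. its within-individual allele
#' frequency times ploidy); expected counts are the focal total scaled by
#' the reference allele proportions. The chi-square statistic uses one
#' degree of freedom. The test is not testable when fewer than two focal
#' or reference lines are scored, or when the reference is fixed
#' (reference B proportion 0 or 1).
#'
#' @param g A `genotype_matrix` under the design's model.
#' @param design A [comparison_design()].
#' @param snp SNP id (row of `g`).
#' @param metadata Sample metadata.
#' @return One-row data frame: snp_id, n_focal, n_reference, allele_chi2,
#'   allele_df, allele_p, allele_testable.
#' @export
allele_freq_test <- function(g, design, snp, metadata) {
  sel <- design_lines(design, metadata)
  ploidy <- model_ploidy(gt_model(g))
  dos <- dosage_of(g[snp, , drop = TRUE])
  df_out <- data.frame(snp_id = snp, n_focal = NA_integer_,
                       n_reference = NA_integer_, allele_chi2 = NA_real_,
                       allele_df = 1L, allele_p = NA_real_,
                       allele_testable = FALSE, stringsAsFactors = FALSE)
  fd <- dos[intersect(sel$focal, names(dos))]
  rd <- dos[intersect(sel$reference, names(dos))]
  fd <- fd[!is.na(fd)]; rd <- rd[!is.na(rd)]
  df_out$n_focal <- length(fd); df_out$n_reference <- length(rd)
  if (length(fd) < 2L || length(rd) < 2L) return(df_out)
  p_ref <- sum(rd) / (ploidy * length(rd))
  if (p_ref <= 0 || p_ref >= 1) return(df_out)
  total <- ploidy * length(fd)
  obs <- c(B = sum(fd), A = total - sum(fd))
  exp <- c(B = total * p_ref, A = total * (1 - p_ref))
  stat <- chi_gof(obs, exp)
  df_out$allele_chi2 <- stat
  df_out$allele_p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  df_out$allele_testable <- TRUE
  df_out
}

#' Genotype-frequency enrichment test at one SNP
#'
#' Categories are the genotype classes present (non-zero count) in the
#' pooled focal and reference lines; expected counts are the focal line
#' total scaled by the reference class proportions. Degrees of freedom
#' are the category count minus one, capped at the model maximum (four
#' tetraploid, two diploid). A category observed in the focal set but
#' absent from the reference makes the test not testable under this
#' construction, as does a single shared category.
#'
#' @inheritParams allele_freq_test
#' @return One-row data frame: snp_id, n_focal, n_reference,
#'   genotype_chi2, genotype_df, genotype_p, genotype_testable.
#' @export
genotype_freq_test <- function(g, design, snp, metadata) {
  sel <- design_lines(design, metadata)
  classes <- genotype_classes(gt_model(g))
  calls <- g[snp, , drop = TRUE]
  df_out <- data.frame(snp_id = snp, n_focal = NA_integer_,
                       n_reference = NA_integer_, genotype_chi2 = NA_real_,
                       genotype_df = NA_integer_, genotype_p = NA_real_,
                       genotype_testable = FALSE, stringsAsFactors = FALSE)
  fc <- calls[intersect(sel$focal, names(calls))]
  rc <- calls[intersect(sel$reference, names(calls))]
  fc <- fc[!is.na(fc)]; rc <- rc[!is.na(rc)]
  df_out$n_focal <- length(fc); df_out$n_reference <- length(rc)
  if (length(fc) < 2L || length(rc) < 2L) return(df_out)
  obs_f <- table(factor(fc, levels = classes))
  obs_r <- table(factor(rc, levels = classes))
  cats <- classes[obs_f + obs_r > 0L]
  if (length(cats) < 2L) return(df_out)
  if (any(obs_r[cats] == 0L & obs_f[cats] > 0L)) return(df_out)
  props <- as.numeric(obs_r[cats]) / length(rc)
  expd <- length(fc) * props
  stat <- chi_gof(as.numeric(obs_f[cats]), expd)
  df <- min(length(cats) - 1L, length(classes) - 1L)
  df_out$genotype_chi2 <- stat
  df_out$genotype_df <- df
  df_out$genotype_p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  df_out$genotype_testable <- TRUE
  df_out
}

#' Run a candidate-gene enrichment panel
#'
#' Applies the allele- and genotype-frequency tests to every candidate
#' SNP of a design and summarizes the fraction significant at the
#' design's alpha. Not-testable SNPs are excluded from the denominators.
#'
#' @param g A `genotype_matrix` under the design's model.
#' @param design A [comparison_design()] with a non-empty candidate list.
#' @param metadata Sample metadata.
#' @param snps Optional SNP ids overriding the design's candidate list.
#' @return List with `results` (per-SNP data frame) and `summary` (design
#'   name, alpha, tested counts, significant fractions for both tests).
#' @export
run_panel <- function(g, design, metadata, snps = NULL) {
  if (is.null(snps)) snps <- design$candidate_snps
  if (length(snps) == 0L) stop("candidate SNP list is empty")
  snps <- intersect(snps, rownames(g))
  res <- lapply(snps, function(s) {
    a <- allele_freq_test(g, design, s, metadata)
    b <- genotype_freq_test(g, design, s, metadata)
    cbind(a, b[, c("genotype_chi2", "genotype_df", "genotype_p",
                   "genotype_testable")])
  })
  res <- do.call(rbind, res)
  alpha <- design$alpha
  a_ok <- res$allele_testable
  g_ok <- res$genotype_testable
  summary <- data.frame(
    design = design$name, alpha = alpha,
    n_candidates = length(snps),
    n_allele_testable = sum(a_ok),
    n_genotype_testable = sum(g_ok),
    allele_significant_fraction =
      if (any(a_ok)) mean(res$allele_p[a_ok] < alpha) else NA_real_,
    genotype_significant_fraction =
      if (any(g_ok)) mean(res$genotype_p[g_ok] < alpha) else NA_real_,
    stringsAsFactors = FALSE
  )
  list(results = res, summary = summary)
}

#' Random-SNP baseline for an enrichment panel
#'
#' Draws `n_random` SNPs uniformly without replacement from the retained
#' non-candidate SNPs and applies the same tests, to check whether the
#' candidate panel's significant fraction exceeds genome background.
#'
#' @inheritParams run_panel
#' @param n_random Number of baseline SNPs; defaults to the candidate
#'   panel size.
#' @param seed Integer seed for the draw.
#' @return As [run_panel()], on the random SNP set (ids in
#'   `summary$design` suffixed `_random_baseline`).
#' @export
random_snp_baseline <- function(g, design, metadata,
                                n_random = length(design$candidate_snps),
                                seed = 1L) {
  if (n_random < 1L) stop("n_random must be >= 1")
  pool <- setdiff(rownames(g), design$candidate_snps)
  if (n_random > length(pool)) stop("n_random exceeds available non-candidate SNPs")
  set.seed(seed)
  snps <- sample(pool, n_random)
  out <- run_panel(g, design, metadata, snps = snps)
  out$summary$design <- paste0(design$name, "_random_baseline")
  out
}

#' The built-in market-class comparison designs
#'
#' The three candidate-gene comparisons: carotenoid-pathway SNPs in
#' Yellow lines against all other cultivated market classes (tetraploid
#' dosage model); carbohydrate-gene SNPs in Chip Processing lines against
#' all other cultivated classes and in French Fry Processing lines
#' against the cultivated non-processing classes (tetraploid); and
#' glycoalkaloid-pathway SNPs in all cultivated lines against the wild
#' species (diploid model).
#'
#' @param carotenoid,carbohydrate,glycoalkaloid Candidate SNP id vectors
#'   for the three panels.
#' @param alpha Significance level shared by the designs.
#' @return Named list of four `comparison_design` objects.
#' @export
builtin_designs <- function(carotenoid = character(0),
                            carbohydrate = character(0),
                            glycoalkaloid = character(0),
                            alpha = 0.05) {
  list(
    carotenoid_yellow = comparison_design(
      "carotenoid_yellow",
      focal = "Yellow",
      reference = c("ChipProcessing", "FrenchFryProcessing", "Pigmented",
                    "RoundWhiteTable", "TableRusset"),
      model = "tetraploid", candidate_snps = carotenoid, alpha = alpha),
    carbohydrate_chip = comparison_design(
      "carbohydrate_chip",
      focal = "ChipProcessing",
      reference = c("FrenchFryProcessing", "Pigmented", "RoundWhiteTable",
                    "TableRusset", "Yellow"),
      model = "tetraploid", candidate_snps = carbohydrate, alpha = alpha),
    carbohydrate_frenchfry = comparison_design(
      "carbohydrate_frenchfry",
      focal = "FrenchFryProcessing",
      reference = c("Pigmented", "RoundWhiteTable", "TableRusset", "Yellow"),
      model = "tetraploid", candidate_snps = carbohydrate, alpha = alpha),
    glycoalkaloid_cultivated = comparison_design(
      "glycoalkaloid_cultivated",
      focal = "cultivated", reference = "wild",
      model = "diploid", candidate_snps = glycoalkaloid, alpha = alpha,
      by = "group")
  )
}
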