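#' Specification for a synthetic diversity panel
#'
#' Defines the statistical structure of a simulated SNP-array panel:
#' subpopulation sizes mirroring a diverse potato panel (cultivated
#' market classes, genetic stocks, wild species), subpopulation baseline
#' B-allele frequency distributions, market-class-selected loci with
#' shifted frequencies, theta cluster centers per dosage with Gaussian
#' noise, and injected missingness. Defaults give a desk-scale panel of
#' 2,000 SNPs x 100 lines whose market-class sizes are proportional to a
#' 250-line diversity panel (69/34/32/38/13/27 cultivated lines per class
#' plus 25 genetic stocks and 12 wild accessions).
#'
#' Cultivated classes share a common baseline frequency (uniform on
#' [0.05, 0.95]) perturbed per class by Gaussian divergence
#' (`class_divergence_sd`), wild accessions draw from Beta(0.2, 0.2)
#' (skewed toward fixation, reflecting array ascertainment in cultivated
#' germplasm), genetic stocks from Beta(0.4, 0.4). Three candidate-gene
#' panels are planted: carotenoid SNPs selected in Yellow lines,
#' carbohydrate SNPs selected in Chip Processing lines, and a
#' glycoalkaloid panel with no selected loci (a null panel).
#'
#' @param n_snps Number of SNPs.
#' @param class_sizes Named integer vector of cultivated tetraploid line
#'   counts per market class.
#' @param n_genetic_stock,n_wild Counts of genetic stock (tetraploid) and
#'   wild (diploid) lines.
#' @param cultivated_freq_range Baseline uniform range for cultivated
#'   B frequencies.
#' @param class_divergence_sd SD of the per-class frequency perturbation.
#' @param stock_beta,wild_beta Beta shape parameters for the genetic
#'   stock and wild frequency distributions.
#' @param candidate_panels List of panels; each has `n` candidates,
#'   `n_selected` selected among them, `focal` market class and `shift`
#'   (absolute frequency displacement in the focal class).
#' @param theta_centers_diploid,theta_centers_tetraploid Cluster centers.
#' @param noise_sd Theta noise SD around each cluster center.
#' @param missing_rate Bernoulli missingness rate on theta values.
#' @param multimap_rate Fraction of SNPs planted with >= 2 genome hits.
#' @param seed Integer seed.
#' @return A list with class `simulation_spec`.
#' @export
simulation_spec <- function(n_snps = 2000L,
                            class_sizes = c(ChipProcessing = 28L,
                                            FrenchFryProcessing = 14L,
                                            Pigmented = 13L,
                                            RoundWhiteTable = 15L,
                                            TableRusset = 5L,
                                            Yellow = 11L),
                            n_genetic_stock = 10L,
                            n_wild = 4L,
                            cultivated_freq_range = c(0.05, 0.95),
                            class_divergence_sd = 0.10,
                            stock_beta = c(0.4, 0.4),
                            wild_beta = c(0.2, 0.2),
                            candidate_panels = list(
                              carotenoid = list(n = 10L, n_selected = 5L,
                                                focal = "Yellow", shift = 0.4),
                              carbohydrate = list(n = 12L, n_selected = 6L,
                                                  focal = "ChipProcessing",
                                                  shift = 0.4),
                              glycoalkaloid = list(n = 10L, n_selected = 0L,
                                                   focal = NULL, shift = 0)),
                            theta_centers_diploid = default_theta_centers("diploid"),
                            theta_centers_tetraploid = default_theta_centers("tetraploid"),
                            noise_sd = 0.03,
                            missing_rate = 0.02,
                            multimap_rate = 0.05,
                            seed = 1L) {
  stopifnot(n_snps >= 1L, all(class_sizes >= 0L), n_genetic_stock >= 0L,
            n_wild >= 0L, noise_sd > 0, missing_rate >= 0, missing_rate < 1,
            multimap_rate >= 0, multimap_rate < 1)
  bad <- setdiff(names(class_sizes), setdiff(VALID_MARKET_CLASSES, "none"))
  if (length(bad)) stop("unknown market class in class_sizes: ",
                        paste(bad, collapse = ", "))
  structure(list(
    n_snps = as.integer(n_snps), class_sizes = class_sizes,
    n_genetic_stock = as.integer(n_genetic_stock), n_wild = as.integer(n_wild),
    cultivated_freq_range = cultivated_freq_range,
    class_divergence_sd = class_divergence_sd,
    stock_beta = stock_beta, wild_beta = wild_beta,
    candidate_panels = candidate_panels,
    theta_centers_diploid = theta_centers_diploid,
    theta_centers_tetraploid = theta_centers_tetraploid,
    noise_sd = noise_sd, missing_rate = missing_rate,
    multimap_rate = multimap_rate, seed = as.integer(seed)
  ), class = "simulation_spec")
}

# Normal(mean, sd) truncated to [0, 1] by rejection.
rtnorm01 <- function(mean, sd) {
  x <- stats::rnorm(length(mean), mean, sd)
  bad <- which(x < 0 | x > 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < 0 | x[bad] > 1]
  }
  x
}

#' Simulate a structured diversity panel
#'
#' Draws, per line and SNP, a true B dosage from Binomial(ploidy,
#' subpopulation frequency) — with selected loci using their shifted
#' frequency in the focal market class — then theta from a Normal
#' centered on the dosage-specific cluster center, truncated to [0, 1],
#' with Bernoulli missingness. Fully reproducible under the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `theta` (matrix), `metadata` (data frame),
#'   `multimap_report`, `candidates` (list of candidate data frames per
#'   panel) and `truth` (true dosage matrix, subpopulation frequencies,
#'   selected-locus table, per-line true heterozygosity, multimapped SNP
#'   ids).
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_snps
  snp_ids <- sprintf("SNP%05d", seq_len(n))

  # subpopulation allele frequencies
  base <- stats::runif(n, spec$cultivated_freq_range[1], spec$cultivated_freq_range[2])
  class_names <- names(spec$class_sizes)
  freqs <- sapply(class_names, function(cc) {
    pmin(pmax(base + stats::rnorm(n, 0, spec$class_divergence_sd), 0.01), 0.99)
  })
  freqs <- cbind(freqs,
                 genetic_stock = stats::rbeta(n, spec$stock_beta[1], spec$stock_beta[2]),
                 wild = stats::rbeta(n, spec$wild_beta[1], spec$wild_beta[2]))
  rownames(freqs) <- snp_ids

  # candidate panels and planted selected loci
  pool <- snp_ids
  candidates <- list()
  selected <- data.frame(snp_id = character(0), focal_class = character(0),
                         base_frequency = numeric(0),
                         shifted_frequency = numeric(0),
                         stringsAsFactors = FALSE)
  for (pn in names(spec$candidate_panels)) {
    p <- spec$candidate_panels[[pn]]
    ids <- sample(pool, p$n)
    pool <- setdiff(pool, ids)
    sel_ids <- if (p$n_selected > 0L) ids[seq_len(p$n_selected)] else character(0)
    if (length(sel_ids)) {
      i <- match(sel_ids, snp_ids)
      p0 <- freqs[i, p$focal]
      shifted <- ifelse(p0 < 0.5, pmin(p0 + p$shift, 0.98),
                        pmax(p0 - p$shift, 0.02))
      freqs[i, p$focal] <- shifted
      selected <- rbind(selected, data.frame(
        snp_id = sel_ids, focal_class = p$focal, base_frequency = p0,
        shifted_frequency = shifted, stringsAsFactors = FALSE))
    }
    candidates[[pn]] <- data.frame(
      snp_id = ids, gene_name = paste0(pn, "_gene_", seq_along(ids)),
      pathway = pn, planted_selected = ids %in% sel_ids,
      stringsAsFactors = FALSE)
  }

  # line metadata
  rows <- list()
  for (cc in class_names) {
    k <- spec$class_sizes[[cc]]
    if (k > 0L) rows[[cc]] <- data.frame(
      line_name = sprintf("%s_%02d", cc, seq_len(k)), ploidy = 4L,
      group = "cultivated", market_class = cc,
      release_year = sample(1857:2011, k, replace = TRUE),
      family_role = "panel", family_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (spec$n_genetic_stock > 0L) rows$stock <- data.frame(
    line_name = sprintf("Stock_%02d", seq_len(spec$n_genetic_stock)),
    ploidy = 4L, group = "genetic_stock", market_class = "none",
    release_year = NA_integer_, family_role = "panel",
    family_id = NA_character_, stringsAsFactors = FALSE)
  if (spec$n_wild > 0L) rows$wild <- data.frame(
    line_name = sprintf("Wild_%02d", seq_len(spec$n_wild)),
    ploidy = 2L, group = "wild", market_class = "none",
    release_year = NA_integer_, family_role = "panel",
    family_id = NA_character_, stringsAsFactors = FALSE)
  metadata <- do.call(rbind, c(rows, make.row.names = FALSE))
  subpop_of <- ifelse(metadata$group == "cultivated", metadata$market_class,
                      metadata$group)

  # true dosages and theta
  n_lines <- nrow(metadata)
  dosage <- matrix(NA_integer_, n, n_lines,
                   dimnames = list(snp_ids, metadata$line_name))
  theta <- matrix(NA_real_, n, n_lines,
                  dimnames = list(snp_ids, metadata$line_name))
  for (j in seq_len(n_lines)) {
    ploidy <- metadata$ploidy[j]
    p <- freqs[, subpop_of[j]]
    d <- stats::rbinom(n, ploidy, p)
    centers <- if (ploidy == 4L) spec$theta_centers_tetraploid else spec$theta_centers_diploid
    dosage[, j] <- d
    theta[, j] <- rtnorm01(centers[d + 1L], spec$noise_sd)
  }
  if (spec$missing_rate > 0) {
    theta[stats::runif(length(theta)) < spec$missing_rate] <- NA_real_
  }

  # multi-mapping report with planted repeats
  n_multi <- floor(spec$multimap_rate * n)
  multi_ids <- if (n_multi > 0L) sample(snp_ids, n_multi) else character(0)
  hit <- rep(1L, n)
  hit[match(multi_ids, snp_ids)] <- sample(2:3, n_multi, replace = TRUE)
  multimap_report <- data.frame(snp_id = snp_ids, hit_count = hit,
                                stringsAsFactors = FALSE)

  het_true <- colMeans(dosage > 0L &
                         dosage < matrix(metadata$ploidy, n, n_lines, byrow = TRUE))
  list(theta = theta, metadata = metadata, multimap_report = multimap_report,
       candidates = candidates,
       truth = list(dosage = dosage, freqs = freqs, selected_loci = selected,
                    het_true = het_true, multimapped = multi_ids))
}

#' Regenerate theta values from true dosages
#'
#' Draws a fresh theta matrix around the dosage-specific cluster centers,
#' emulating an independent array replicate of the same DNA (same true
#' genotypes, new intensity noise).
#'
#' @param dosage Integer matrix of true B dosages (SNP x line).
#' @param ploidy Integer vector of line ploidies (recycled over columns).
#' @param centers_tetraploid,centers_diploid Cluster centers per model.
#' @param noise_sd Theta noise SD.
#' @param missing_rate Bernoulli missingness.
#' @param seed Integer seed.
#' @return Theta matrix with the dimnames of `dosage`.
#' @export
theta_from_dosage <- function(dosage, ploidy,
                              centers_tetraploid = default_theta_centers("tetraploid"),
                              centers_diploid = default_theta_centers("diploid"),
                              noise_sd = 0.03, missing_rate = 0, seed = 1L) {
  set.seed(seed)
  ploidy <- rep_len(ploidy, ncol(dosage))
  theta <- matrix(NA_real_, nrow(dosage), ncol(dosage),
                  dimnames = dimnames(dosage))
  for (j in seq_len(ncol(dosage))) {
    centers <- if (ploidy[j] == 4L) centers_tetraploid else centers_diploid
    theta[, j] <- rtnorm01(centers[dosage[, j] + 1L], noise_sd)
  }
  if (missing_rate > 0) {
    theta[stats::runif(length(theta)) < missing_rate] <- NA_real_
  }
  theta
}

#' Simulate an F1 mapping family
#'
#' Progeny dosages are drawn per SNP from the expected F1 segregation
#' distribution given the parental dosages (random chromosomal
#' segregation, no double reduction); theta values for parents and
#' progeny are generated as in [simulate_panel()].
#'
#' @param parent1_dosage,parent2_dosage Integer vectors of parental B
#'   dosages, one entry per SNP (recycled if length 1).
#' @param n_progeny Number of F1 progeny.
#' @param model Calling model (sets ploidy and theta centers).
#' @param noise_sd Theta noise SD.
#' @param centers Theta cluster centers; defaults to the model's.
#' @param missing_rate Bernoulli missingness on theta.
#' @param seed Integer seed.
#' @param family_id Label used in line names and metadata.
#' @return List with `theta` (SNP x (2 + n_progeny) matrix, parents
#'   first), `metadata` rows for the family, and `truth` (dosage matrix).
#' @export
simulate_f1_family <- function(parent1_dosage, parent2_dosage, n_progeny,
                               model = "tetraploid", noise_sd = 0.03,
                               centers = default_theta_centers(model),
                               missing_rate = 0, seed = 1L,
                               family_id = "FAM1") {
  model <- match_model(model)
  ploidy <- model_ploidy(model)
  n <- max(length(parent1_dosage), length(parent2_dosage))
  d1 <- rep_len(as.integer(parent1_dosage), n)
  d2 <- rep_len(as.integer(parent2_dosage), n)
  if (any(d1 < 0 | d1 > ploidy | d2 < 0 | d2 > ploidy)) {
    stop("parental dosages must lie in 0..", ploidy)
  }
  set.seed(seed)
  classes <- genotype_classes(model)
  prog <- matrix(NA_integer_, n, n_progeny)
  for (key in unique(paste(d1, d2))) {
    idx <- which(paste(d1, d2) == key)
    dd <- as.integer(strsplit(key, " ")[[1L]])
    dist <- expected_f1_segregation(classes[dd[1L] + 1L], classes[dd[2L] + 1L],
                                    model)$offspring_distribution
    prog[idx, ] <- sample.int(ploidy + 1L, length(idx) * n_progeny,
                              replace = TRUE, prob = dist) - 1L
  }
  dosage <- cbind(d1, d2, prog)
  snp_ids <- sprintf("SNP%05d", seq_len(n))
  line_names <- c(paste0(family_id, "_P1"), paste0(family_id, "_P2"),
                  sprintf("%s_F1_%03d", family_id, seq_len(n_progeny)))
  dimnames(dosage) <- list(snp_ids, line_names)
  theta <- matrix(rtnorm01(centers[dosage + 1L], noise_sd), n,
                  dimnames = dimnames(dosage))
  if (missing_rate > 0) {
    theta[stats::runif(length(theta)) < missing_rate] <- NA_real_
  }
  # mapping families are breeding material, not panel market classes
  metadata <- data.frame(
    line_name = line_names, ploidy = ploidy, group = "genetic_stock",
    market_class = "none", release_year = NA_integer_,
    family_role = c("parent1", "parent2", rep("f1_progeny", n_progeny)),
    family_id = family_id, stringsAsFactors = FALSE)
  list(theta = theta, metadata = metadata, truth = list(dosage = dosage))
}

#' Write a complete fixture bundle for the pipeline
#'
#' Simulates a panel and writes every input format the pipeline reads:
#' theta matrix, sample metadata, multi-mapping report, one candidate
#' list per panel (planted selected loci plus null decoys), the
#' simulation config, and ground-truth tables (true dosages, per-line
#' true heterozygosity, selected loci).
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Writable output directory (created if absent).
#' @return Named character vector of the written file paths, invisibly;
#'   the simulated objects are attached as attribute `panel`.
#' @export
emit_fixture_bundle <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(spec)
  paths <- c(
    theta = file.path(out_dir, "theta.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    multimap = file.path(out_dir, "multimap_report.tsv"),
    truth_dosage = file.path(out_dir, "truth_dosage.tsv"),
    truth_lines = file.path(out_dir, "truth_lines.tsv"),
    selected_loci = file.path(out_dir, "truth_selected_loci.tsv"),
    config = file.path(out_dir, "simulation_config.txt")
  )
  write_theta_matrix(sim$theta, paths["theta"])
  write_sample_metadata(sim$metadata, paths["metadata"])
  write_tsv(sim$multimap_report, paths["multimap"])
  for (pn in names(sim$candidates)) {
    p <- file.path(out_dir, paste0("candidates_", pn, ".tsv"))
    write_tsv(sim$candidates[[pn]], p)
    paths[paste0("candidates_", pn)] <- p
  }
  write_tsv(data.frame(snp_id = rownames(sim$truth$dosage), sim$truth$dosage,
                       check.names = FALSE), paths["truth_dosage"])
  write_tsv(data.frame(line_name = sim$metadata$line_name,
                       true_heterozygosity = sim$truth$het_true),
            paths["truth_lines"])
  write_tsv(sim$truth$selected_loci, paths["selected_loci"])
  keys <- names(spec)
  writeLines(vapply(keys, function(k) {
    v <- spec[[k]]
    if (is.list(v)) v <- vapply(names(v), function(nm) {
      paste0(nm, ":", paste(unlist(v[[nm]]), collapse = "/"))
    }, character(1))
    if (!is.null(names(v)) && !is.list(spec[[k]])) {
      v <- paste0(names(v), ":", v)
    }
    paste0(k, "=", paste(v, collapse = ","))
  }, character(1)), paths["config"])
  attr(paths, "panel") <- sim
  invisible(paths)
}
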