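#' Genotype class labels for a calling model
#'
#' The diploid model scores each biallelic SNP as one of three classes
#' (AA, AB, BB); the tetraploid (dosage) model scores the count of B
#' alleles over the four homologous chromosomes (AAAA through BBBB).
#' Class order is ascending B dosage throughout the package.
#'
#' @param model `"diploid"` or `"tetraploid"`.
#' @return Character vector of class labels in ascending B-dosage order.
#' @export
#' @examples
#' genotype_classes("tetraploid")
genotype_classes <- function(model) {
  model <- match_model(model)
  switch(model,
    diploid    = c("AA", "AB", "BB"),
    tetraploid = c("AAAA", "AAAB", "AABB", "ABBB", "BBBB")
  )
}

#' Ploidy implied by a calling model
#' @param model `"diploid"` or `"tetraploid"`.
#' @return 2 or 4.
#' @export
model_ploidy <- function(model) {
  switch(match_model(model), diploid = 2L, tetraploid = 4L)
}

match_model <- function(model) {
  match.arg(model, c("diploid", "tetraploid"))
}

#' B-allele dosage of genotype calls
#'
#' @param calls Character vector (or matrix) of class labels; `NA` allowed.
#' @return Integer count of B alleles per call (`NA` preserved). Matrices
#'   keep their dimensions.
#' @export
#' @examples
#' dosage_of(c("AABB", "BBBB", NA))
dosage_of <- function(calls) {
  d <- nchar(gsub("A", "", calls))
  d[is.na(calls)] <- NA_integer_
  if (is.matrix(calls)) dim(d) <- dim(calls)
  storage.mode(d) <- "integer"
  dimnames(d) <- dimnames(calls)
  d
}

#' Class label for a B-allele dosage
#' @param dosage Integer vector in `0:ploidy`; `NA` allowed.
#' @param model Calling model.
#' @return Character class labels.
#' @export
class_of_dosage <- function(dosage, model) {
  classes <- genotype_classes(model)
  bad <- !is.na(dosage) & (dosage < 0 | dosage > length(classes) - 1)
  if (any(bad)) {
    stop("dosage out of range for ", model, " model: ",
         paste(dosage[bad], collapse = ", "))
  }
  classes[dosage + 1L]
}

#' Construct a genotype matrix
#'
#' A genotype matrix is a character matrix (SNPs in rows, lines in columns)
#' of class labels under one calling model, with `NA` for missing calls.
#'
#' @param calls Character matrix with SNP row names and sample column names.
#' @param model Calling model the labels belong to.
#' @return The matrix with class `genotype_matrix` and a `model` attribute.
#' @export
genotype_matrix <- function(calls, model) {
  model <- match_model(model)
  if (!is.matrix(calls)) stop("calls must be a matrix")
  classes <- genotype_classes(model)
  bad <- !is.na(calls) & !(calls %in% classes)
  if (any(bad)) {
    stop("invalid ", model, " class labels: ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must have SNP row names and sample column names")
  }
  structure(calls, class = c("genotype_matrix", class(calls)), model = model)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = TRUE) {
  y <- NextMethod("[")
  if (is.matrix(y)) genotype_matrix(y, attr(x, "model")) else y
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples (%s model), %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "model"), 100 * mean(is.na(x))))
  invisible(x)
}

gt_model <- function(g) {
  m <- attr(g, "model")
  if (is.null(m)) stop("genotype matrix has no model attribute")
  m
}

#' Collapse tetraploid dosage calls to the diploid model
#'
#' Simplex, duplex and triplex classes (AAAB, AABB, ABBB) all collapse to
#' the single heterozygous class AB; the homozygotes map to AA and BB.
#'
#' @param g A tetraploid `genotype_matrix`.
#' @return A diploid `genotype_matrix` on the same SNPs and samples.
#' @export
collapse_to_diploid <- function(g) {
  if (gt_model(g) != "tetraploid") stop("collapse_to_diploid needs tetraploid calls")
  map <- c(AAAA = "AA", AAAB = "AB", AABB = "AB", ABBB = "AB", BBBB = "BB")
  out <- matrix(map[g], nrow = nrow(g), dimnames = dimnames(g))
  genotype_matrix(out, "diploid")
}

#' Run configuration for genotype calling
#'
#' Bundles the tunable parameters of boundary estimation and calling.
#'
#' @param model Calling model; sets the number of mixture components.
#' @param missing_threshold Missing-data fraction above which a SNP is
#'   removed (strict inequality), default 0.20.
#' @param significance_level Alpha used for enrichment summaries.
#' @param seed Integer seed for stochastic steps.
#' @param cluster_center_priors Strictly increasing theta positions used to
#'   initialize the per-SNP mixture; length 3 (diploid) or 5 (tetraploid).
#' @param noise_sd Initial within-cluster standard deviation on theta.
#' @param min_separation Minimum gap between adjacent retained cluster means
#'   before a SNP is flagged low quality; clusters closer than this merge.
#' @param max_spread Maximum within-cluster standard deviation before the
#'   SNP is flagged low quality (loose clustering).
#' @return A list with class `run_config`.
#' @export
run_config <- function(model = "tetraploid",
                       missing_threshold = 0.20,
                       significance_level = 0.05,
                       seed = 1L,
                       cluster_center_priors = NULL,
                       noise_sd = 0.03,
                       min_separation = 0.04,
                       max_spread = 0.10) {
  model <- match_model(model)
  if (is.null(cluster_center_priors)) {
    cluster_center_priors <- default_theta_centers(model)
  }
  k <- length(genotype_classes(model))
  if (length(cluster_center_priors) != k ||
      any(diff(cluster_center_priors) <= 0) ||
      any(cluster_center_priors < 0 | cluster_center_priors > 1)) {
    stop("cluster_center_priors must be ", k,
         " strictly increasing values in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (missing_threshold <= 0 || missing_threshold >= 1) {
    stop("missing_threshold must be in (0, 1)")
  }
  structure(list(
    model = model,
    missing_threshold = missing_threshold,
    significance_level = significance_level,
    seed = as.integer(seed),
    cluster_center_priors = cluster_center_priors,
    noise_sd = noise_sd,
    min_separation = min_separation,
    max_spread = max_spread
  ), class = "run_config")
}

#' Default theta cluster centers per model
#' @param model Calling model.
#' @return Numeric vector of evenly spread centers in [0, 1].
#' @export
default_theta_centers <- function(model) {
  switch(match_model(model),
    diploid    = c(0.10, 0.50, 0.90),
    tetraploid = c(0.05, 0.275, 0.50, 0.725, 0.95)
  )
}
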