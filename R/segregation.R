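#' Gamete dosage distribution for one parent
#'
#' Under random chromosomal segregation an autotetraploid gamete receives
#' an unordered pair of the parent's four homologs, all C(4,2) = 6 pairs
#' equiprobable, so the B count in a gamete is hypergeometric. Double
#' reduction is not modeled. A diploid gamete receives one of the two
#' alleles with equal probability.
#'
#' @param parent_dosage Integer B-allele count of the parent (0..ploidy).
#' @param model Calling model of the parent.
#' @return Named numeric vector of probabilities over gamete B counts
#'   (names `"0"`, `"1"`, ... up to ploidy/2).
#' @export
#' @examples
#' gamete_distribution(2, "tetraploid")  # AABB parent: 1/6, 4/6, 1/6
gamete_distribution <- function(parent_dosage, model) {
  model <- match_model(model)
  ploidy <- model_ploidy(model)
  if (length(parent_dosage) != 1L || is.na(parent_dosage) ||
      parent_dosage < 0 || parent_dosage > ploidy) {
    stop("parent_dosage must be a single integer in 0..", ploidy)
  }
  g <- ploidy / 2L
  k <- 0:g
  # B alleles drawn without replacement from the parent's ploidy alleles
  p <- stats::dhyper(k, m = parent_dosage, n = ploidy - parent_dosage, k = g)
  names(p) <- as.character(k)
  p
}

#' Expected F1 segregation ratios
#'
#' Offspring genotype-class distribution for a biparental cross, as the
#' convolution of the two parental gamete distributions. Tetraploid
#' parents follow random chromosomal segregation without double
#' reduction; diploid parents follow Mendelian segregation.
#'
#' @param parent1_class,parent2_class Genotype class labels of the parents
#'   (e.g. `"AAAB"`), valid for `model`.
#' @param model Calling model.
#' @return A list with class `segregation_expectation`: `parent1_dosage`,
#'   `parent2_dosage`, and `offspring_distribution`, a named probability
#'   vector over all offspring classes of the model (sums to 1).
#' @export
#' @examples
#' expected_f1_segregation("AAAB", "AAAB", "tetraploid")
expected_f1_segregation <- function(parent1_class, parent2_class, model) {
  model <- match_model(model)
  classes <- genotype_classes(model)
  for (p in c(parent1_class, parent2_class)) {
    if (!p %in% classes) {
      stop("'", p, "' is not a valid ", model, " genotype class")
    }
  }
  d1 <- dosage_of(parent1_class)
  d2 <- dosage_of(parent2_class)
  g1 <- gamete_distribution(d1, model)
  g2 <- gamete_distribution(d2, model)
  ploidy <- model_ploidy(model)
  off <- numeric(ploidy + 1L)
  for (i in seq_along(g1)) {
    for (j in seq_along(g2)) {
      k <- (i - 1L) + (j - 1L)
      off[k + 1L] <- off[k + 1L] + g1[i] * g2[j]
    }
  }
  names(off) <- classes
  stopifnot(abs(sum(off) - 1) < 1e-12)
  structure(list(
    parent1_dosage = d1,
    parent2_dosage = d2,
    offspring_distribution = off
  ), class = "segregation_expectation")
}

#' @export
print.segregation_expectation <- function(x, ...) {
  cat(sprintf("F1 segregation, parental dosages %d x %d:\n",
              x$parent1_dosage, x$parent2_dosage))
  print(round(x$offspring_distribution, 4))
  invisible(x)
}
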