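#' Percent heterozygosity per line
#'
#' A call is heterozygous when it is not fully homozygous: under the
#' tetraploid model the simplex, duplex and triplex classes (AAAB, AABB,
#' ABBB) all count as a single heterozygous class; under the diploid
#' model only AB does. The denominator is the number of non-missing loci
#' for that line.
#'
#' @param g A `genotype_matrix`.
#' @return Data frame with `line_name`, `pct_heterozygous` (0..100, `NA`
#'   when the line has no scored loci) and `n_loci_used`.
#' @export
percent_heterozygosity <- function(g) {
  if (nrow(g) == 0L) stop("empty genotype matrix")
  homo <- g %in% c("AA", "BB", "AAAA", "BBBB")
  dim(homo) <- dim(g)
  het <- !is.na(g) & !homo
  n_used <- colSums(!is.na(g))
  pct <- ifelse(n_used > 0L, 100 * colSums(het) / n_used, NA_real_)
  data.frame(line_name = colnames(g), pct_heterozygous = pct,
             n_loci_used = n_used, row.names = NULL, stringsAsFactors = FALSE)
}

#' Group summaries of heterozygosity profiles
#'
#' Unweighted per-group mean, min and max of per-line percent
#' heterozygosity.
#'
#' @param profiles Output of [percent_heterozygosity()].
#' @param metadata Sample metadata covering every profiled line.
#' @param grouping `"market_class"`, `"group"` or `"ploidy"`.
#' @return Data frame with one row per non-empty group: group label,
#'   `n_lines`, `mean`, `min`, `max`.
#' @export
group_summary <- function(profiles, metadata,
                          grouping = c("market_class", "group", "ploidy")) {
  grouping <- match.arg(grouping)
  idx <- match(profiles$line_name, metadata$line_name)
  if (anyNA(idx)) {
    stop("metadata missing for line(s): ",
         paste(utils::head(profiles$line_name[is.na(idx)], 5), collapse = ", "))
  }
  key <- as.character(metadata[[grouping]][idx])
  keep <- !is.na(profiles$pct_heterozygous)
  if (any(!keep)) warning(sum(!keep), " line(s) without scored loci omitted")
  vals <- split(profiles$pct_heterozygous[keep], key[keep])
  out <- data.frame(
    group = names(vals),
    n_lines = vapply(vals, length, integer(1)),
    mean = vapply(vals, mean, numeric(1)),
    min = vapply(vals, min, numeric(1)),
    max = vapply(vals, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(out)[1L] <- grouping
  out
}

#' Subsampling correction for unequal group sizes
#'
#' Repeatedly draws `subsample_size` lines without replacement from the
#' profiled population and records the subsample mean percent
#' heterozygosity, to compare a large group against a small one on equal
#' footing (e.g. 10,000 subsamples of n = 12 cultivated lines against 12
#' wild accessions).
#'
#' @param profiles Output of [percent_heterozygosity()] restricted to the
#'   population to subsample.
#' @param subsample_size Lines per subsample.
#' @param replicates Number of subsamples.
#' @param seed Integer seed; fixed seed reproduces the draw stream.
#' @return List with `mean`, `min`, `max`, `percentiles` (1, 5, 25, 50,
#'   75, 95, 99) and the vector of `subsample_means`.
#' @export
subsample_heterozygosity <- function(profiles, subsample_size, replicates,
                                     seed = 1L) {
  vals <- profiles$pct_heterozygous[!is.na(profiles$pct_heterozygous)]
  if (subsample_size > length(vals)) {
    stop("subsample_size exceeds population size")
  }
  if (replicates < 1L) stop("replicates must be >= 1")
  set.seed(seed)
  means <- vapply(seq_len(replicates),
                  function(i) mean(sample(vals, subsample_size)),
                  numeric(1))
  list(mean = mean(means), min = min(means), max = max(means),
       percentiles = stats::quantile(means, c(.01, .05, .25, .5, .75, .95, .99)),
       subsample_means = means)
}

#' Allele-dosage frequency spectrum
#'
#' Per-line fractions of homozygous (AAAA or BBBB), single-dose (AAAB or
#' ABBB; simplex/triplex) and duplex (AABB) loci among non-missing calls,
#' with unweighted per-group means and an optional release-year series.
#'
#' @param g A tetraploid `genotype_matrix`.
#' @param metadata Optional metadata; enables per-market-class means and
#'   the release-year series.
#' @return List with `per_line` (line_name, homozygous_frac,
#'   single_dose_frac, duplex_frac, n_loci_used), and when metadata is
#'   given, `per_group` (by market class) and `by_year` (released lines
#'   only).
#' @export
dosage_spectrum <- function(g, metadata = NULL) {
  if (gt_model(g) != "tetraploid") stop("dosage spectrum needs tetraploid calls")
  count_frac <- function(labels) {
    inset <- matrix(g %in% labels, nrow(g))
    colSums(inset)
  }
  n_used <- colSums(!is.na(g))
  homo <- count_frac(c("AAAA", "BBBB")) / n_used
  single <- count_frac(c("AAAB", "ABBB")) / n_used
  duplex <- count_frac("AABB") / n_used
  per_line <- data.frame(line_name = colnames(g),
                         homozygous_frac = homo, single_dose_frac = single,
                         duplex_frac = duplex, n_loci_used = n_used,
                         row.names = NULL, stringsAsFactors = FALSE)
  out <- list(per_line = per_line)
  if (!is.null(metadata)) {
    idx <- match(per_line$line_name, metadata$line_name)
    cls <- metadata$market_class[idx]
    ok <- !is.na(cls) & n_used > 0L
    agg <- stats::aggregate(
      per_line[ok, c("homozygous_frac", "single_dose_frac", "duplex_frac")],
      by = list(market_class = cls[ok]), FUN = mean)
    out$per_group <- agg
    yr <- metadata$release_year[idx]
    sel <- !is.na(yr) & n_used > 0L
    out$by_year <- cbind(per_line[sel, , drop = FALSE], release_year = yr[sel])
  }
  out
}

#' Within-individual allele frequencies
#'
#' The B-allele frequency within one individual at one locus is its B
#' dosage divided by the model ploidy, so the possible values are 0,
#' 0.25, 0.5, 0.75, 1 under the tetraploid model and 0, 0.5, 1 under the
#' diploid model.
#'
#' @param g A `genotype_matrix`.
#' @return Numeric matrix (SNP x line) of B frequencies, `NA` for missing
#'   calls, with a `model` attribute.
#' @export
individual_allele_frequencies <- function(g) {
  f <- dosage_of(g) / model_ploidy(gt_model(g))
  dimnames(f) <- dimnames(g)
  attr(f, "model") <- gt_model(g)
  f
}
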