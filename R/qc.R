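#' Remove SNPs exceeding a missing-data threshold
#'
#' A SNP is removed if and only if its missing-call fraction is strictly
#' greater than `threshold` (a SNP at exactly the threshold is retained).
#'
#' @param g A `genotype_matrix`.
#' @param threshold Missing fraction cutoff in (0, 1); default 0.20.
#' @return List with `retained` (genotype matrix) and `removed` (log
#'   data frame: snp_id, reason, value).
#' @export
filter_missing <- function(g, threshold = 0.20) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  frac <- rowMeans(is.na(g))
  drop <- frac > threshold
  list(
    retained = genotype_matrix(unclass(g)[!drop, , drop = FALSE], gt_model(g)),
    removed = data.frame(snp_id = rownames(g)[drop],
                         reason = rep("missing_gt_threshold", sum(drop)),
                         value = frac[drop], row.names = NULL,
                         stringsAsFactors = FALSE)
  )
}

#' Remove SNPs mapping to multiple genomic locations
#'
#' A SNP is removed when its precomputed genome hit count is two or more.
#' SNPs absent from the report are retained with a warning (treated as a
#' single placement) and noted in the log.
#'
#' @param g A `genotype_matrix`.
#' @param report Multi-mapping report (`snp_id`, `hit_count`), see
#'   [read_multimap_report()].
#' @return List with `retained`, `removed` (log data frame) and
#'   `unreported` (SNP ids missing from the report).
#' @export
filter_multimapped <- function(g, report) {
  hits <- report$hit_count[match(rownames(g), report$snp_id)]
  unreported <- rownames(g)[is.na(hits)]
  if (length(unreported)) {
    warning(length(unreported),
            " SNP(s) absent from multimap report; treated as single-placement")
    hits[is.na(hits)] <- 1L
  }
  drop <- hits >= 2L
  list(
    retained = genotype_matrix(unclass(g)[!drop, , drop = FALSE], gt_model(g)),
    removed = data.frame(snp_id = rownames(g)[drop],
                         reason = rep("multi_mapped", sum(drop)),
                         value = hits[drop], row.names = NULL,
                         stringsAsFactors = FALSE),
    unreported = unreported
  )
}

#' Remove SNPs flagged during boundary estimation
#'
#' Drops SNPs whose boundary sets are flagged `low_quality` or
#' `all_missing` (low signal, loose clustering, or assay failure).
#'
#' @param g A `genotype_matrix`.
#' @param bounds Boundary table covering the SNPs of `g`.
#' @return List with `retained` and `removed` as in [filter_missing()].
#' @export
filter_flagged <- function(g, bounds) {
  flag <- bounds$flag[match(rownames(g), bounds$snp_id)]
  flag[is.na(flag)] <- "ok"
  drop <- flag != "ok"
  list(
    retained = genotype_matrix(unclass(g)[!drop, , drop = FALSE], gt_model(g)),
    removed = data.frame(snp_id = rownames(g)[drop], reason = flag[drop],
                         value = rep(NA_real_, sum(drop)), row.names = NULL,
                         stringsAsFactors = FALSE)
  )
}

#' Census of boundary completeness
#'
#' Counts, for a tetraploid boundary table, how many SNPs have class
#' intervals defined for 5, 4, 3 and 2 of the five dosage clusters. SNPs
#' with fewer than two defined clusters are unusable for genotype calling
#' and are reported separately.
#'
#' @param bounds Boundary table (tetraploid).
#' @return List with `counts` (named integer vector over "2".."5") and
#'   `unusable` (number of SNPs with < 2 defined clusters).
#' @export
boundary_completeness_census <- function(bounds) {
  if (!all(bounds$model == "tetraploid")) {
    stop("census is defined for tetraploid boundary sets")
  }
  n_def <- lengths(bounds$defined_classes)
  counts <- vapply(2:5, function(k) sum(n_def == k), integer(1))
  names(counts) <- as.character(2:5)
  list(counts = counts, unusable = sum(n_def < 2L))
}
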