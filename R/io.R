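#' Read a theta intensity matrix
#'
#' Reads a tab-separated table of normalized theta intensities in the
#' GenomeStudio-export style: a header row of sample ids, one row per SNP
#' with the SNP id in the first column. Missing values may be encoded as
#' an empty field or `NA`. Values outside [0, 1] are an error, never
#' clamped; duplicate SNP or sample ids are an error.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, SNPs in rows (row names = SNP ids), samples in
#'   columns (column names = sample ids), `NA` for missing.
#' @export
read_theta_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""), check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("theta file needs a SNP id column plus >=1 sample")
  snp_ids <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(snp_ids)) {
    stop("duplicate SNP ids in ", path, ": ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric theta values in ", path)
  dimnames(m) <- list(snp_ids, sample_ids)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("theta value out of [0, 1] at (%s, %s): %g",
                 snp_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
                 m[bad[1L, , drop = FALSE]]))
  }
  m
}

#' Write a theta intensity matrix
#' @param theta Numeric matrix with SNP row names and sample column names.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_theta_matrix <- function(theta, path) {
  stopifnot(is.matrix(theta), !is.null(rownames(theta)), !is.null(colnames(theta)))
  df <- data.frame(snp_id = rownames(theta), theta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

VALID_GROUPS <- c("wild", "genetic_stock", "cultivated")
VALID_MARKET_CLASSES <- c("ChipProcessing", "FrenchFryProcessing", "Pigmented",
                          "RoundWhiteTable", "TableRusset", "Yellow", "none")
VALID_FAMILY_ROLES <- c("parent1", "parent2", "f1_progeny", "panel")

#' Read a sample metadata table
#'
#' TSV with columns `line_name`, `ploidy`, `group`, `market_class`,
#' `release_year`, `family_role`, `family_id` (the last three optional;
#' missing `family_role` means `panel`). Enforces the panel rules: each
#' line carries a single market class, only cultivated lines carry one,
#' and every F1 progeny references a family with exactly two parents.
#'
#' @param path TSV path.
#' @return A `data.frame`, one row per line.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  req <- c("line_name", "ploidy", "group", "market_class")
  miss <- setdiff(req, colnames(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (!"release_year" %in% colnames(md)) md$release_year <- NA_integer_
  if (!"family_role" %in% colnames(md)) md$family_role <- "panel"
  if (!"family_id" %in% colnames(md)) md$family_id <- NA_character_
  md$family_role[is.na(md$family_role)] <- "panel"
  md$market_class[is.na(md$market_class)] <- "none"
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  if (anyDuplicated(md$line_name)) {
    stop("duplicate line names: ",
         paste(unique(md$line_name[duplicated(md$line_name)]), collapse = ", "))
  }
  if (!all(md$ploidy %in% c(1L, 2L, 4L))) stop("ploidy must be 1, 2 or 4")
  bad <- setdiff(md$group, VALID_GROUPS)
  if (length(bad)) stop("unknown group: ", paste(bad, collapse = ", "))
  bad <- setdiff(md$market_class, VALID_MARKET_CLASSES)
  if (length(bad)) {
    stop("unknown market class: ", paste(bad, collapse = ", "),
         " (one class per line; valid: ",
         paste(VALID_MARKET_CLASSES, collapse = ", "), ")")
  }
  offender <- md$market_class != "none" & md$group != "cultivated"
  if (any(offender)) {
    stop("market_class set for non-cultivated line(s): ",
         paste(md$line_name[offender], collapse = ", "))
  }
  bad <- setdiff(md$family_role, VALID_FAMILY_ROLES)
  if (length(bad)) stop("unknown family_role: ", paste(bad, collapse = ", "))
  prog <- md[md$family_role == "f1_progeny", , drop = FALSE]
  for (fam in unique(prog$family_id)) {
    if (is.na(fam)) stop("f1_progeny without family_id")
    par_roles <- md$family_role[!is.na(md$family_id) & md$family_id == fam &
                                  md$family_role %in% c("parent1", "parent2")]
    if (!setequal(par_roles, c("parent1", "parent2"))) {
      stop("family '", fam, "' must have exactly one parent1 and one parent2")
    }
  }
  invisible(md)
}

#' Write a sample metadata table
#' @param metadata Metadata data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  write_tsv(metadata, path)
}

#' Read / write a genotype matrix
#'
#' On disk genotype calls are literal class strings (`AA`..`BBBB`); the
#' B-allele dosage is the count of `B` characters in the label. Layout is
#' as for the theta matrix: SNPs in rows, samples in columns.
#'
#' @param path TSV path.
#' @param model Calling model the file's labels belong to.
#' @return A `genotype_matrix`.
#' @export
read_genotype_matrix <- function(path, model) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""), check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  snp_ids <- tab[[1L]]
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(m) <- list(snp_ids, colnames(tab)[-1L])
  genotype_matrix(m, model)
}

#' @rdname read_genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
write_genotype_matrix <- function(g, path) {
  df <- data.frame(snp_id = rownames(g), unclass(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read / write a cluster-boundary table
#'
#' One row per SNP: `snp_id`, `model`, boundary columns `b1`..`b4` (empty
#' when undefined), `defined_classes` (comma-separated labels, ascending
#' dosage), `flag` (`ok`, `low_quality`, or `all_missing`).
#'
#' @param path TSV path.
#' @return A boundary table: `data.frame` with list columns `boundaries`
#'   and `defined_classes`.
#' @export
read_boundary_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""), stringsAsFactors = FALSE)
  bcols <- grep("^b[0-9]+$", colnames(tab), value = TRUE)
  boundaries <- lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(unlist(tab[i, bcols]))
    v <- v[!is.na(v)]
    if (is.unsorted(v, strictly = TRUE)) {
      stop("boundaries not strictly increasing for SNP ", tab$snp_id[i])
    }
    v
  })
  defined <- lapply(tab$defined_classes, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1L]]
  })
  out <- data.frame(snp_id = tab$snp_id, model = tab$model,
                    flag = if ("flag" %in% colnames(tab)) tab$flag else "ok",
                    stringsAsFactors = FALSE)
  out$boundaries <- boundaries
  out$defined_classes <- defined
  validate_boundary_table(out)
  out
}

validate_boundary_table <- function(bt) {
  for (i in seq_len(nrow(bt))) {
    b <- bt$boundaries[[i]]
    cls <- bt$defined_classes[[i]]
    if (length(b) && is.unsorted(b, strictly = TRUE)) {
      stop("boundaries not strictly increasing for SNP ", bt$snp_id[i])
    }
    if (length(b) && (any(b <= 0) || any(b >= 1))) {
      stop("boundaries must lie in (0, 1) for SNP ", bt$snp_id[i])
    }
    if (length(cls) && length(cls) != length(b) + 1L) {
      stop("SNP ", bt$snp_id[i], ": ", length(cls), " classes need ",
           length(cls) - 1L, " boundaries, got ", length(b))
    }
    model_cls <- genotype_classes(bt$model[i])
    if (!all(cls %in% model_cls)) {
      stop("SNP ", bt$snp_id[i], ": classes not valid for ", bt$model[i])
    }
  }
  invisible(bt)
}

#' @rdname read_boundary_table
#' @param bt A boundary table.
#' @export
write_boundary_table <- function(bt, path) {
  nb <- max(4L, max(lengths(bt$boundaries), 0L))
  bmat <- t(vapply(bt$boundaries, function(v) {
    c(v, rep(NA_real_, nb - length(v)))
  }, numeric(nb)))
  colnames(bmat) <- paste0("b", seq_len(nb))
  df <- data.frame(snp_id = bt$snp_id, model = bt$model, bmat,
                   defined_classes = vapply(bt$defined_classes, paste,
                                            character(1), collapse = ","),
                   flag = bt$flag, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a multi-mapping report
#'
#' TSV with columns `snp_id` and `hit_count` (number of genomic placements
#' of the SNP's context sequence, precomputed by an external aligner).
#'
#' @param path TSV path.
#' @return `data.frame` with one record per SNP.
#' @export
read_multimap_report <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("snp_id", "hit_count") %in% colnames(tab))) {
    stop("multimap report needs columns snp_id, hit_count")
  }
  if (anyDuplicated(tab$snp_id)) stop("duplicate SNP ids in multimap report")
  if (any(tab$hit_count < 0)) stop("negative hit_count")
  tab
}

#' Read a candidate-gene SNP list
#'
#' TSV with columns `snp_id`, `gene_name`, `pathway`.
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_candidate_list <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"snp_id" %in% colnames(tab)) stop("candidate list needs column snp_id")
  tab
}

#' Write a tree in Newick format
#'
#' @param tree An ultrametric `phylo` tree (e.g. from [upgma_tree()]).
#' @param path Output path; the file ends with `;` and a newline.
#' @return `path`, invisibly.
#' @export
write_newick_tree <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo") || length(tree$tip.label) == 0L) {
    stop("tree must be a non-empty phylo object")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length; refusing to serialize")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Plain-text `key=value` files; vector values are comma-separated.
#'
#' @param path File path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1)))
  named <- stats::setNames(as.list(vals), keys)
  num <- function(k, default) if (k %in% keys) as.numeric(strsplit(named[[k]], ",")[[1L]]) else default
  run_config(
    model = if ("model" %in% keys) named$model else "tetraploid",
    missing_threshold = num("missing_threshold", 0.20),
    significance_level = num("significance_level", 0.05),
    seed = as.integer(num("seed", 1)),
    cluster_center_priors = num("cluster_center_priors", NULL),
    noise_sd = num("noise_sd", 0.03),
    min_separation = num("min_separation", 0.04),
    max_spread = num("max_spread", 0.10)
  )
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, "=", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
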