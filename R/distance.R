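#' Rogers genetic distance between lines
#'
#' At each biallelic locus the distance between two lines is the
#' Euclidean-type form sqrt(1/2 * sum over alleles of (p - q)^2) applied
#' to the within-individual allele-frequency vectors, which for the pair
#' {A, B} reduces to |pB_i - pB_j|; the overall distance is the mean over
#' loci where both lines are scored (pairwise deletion of missing data).
#' Distances lie in [0, 1].
#'
#' @param freqs Within-individual B-frequency matrix (SNP x line) from
#'   [individual_allele_frequencies()].
#' @param line_i,line_j Column names of the pair.
#' @return Single distance for the pair form; [rogers_distance_matrix()]
#'   returns the symmetric all-pairs `dist`-compatible matrix.
#' @export
rogers_distance <- function(freqs, line_i, line_j) {
  pi <- freqs[, line_i]
  pj <- freqs[, line_j]
  joint <- !is.na(pi) & !is.na(pj)
  if (!any(joint)) {
    stop("lines ", line_i, " and ", line_j, " share no scored loci")
  }
  mean(sqrt(0.5 * ((pi[joint] - pj[joint])^2 + ((1 - pi[joint]) - (1 - pj[joint]))^2)))
}

#' @rdname rogers_distance
#' @export
rogers_distance_matrix <- function(freqs) {
  labels <- colnames(freqs)
  n <- length(labels)
  obs <- !is.na(freqs)
  f0 <- freqs
  f0[!obs] <- 0
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    joint <- obs & obs[, i]              # loci scored in both members
    diffs <- abs(f0 - f0[, i])
    diffs[!joint] <- 0
    nj <- colSums(joint)
    if (any(nj == 0L & seq_len(n) != i)) {
      j <- which(nj == 0L & seq_len(n) != i)[1L]
      stop("lines ", labels[i], " and ", labels[j], " share no scored loci")
    }
    d[, i] <- colSums(diffs) / pmax(nj, 1L)
  }
  d[cbind(seq_len(n), seq_len(n))] <- 0
  (d + t(d)) / 2
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group average-linkage clustering: the closest
#' pair of clusters is merged and inter-cluster distances are updated as
#' size-weighted arithmetic means; each merge creates a node at height
#' merge-distance / 2, so the tree is ultrametric. Labels are processed
#' in lexicographic order, which makes tie resolution deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal and row/column
#'   labels (no `NA`/`NaN`), or a `dist` object.
#' @return A rooted, ultrametric `phylo` tree.
#' @export
upgma_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(is.na(d)) || any(is.nan(d))) stop("distance matrix contains NA/NaN")
  if (nrow(d) < 2L) stop("need at least 2 labels")
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # as.phylo.hclust halves merge heights, giving node height = d / 2
  ape::as.phylo(hc)
}

#' Market-class concentration on a tree
#'
#' For each market class, the minimum number of leaf-disjoint subtrees
#' needed to cover all of the class's members — 1 when the class sits on
#' a single branch (is monophyletic), more when it is split across the
#' tree. Computed as the number of maximal pure-class clades.
#'
#' @param tree A `phylo` tree whose tips are line names.
#' @param metadata Metadata assigning a `market_class` to every tip.
#' @return Data frame with `market_class`, `n_lines`, `n_subtrees`.
#' @export
class_concentration <- function(tree, metadata) {
  tips <- tree$tip.label
  idx <- match(tips, metadata$line_name)
  if (anyNA(idx)) {
    stop("metadata missing for tip(s): ",
         paste(utils::head(tips[is.na(idx)], 5), collapse = ", "))
  }
  cls <- metadata$market_class[idx]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  parent_of <- integer(n_node)
  parent_of[edge[, 2L]] <- edge[, 1L]
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  parent_of[root] <- root  # root guarded explicitly below

  classes <- setdiff(unique(cls), "none")
  out <- lapply(classes, function(cc) {
    pure <- logical(n_node)
    pure[seq_len(n_tip)] <- cls == cc
    pure[(n_tip + 1L):n_node] <- TRUE
    for (k in seq_len(nrow(edge))) {
      pure[edge[k, 1L]] <- pure[edge[k, 1L]] && pure[edge[k, 2L]]
    }
    has_member <- logical(n_node)
    has_member[seq_len(n_tip)] <- cls == cc
    for (k in seq_len(nrow(edge))) {
      has_member[edge[k, 1L]] <- has_member[edge[k, 1L]] || has_member[edge[k, 2L]]
    }
    maximal <- pure & has_member &
      (seq_len(n_node) == root | !pure[parent_of])
    data.frame(market_class = cc, n_lines = sum(cls == cc),
               n_subtrees = sum(maximal), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
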