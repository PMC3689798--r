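# Shared fixtures and independent oracles used across test files.

# Quick metadata builder for panel lines.
make_metadata <- function(line_name, ploidy = 4L, group = "cultivated",
                          market_class = "none", release_year = NA_integer_,
                          family_role = "panel", family_id = NA_character_) {
  data.frame(line_name = line_name, ploidy = ploidy, group = group,
             market_class = market_class, release_year = release_year,
             family_role = family_role, family_id = family_id,
             stringsAsFactors = FALSE)
}

gm <- function(calls, model, snps = NULL, lines = NULL) {
  m <- as.matrix(calls)
  if (!is.null(snps)) rownames(m) <- snps
  if (!is.null(lines)) colnames(m) <- lines
  genotype_matrix(m, model)
}

# Exhaustive gamete-pair enumeration oracle for F1 segregation: every
# parent gamete is an unordered pair (tetraploid) or single allele
# (diploid) of explicitly enumerated allele slots, all equiprobable.
enumerate_f1_segregation <- function(d1, d2, model) {
  ploidy <- if (model == "tetraploid") 4L else 2L
  gametes <- function(b) {
    alleles <- c(rep(1L, b), rep(0L, ploidy - b))
    if (ploidy == 4L) {
      combos <- utils::combn(4L, 2L)
      apply(combos, 2L, function(ix) sum(alleles[ix]))
    } else {
      alleles
    }
  }
  g1 <- gametes(d1)
  g2 <- gametes(d2)
  off <- outer(g1, g2, "+")
  counts <- tabulate(as.vector(off) + 1L, nbins = ploidy + 1L)
  p <- counts / length(off)
  names(p) <- genotype_classes(model)
  p
}

# Naive O(n^3) UPGMA oracle: returns the ultrametric cophenetic height
# matrix (height of the MRCA of each leaf pair = merge distance / 2).
naive_upgma_heights <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  U <- matrix(0, n, n, dimnames = list(labels, labels))
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && D[a, b] < bestd) { bestd <- D[a, b]; best <- c(a, b) }
    }
    i <- best[1L]; j <- best[2L]
    h <- bestd / 2
    for (a in members[[i]]) for (b in members[[j]]) {
      U[a, b] <- U[b, a] <- h
    }
    # size-weighted average linkage update, merged cluster kept in slot i
    for (k in which(active)) {
      if (k != i && k != j) {
        D[i, k] <- D[k, i] <-
          (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
  }
  U
}

# One shared default synthetic panel per test run (boundary estimation on
# 2,000 SNPs is the expensive step; several acceptance checks reuse it).
default_panel_cache <- new.env(parent = emptyenv())
get_default_panel <- function() {
  if (is.null(default_panel_cache$panel)) {
    spec <- simulation_spec(seed = 20260101L)
    sim <- simulate_panel(spec)
    bounds <- estimate_boundaries(sim$theta, sim$metadata, "tetraploid")
    calls <- call_genotypes(sim$theta, bounds)
    default_panel_cache$panel <- list(spec = spec, sim = sim,
                                      bounds = bounds, calls = calls)
  }
  default_panel_cache$panel
}
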