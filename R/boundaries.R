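#' Estimate per-SNP theta cluster boundaries
#'
#' For each SNP the non-missing theta values are fit with a 1-D Gaussian
#' mixture whose component count equals the model's genotype-class count,
#' initialized at `config$cluster_center_priors`. Components that capture
#' posterior mass below 2/n are dropped and near-coincident components are
#' merged, so only marker classes actually present in the panel receive a
#' class interval. Retained clusters are assigned class identities
#' (ascending theta maps AAAA..BBBB by default) by the monotone assignment
#' closest to the prior centers; when an F1 family is present in
#' `metadata`, candidate assignments are instead scored by the multinomial
#' likelihood of the observed progeny cluster occupancies under the
#' expected F1 segregation ratios given the parental cluster assignments,
#' and the best-scoring labeling wins. Boundaries are placed at
#' equal-posterior points between adjacent retained components, falling
#' back to the midpoint of the component means when the components barely
#' overlap.
#'
#' SNPs whose retained clusters sit closer than `config$min_separation`,
#' or spread wider than `config$max_spread`, are flagged `low_quality`;
#' SNPs with fewer than two non-missing samples are flagged `all_missing`.
#'
#' @param theta Numeric theta matrix (SNP x sample, values in [0, 1]).
#' @param metadata Optional sample metadata; rows with `family_role`
#'   `parent1`/`parent2`/`f1_progeny` sharing a `family_id` anchor the
#'   class labeling.
#' @param model Calling model.
#' @param config A [run_config()]; its model must match `model`.
#' @param orientation `"ascending"` (default: low theta = AAAA) or
#'   `"descending"` for the opposite strand convention.
#' @param samples Sample names whose theta values inform the clusters.
#'   Defaults to all samples, or, when `metadata` is supplied, to the
#'   samples whose ploidy matches the model (mixed-ploidy panels place
#'   off-model lines between dosage clusters and would distort them);
#'   calling via [call_genotypes()] still covers every sample.
#' @return A boundary table (`data.frame` with list columns `boundaries`
#'   and `defined_classes`, plus `flag`).
#' @export
estimate_boundaries <- function(theta, metadata = NULL, model = "tetraploid",
                                config = run_config(model),
                                orientation = c("ascending", "descending"),
                                samples = NULL) {
  model <- match_model(model)
  orientation <- match.arg(orientation)
  if (config$model != model) stop("config model does not match model")
  classes <- genotype_classes(model)
  if (orientation == "descending") classes <- rev(classes)
  centers <- config$cluster_center_priors
  k <- length(centers)

  if (is.null(samples) && !is.null(metadata)) {
    matched <- metadata$line_name[metadata$ploidy == model_ploidy(model)]
    samples <- intersect(colnames(theta), matched)
  }
  if (!is.null(samples) && length(samples) >= 2L) {
    theta <- theta[, samples, drop = FALSE]
  }

  families <- anchor_families(metadata, colnames(theta))
  seg_cache <- new.env(parent = emptyenv())

  n_snp <- nrow(theta)
  boundaries <- vector("list", n_snp)
  defined <- vector("list", n_snp)
  flag <- character(n_snp)

  for (i in seq_len(n_snp)) {
    x <- theta[i, ]
    obs <- which(!is.na(x))
    if (length(obs) < 2L) {
      boundaries[[i]] <- numeric(0)
      defined[[i]] <- character(0)
      flag[i] <- "all_missing"
      next
    }
    xs <- as.numeric(x[obs])
    fit <- fit_theta_mixture(xs, centers, init_sd = config$noise_sd,
                             min_mass = 2 / length(xs),
                             merge_tol = config$min_separation / 2)
    m <- length(fit$mean)
    cand <- monotone_assignments(k, m)
    assign_idx <- pick_assignment(fit, cand, centers, classes, model,
                                  x, obs, families, seg_cache)
    # defined_classes is stored in theta-interval order (ascending theta),
    # which is ascending dosage unless orientation is descending
    boundaries[[i]] <- component_boundaries(fit)
    defined[[i]] <- classes[cand[[assign_idx]]]
    low <- (m > 1L && min(diff(fit$mean)) < config$min_separation) ||
      max(fit$sd) > config$max_spread
    flag[i] <- if (low) "low_quality" else "ok"
  }

  out <- data.frame(snp_id = rownames(theta), model = model, flag = flag,
                    stringsAsFactors = FALSE)
  out$boundaries <- boundaries
  out$defined_classes <- defined
  out
}

# All monotone injections of m retained components into k ordered classes.
monotone_assignments <- function(k, m) {
  combos <- utils::combn(k, m)
  lapply(seq_len(ncol(combos)), function(j) combos[, j])
}

# Choose among candidate class assignments: F1 multinomial likelihood when
# a usable family exists, otherwise (and as tie-break) proximity of
# component means to the prior class centers.
pick_assignment <- function(fit, cand, centers, classes, model,
                            x, obs, families, seg_cache) {
  cost <- vapply(cand, function(a) sum(abs(fit$mean - centers[a])), numeric(1))
  if (length(cand) == 1L || length(families) == 0L) {
    return(which.min(cost))
  }
  hard <- integer(length(x))
  hard[obs] <- hard_assign(as.numeric(x[obs]), fit)
  ll <- numeric(length(cand))
  usable <- FALSE
  for (fam in families) {
    i1 <- fam$parent1; i2 <- fam$parent2
    if (is.na(x[i1]) || is.na(x[i2])) next
    prog <- fam$progeny[!is.na(x[fam$progeny])]
    if (length(prog) == 0L) next
    usable <- TRUE
    occ <- tabulate(hard[prog], nbins = length(fit$mean))
    for (j in seq_along(cand)) {
      a <- cand[[j]]
      p1 <- classes[a[hard[i1]]]
      p2 <- classes[a[hard[i2]]]
      key <- paste(p1, p2, sep = "|")
      seg <- seg_cache[[key]]
      if (is.null(seg)) {
        seg <- expected_f1_segregation(p1, p2, model)$offspring_distribution
        seg_cache[[key]] <- seg
      }
      pr <- pmax(seg[classes[a]], 1e-6)
      ll[j] <- ll[j] + sum(occ * log(pr))
    }
  }
  if (!usable) return(which.min(cost))
  best <- which(ll > max(ll) - 1e-9)
  best[which.min(cost[best])]
}

anchor_families <- function(metadata, sample_ids) {
  if (is.null(metadata)) return(list())
  md <- metadata[metadata$family_role != "panel" &
                   metadata$line_name %in% sample_ids, , drop = FALSE]
  fams <- list()
  for (fam in unique(stats::na.omit(md$family_id))) {
    sub <- md[!is.na(md$family_id) & md$family_id == fam, , drop = FALSE]
    p1 <- sub$line_name[sub$family_role == "parent1"]
    p2 <- sub$line_name[sub$family_role == "parent2"]
    pr <- sub$line_name[sub$family_role == "f1_progeny"]
    if (length(p1) == 1L && length(p2) == 1L && length(pr) > 0L) {
      fams[[fam]] <- list(parent1 = match(p1, sample_ids),
                          parent2 = match(p2, sample_ids),
                          progeny = match(pr, sample_ids))
    }
  }
  fams
}

# Fixed-K 1-D Gaussian mixture EM, components kept sorted by mean.
fit_theta_mixture <- function(x, centers, init_sd = 0.03, min_mass = 0,
                              merge_tol = 0.02, max_iter = 300L,
                              tol = 1e-10, sd_floor = 0.005) {
  k <- length(centers)
  n <- length(x)
  mu <- centers
  sd <- rep(max(init_sd, 2 * sd_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    r <- dens / tot
    ll <- sum(log(tot))
    nk <- colSums(r)
    upd <- nk > 1e-8
    w <- nk / n
    mu[upd] <- (colSums(r * x) / nk)[upd]
    v <- colSums(r * (outer(x, mu, "-"))^2) / pmax(nk, 1e-8)
    sd[upd] <- pmax(sqrt(v[upd]), sd_floor)
    ord <- order(mu)
    mu <- mu[ord]; sd <- sd[ord]; w <- w[ord]
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  keep <- w >= min_mass
  if (!any(keep)) keep[which.max(w)] <- TRUE
  fit <- list(mean = mu[keep], sd = sd[keep], weight = w[keep])
  merge_components(fit, merge_tol)
}

# Merge adjacent components that do not describe two separate clusters:
# either their means nearly coincide (several components collapsed onto
# one observed cluster) or the two-component density has no real valley
# between the means (a spurious component latched onto a cluster tail).
# The valley test compares the pair's density at its internal minimum to
# the lower of the two peak densities; a genuine pair of clusters has a
# minimum well below both peaks.
merge_components <- function(fit, merge_tol, valley_ratio = 0.5) {
  pair_valley <- function(j) {
    dens <- function(x) {
      fit$weight[j] * stats::dnorm(x, fit$mean[j], fit$sd[j]) +
        fit$weight[j + 1L] * stats::dnorm(x, fit$mean[j + 1L], fit$sd[j + 1L])
    }
    grid <- seq(fit$mean[j], fit$mean[j + 1L], length.out = 64L)
    min(dens(grid)) / min(dens(fit$mean[j]), dens(fit$mean[j + 1L]))
  }
  repeat {
    m <- length(fit$mean)
    if (m < 2L) return(fit)
    gaps <- diff(fit$mean)
    j <- which.min(gaps)
    if (gaps[j] >= merge_tol) {
      ratios <- vapply(seq_len(m - 1L), pair_valley, numeric(1))
      j <- which.max(ratios)
      if (ratios[j] <= valley_ratio) return(fit)
    }
    w <- fit$weight[j] + fit$weight[j + 1L]
    mu <- (fit$weight[j] * fit$mean[j] + fit$weight[j + 1L] * fit$mean[j + 1L]) / w
    s <- sqrt((fit$weight[j] * (fit$sd[j]^2 + (fit$mean[j] - mu)^2) +
                 fit$weight[j + 1L] * (fit$sd[j + 1L]^2 + (fit$mean[j + 1L] - mu)^2)) / w)
    fit$mean <- append(fit$mean[-c(j, j + 1L)], mu, after = j - 1L)
    fit$sd <- append(fit$sd[-c(j, j + 1L)], s, after = j - 1L)
    fit$weight <- append(fit$weight[-c(j, j + 1L)], w, after = j - 1L)
  }
}

hard_assign <- function(x, fit) {
  dens <- vapply(seq_along(fit$mean), function(j) {
    fit$weight[j] * stats::dnorm(x, fit$mean[j], fit$sd[j])
  }, numeric(length(x)))
  if (length(x) == 1L) dens <- matrix(dens, nrow = 1L)
  max.col(dens, ties.method = "first")
}

# Equal-posterior point between each pair of adjacent components, falling
# back to the midpoint of means when the densities barely overlap.
component_boundaries <- function(fit) {
  m <- length(fit$mean)
  if (m < 2L) return(numeric(0))
  vapply(seq_len(m - 1L), function(j) {
    f <- function(x) {
      log(fit$weight[j]) + stats::dnorm(x, fit$mean[j], fit$sd[j], log = TRUE) -
        log(fit$weight[j + 1L]) - stats::dnorm(x, fit$mean[j + 1L], fit$sd[j + 1L], log = TRUE)
    }
    lo <- fit$mean[j]; hi <- fit$mean[j + 1L]
    flo <- f(lo); fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && flo > 0 && fhi < 0) {
      stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    } else {
      (lo + hi) / 2
    }
  }, numeric(1))
}

#' Convert a theta matrix into genotype calls
#'
#' Each theta value is assigned the class of the boundary interval that
#' contains it. Intervals are left-closed, right-open (a value exactly on
#' a boundary belongs to the higher-dosage side); the final interval is
#' right-closed at 1. Missing theta gives a missing call, as does any SNP
#' whose boundary set defines no classes; classes absent from
#' `defined_classes` are never produced.
#'
#' @param theta Theta matrix; every SNP must appear in `bounds`.
#' @param bounds Boundary table from [estimate_boundaries()] or
#'   [read_boundary_table()]; a single model throughout.
#' @return A `genotype_matrix`.
#' @export
call_genotypes <- function(theta, bounds) {
  model <- unique(bounds$model)
  if (length(model) != 1L) stop("boundary table mixes models")
  model <- match_model(model)
  idx <- match(rownames(theta), bounds$snp_id)
  if (anyNA(idx)) {
    stop("no boundaries for SNP(s): ",
         paste(utils::head(rownames(theta)[is.na(idx)], 5), collapse = ", "))
  }
  calls <- matrix(NA_character_, nrow(theta), ncol(theta),
                  dimnames = dimnames(theta))
  for (r in seq_len(nrow(theta))) {
    b <- bounds$boundaries[[idx[r]]]
    cls <- bounds$defined_classes[[idx[r]]]
    if (length(cls) == 0L) next
    if (length(b) && is.unsorted(b, strictly = TRUE)) {
      stop("boundaries not sorted for SNP ", rownames(theta)[r])
    }
    x <- theta[r, ]
    ok <- !is.na(x)
    calls[r, ok] <- cls[findInterval(x[ok], b) + 1L]
  }
  genotype_matrix(calls, model)
}

#' Replicate call concordance
#'
#' Fraction of contradicting calls between paired replicate samples,
#' computed over loci where both replicates have a non-missing call.
#'
#' @param calls_a,calls_b Genotype matrices under the same model sharing a
#'   SNP set.
#' @param pairs Data frame with columns `a` and `b` naming paired samples
#'   in `calls_a` and `calls_b`; by default, shared column names are
#'   paired with themselves.
#' @return List with `per_pair` (data frame: a, b, n_joint, discordance),
#'   `mean` and `max` over pairs with at least one jointly scored locus
#'   (pairs without any are reported with `NA` discordance).
#' @export
replicate_concordance <- function(calls_a, calls_b, pairs = NULL) {
  if (gt_model(calls_a) != gt_model(calls_b)) stop("models differ")
  common <- intersect(rownames(calls_a), rownames(calls_b))
  if (!setequal(rownames(calls_a), rownames(calls_b))) {
    stop("matrices must share their SNP set")
  }
  if (is.null(pairs)) {
    shared <- intersect(colnames(calls_a), colnames(calls_b))
    pairs <- data.frame(a = shared, b = shared, stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    va <- calls_a[common, pairs$a[i]]
    vb <- calls_b[common, pairs$b[i]]
    joint <- !is.na(va) & !is.na(vb)
    n <- sum(joint)
    data.frame(a = pairs$a[i], b = pairs$b[i], n_joint = n,
               discordance = if (n == 0L) NA_real_ else mean(va[joint] != vb[joint]),
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, res)
  d <- per_pair$discordance
  list(per_pair = per_pair,
       mean = if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE),
       max = if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE))
}
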