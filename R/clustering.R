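#' Nei's standard genetic distance between populations
#'
#' For each population pair, over loci where both frequencies are non-missing:
#' gene identities \eqn{J_{XY} = \mathrm{mean}_l (x y + (1-x)(1-y))},
#' \eqn{J_X = \mathrm{mean}_l (x^2 + (1-x)^2)} (and likewise \eqn{J_Y}), and
#' \eqn{D = -\ln( J_{XY} / \sqrt{J_X J_Y} )}. A zero cross-identity yields
#' `Inf`, flagged in the `infinite` attribute.
#'
#' @param freqs numeric matrix (SNPs x populations) of alternate-allele
#'   frequencies with population column names.
#' @return symmetric distance matrix with zero diagonal and attribute
#'   `infinite`.
#' @export
nei_distance <- function(freqs) {
  P <- ncol(freqs)
  if (is.null(colnames(freqs))) stopf("population column names are required")
  D <- matrix(0, P, P, dimnames = list(colnames(freqs), colnames(freqs)))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    x <- freqs[, i]; y <- freqs[, j]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    jxy <- mean(x * y + (1 - x) * (1 - y))
    jx <- mean(x^2 + (1 - x)^2)
    jy <- mean(y^2 + (1 - y)^2)
    D[i, j] <- D[j, i] <- if (jxy == 0) Inf else -log(jxy / sqrt(jx * jy))
  }
  attr(D, "infinite") <- any(is.infinite(D))
  D
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Saitou-Nei agglomeration via [ape::nj()]. Any negative branch length is
#' clamped to zero and its deficit transferred to the sister branch sharing
#' the same internal node, preserving the path length between the two
#' daughters.
#'
#' @param D symmetric distance matrix (>= 3 populations, finite entries).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (any(is.infinite(D))) stopf("infinite distances cannot be joined")
  if (nrow(D) < 3) stopf("at least 3 populations are required")
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sis <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sis)) {
      s <- sis[1]
      tr$edge.length[s] <- tr$edge.length[s] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Locus-bootstrap support for a neighbor-joining network
#'
#' Resamples loci with replacement, recomputes Nei distances and the NJ tree,
#' and reports the percentage of replicates recovering each bipartition of
#' the observed tree. Replicates producing non-finite distances are skipped
#' and counted.
#'
#' @param freqs numeric matrix (SNPs x populations).
#' @param n_reps bootstrap replicates.
#' @param seed integer seed.
#' @return the observed tree with `node.label` set to supports (in percent)
#'   and attributes `n_used`, `n_skipped`.
#' @export
bootstrap_nj <- function(freqs, n_reps = 10000, seed = 1L) {
  set.seed(seed)
  obs <- nj_tree(nei_distance(freqs))
  S <- nrow(freqs)
  trees <- vector("list", n_reps)
  used <- 0L
  for (b in seq_len(n_reps)) {
    fb <- freqs[sample.int(S, S, replace = TRUE), , drop = FALSE]
    Db <- nei_distance(fb)
    if (any(!is.finite(Db))) next
    used <- used + 1L
    trees[[used]] <- nj_tree(Db)
  }
  if (!used) stopf("all bootstrap replicates were degenerate")
  trees <- trees[seq_len(used)]
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(obs, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  obs$node.label <- round(100 * counts / used, 1)
  attr(obs, "n_used") <- used
  attr(obs, "n_skipped") <- n_reps - used
  obs
}

# Impute missing dosages with the per-SNP mean and center columns.
center_impute <- function(D) {
  mu <- colMeans(D, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  X <- sweep(D, 2, mu)
  X[is.na(X)] <- 0
  X
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Dimension reduction by PCA of the (mean-imputed, centered) dosage matrix
#' followed by linear discriminant analysis on the retained PC scores with
#' equal group priors and pooled within-group covariance. Gaussian LDA
#' posteriors give per-individual membership probabilities; the headline
#' statistic is the mean posterior probability of correct self-assignment.
#'
#' @param D dosage matrix (individuals x SNPs).
#' @param groups factor (or vector) of pre-defined population labels, one per
#'   individual; >= 2 groups with >= 2 individuals each.
#' @param n_pca number of retained principal components (>= 1, at most the
#'   matrix rank).
#' @param scale_snps scale dosages to unit variance before PCA (default
#'   centering only).
#' @return object of class `dapc_fit`: `membership` (individuals x groups,
#'   rows sum to 1), `assign_mean` (mean correct-assignment probability),
#'   `assign_hard` (proportion assigned to own group), `coords`
#'   (discriminant coordinates), `eig_shares`, `pc_scores`, `groups`,
#'   `n_pca`, `pca_var` (explained variance shares).
#' @export
dapc_fit <- function(D, groups, n_pca, scale_snps = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("at least 2 groups are required")
  if (any(table(groups) < 2)) stopf("every group needs >= 2 individuals")
  if (n_pca < 1) stopf("n_pca must be >= 1")
  X <- center_impute(D)
  if (scale_snps) {
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(X, 2, sdv, `/`)
  }
  pca <- stats::prcomp(X, center = FALSE)
  rank <- sum(pca$sdev > 1e-9)
  if (n_pca > rank) stopf("n_pca exceeds the rank of the data (%d)", rank)
  scores <- pca$x[, seq_len(n_pca), drop = FALSE]
  fit <- lda_membership(scores, groups)
  structure(list(
    membership = fit$posterior, assign_mean = fit$assign_mean,
    assign_hard = fit$assign_hard, coords = fit$coords,
    eig_shares = fit$eig_shares, pc_scores = scores, groups = groups,
    n_pca = n_pca,
    pca_var = (pca$sdev^2 / sum(pca$sdev^2))[seq_len(n_pca)]),
    class = "dapc_fit")
}

# LDA with equal priors on PC scores; returns posteriors and summaries.
lda_membership <- function(scores, groups) {
  k <- nlevels(groups)
  ld <- MASS::lda(scores, grouping = groups, prior = rep(1 / k, k))
  pr <- stats::predict(ld)
  post <- pr$posterior
  own <- post[cbind(seq_along(groups), as.integer(groups))]
  list(posterior = post,
       assign_mean = mean(own),
       assign_hard = mean(pr$class == groups),
       coords = pr$x,
       eig_shares = ld$svd^2 / sum(ld$svd^2),
       lda = ld)
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat(sprintf(
    "DAPC: %d groups, %d PCs, %d discriminant function(s); mean correct-assignment probability %.3f\n",
    nlevels(x$groups), x$n_pca, length(x$eig_shares), x$assign_mean))
  invisible(x)
}

#' Choose the number of retained PCs by a-score
#'
#' For each candidate number of PCs, the a-score is the observed proportion
#' of successful reassignment of individuals to their pre-defined populations
#' minus the mean proportion over `n_rand` runs with randomized group labels
#' (the penalty for discrimination achievable by chance with that many PCs).
#' Returns the smallest `m` attaining the maximum a-score.
#'
#' @param D dosage matrix (individuals x SNPs).
#' @param groups population labels.
#' @param m_grid candidate numbers of PCs (defaults to `1:min(10, rank)`).
#' @param n_rand randomized-label runs per candidate.
#' @param seed integer seed.
#' @return list with `best_m` and `curve` (data frame m, observed,
#'   random_mean, a_score).
#' @export
optimize_a_score <- function(D, groups, m_grid = NULL, n_rand = 10,
                             seed = 1L) {
  set.seed(seed)
  groups <- factor(groups)
  X <- center_impute(D)
  pca <- stats::prcomp(X, center = FALSE)
  rank <- sum(pca$sdev > 1e-9)
  m_grid <- m_grid %||% seq_len(min(10L, rank))
  if (!length(m_grid)) stopf("empty PC grid")
  if (max(m_grid) > rank) stopf("m grid exceeds the rank of the data")
  rows <- lapply(m_grid, function(m) {
    sc <- pca$x[, seq_len(m), drop = FALSE]
    obs <- lda_membership(sc, groups)$assign_hard
    rnd <- vapply(seq_len(n_rand), function(i)
      lda_membership(sc, sample(groups))$assign_hard, numeric(1))
    data.frame(m = m, observed = obs, random_mean = mean(rnd),
               a_score = obs - mean(rnd))
  })
  curve <- do.call(rbind, rows)
  best_m <- curve$m[which.max(curve$a_score)]  # which.max takes the first tie
  list(best_m = best_m, curve = curve)
}

#' Permutation significance of DAPC clustering
#'
#' Randomly reassigns individuals to the pre-designated populations (group
#' sizes preserved), refits the discriminant analysis on the same retained
#' PCs, and records the mean correct-assignment probability. `p` is the
#' fraction of permuted values at or above the observed one.
#'
#' @param fit a [dapc_fit()] object.
#' @param n_reps permutation replicates (>= 1).
#' @param seed integer seed.
#' @return list with `observed`, `p`, `null` (permuted values).
#' @export
cluster_significance <- function(fit, n_reps = 10000, seed = 1L) {
  stopifnot(inherits(fit, "dapc_fit"))
  if (n_reps < 1) stopf("n_reps must be >= 1")
  set.seed(seed)
  null <- vapply(seq_len(n_reps), function(i)
    lda_membership(fit$pc_scores, sample(fit$groups))$assign_mean,
    numeric(1))
  list(observed = fit$assign_mean, p = mean(null >= fit$assign_mean),
       null = null)
}

#' Geographic and ecological predictor matrices for Mantel tests
#'
#' Geographic distance between populations is the absolute difference of
#' their latitudinal site orders; ecological (host) distance is 0 for the
#' same host and 1 for different hosts.
#'
#' @param pops data frame with columns `pop`, `site_order`, `host`.
#' @return list with matrices `geo` and `host`.
#' @export
build_predictor_matrices <- function(pops) {
  if (anyNA(pops$site_order)) stopf("site_order is missing for a population")
  geo <- abs(outer(pops$site_order, pops$site_order, `-`))
  host <- 1 * outer(pops$host, pops$host, `!=`)
  dimnames(geo) <- dimnames(host) <- list(pops$pop, pops$pop)
  list(geo = geo, host = host)
}

#' Mantel permutation test
#'
#' Pearson correlation of the upper-triangle entries of a genetic distance
#' matrix with a predictor distance matrix; significance by jointly permuting
#' rows and columns of the genetic matrix. One-tailed: `p` is the fraction of
#' permuted correlations at or above the observed one.
#'
#' @param gen symmetric genetic distance matrix.
#' @param pred symmetric predictor matrix in matching label order.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(gen, pred, n_perm = 10000, seed = 1L) {
  stopifnot(identical(dim(gen), dim(pred)))
  if (nrow(gen) < 4) stopf("at least 4 populations are required")
  ut <- upper.tri(gen)
  if (stats::sd(pred[ut]) == 0) stopf("constant predictor matrix")
  set.seed(seed)
  r_obs <- stats::cor(gen[ut], pred[ut])
  n <- nrow(gen)
  r_null <- vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(n)
    stats::cor(gen[ix, ix][ut], pred[ut])
  }, numeric(1))
  list(r = r_obs, p = mean(r_null >= r_obs), n_perm = n_perm)
}
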