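#' Burrows composite linkage disequilibrium between two loci
#'
#' The composite disequilibrium estimable from unphased genotypes:
#' \deqn{\hat\Delta = \frac{1}{2n}\sum_i X_i Y_i - 2 \hat p_A \hat p_B,}
#' i.e., half the (population-normalized) covariance of allele dosages, and
#' the composite correlation
#' \deqn{\hat r = \hat\Delta / \sqrt{(\hat p_A \hat q_A + \hat D_A)
#'   (\hat p_B \hat q_B + \hat D_B)},}
#' whose denominator terms equal half the dosage variances (\eqn{\hat D_A}
#' is the within-locus Hardy-Weinberg disequilibrium), so \eqn{\hat r} is the
#' dosage Pearson correlation. Computed over individuals with both entries
#' non-missing; requires at least two such individuals and both loci
#' polymorphic (else `NA` with a `reason`).
#'
#' @param x,y numeric dosage vectors (hard 0/1/2 calls or posterior means).
#' @return list with `delta`, `r`, `r2`, `n`, and `reason` when undefined.
#' @export
composite_ld <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2) return(list(delta = NA_real_, r = NA_real_, r2 = NA_real_,
                         n = n, reason = "fewer than 2 complete pairs"))
  x <- x[ok]; y <- y[ok]
  vx <- mean(x^2) - mean(x)^2
  vy <- mean(y^2) - mean(y)^2
  if (vx == 0 || vy == 0)
    return(list(delta = NA_real_, r = NA_real_, r2 = NA_real_, n = n,
                reason = "monomorphic locus"))
  delta <- mean(x * y) / 2 - 2 * (mean(x) / 2) * (mean(y) / 2)
  r <- 2 * delta / sqrt(vx * vy)
  list(delta = delta, r = r, r2 = r^2, n = n, reason = NA_character_)
}

#' All-pairs composite LD for a dosage matrix
#'
#' Pairwise-complete version of [composite_ld()] over the columns of a
#' dosage matrix, computed with matrix products so thousands of loci are
#' feasible. Population (not n-1) normalization throughout.
#'
#' @param D numeric matrix (individuals x SNPs), `NA` = missing.
#' @return list of symmetric matrices `delta`, `r`, `r2`, `n`.
#' @export
composite_ld_matrix <- function(D) {
  M <- !is.na(D)
  X <- D; X[!M] <- 0
  Mn <- 1 * M
  n <- crossprod(Mn)
  Sxy <- crossprod(X)
  Sx <- crossprod(X, Mn)     # sum of x over pairwise-complete entries
  Sxx <- crossprod(X^2, Mn)
  mx <- Sx / n
  cov <- Sxy / n - mx * t(mx)
  vx <- Sxx / n - mx^2       # var of column i over entries complete with j
  bad <- n < 2 | vx <= 0 | t(vx) <= 0
  delta <- cov / 2
  r <- cov / sqrt(vx * t(vx))
  delta[bad] <- NA_real_
  r[bad] <- NA_real_
  diag(delta) <- NA_real_
  diag(r) <- NA_real_
  dimnames(delta) <- dimnames(r) <- dimnames(n) <- dimnames(D)[c(2, 2)]
  list(delta = delta, r = r, r2 = r^2, n = n)
}

#' Classify SNPs into high / intermediate / low LD classes
#'
#' Threshold-graph reading of LD network analysis: a SNP is `high` iff its
#' maximum composite r-squared with another SNP on the same chromosome
#' strictly exceeds `high` (default 0.6); `low` iff that maximum is strictly
#' below `low` (default 0.15); otherwise `intermediate`. High-class SNPs are
#' additionally grouped into connected components of the `> high` graph.
#' A SNP alone on its chromosome is `low` (the "below threshold with any
#' other SNP" condition holds vacuously); a SNP whose pairwise values are all
#' `NA` is `unassigned`.
#'
#' @param r2 square symmetric matrix of composite r-squared values for the
#'   SNPs of one chromosome (diagonal ignored), with dimnames.
#' @param high,low class thresholds.
#' @return data frame `snp_id`, `ld_class`, `max_r2`, `component`.
#' @export
classify_ld_network <- function(r2, high = 0.6, low = 0.15) {
  stopifnot(nrow(r2) == ncol(r2))
  S <- nrow(r2)
  diag(r2) <- NA_real_
  max_r2 <- suppressWarnings(apply(r2, 1, max, na.rm = TRUE))
  max_r2[!is.finite(max_r2)] <- NA_real_
  cls <- rep("intermediate", S)
  cls[!is.na(max_r2) & max_r2 > high] <- "high"
  cls[!is.na(max_r2) & max_r2 < low] <- "low"
  cls[is.na(max_r2)] <- if (S == 1) "low" else "unassigned"
  comp <- rep(NA_integer_, S)
  hi <- which(cls == "high")
  if (length(hi)) {
    adj <- r2[hi, hi, drop = FALSE] > high
    adj[is.na(adj)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp[hi] <- igraph::components(g)$membership
  }
  data.frame(snp_id = rownames(r2) %||% as.character(seq_len(S)),
             ld_class = cls, max_r2 = max_r2, component = comp,
             stringsAsFactors = FALSE)
}

#' Assign LD classes to all mapped SNPs of a dataset
#'
#' Computes the within-chromosome composite r-squared matrices from a dosage
#' matrix and applies [classify_ld_network()] per chromosome. Unmapped SNPs
#' are `unassigned`.
#'
#' @param D dosage matrix (individuals x SNPs).
#' @param snp_map data frame with `snp_id` and `chrom` (characters `1`-`5`
#'   or `unmapped`).
#' @param high,low thresholds passed through.
#' @return data frame `snp_id`, `chrom`, `ld_class`, `max_r2`, `component`.
#' @export
assign_ld_classes <- function(D, snp_map, high = 0.6, low = 0.15) {
  stopifnot(identical(colnames(D), snp_map$snp_id))
  out <- data.frame(snp_id = snp_map$snp_id, chrom = snp_map$chrom,
                    ld_class = "unassigned", max_r2 = NA_real_,
                    component = NA_integer_, stringsAsFactors = FALSE)
  for (ch in setdiff(unique(snp_map$chrom), "unmapped")) {
    ix <- which(snp_map$chrom == ch)
    cl <- composite_ld_matrix(D[, ix, drop = FALSE])
    res <- classify_ld_network(cl$r2, high = high, low = low)
    out$ld_class[ix] <- res$ld_class
    out$max_r2[ix] <- res$max_r2
    out$component[ix] <- res$component
  }
  out
}

#' Mean LD of each SNP to all other loci on its chromosome
#'
#' Per mapped SNP, the mean composite r-squared to every other SNP on the
#' same chromosome (`NA` pairs excluded). Used as the "LD" covariate of the
#' multiple-regression models. A SNP alone on its chromosome, or unmapped,
#' is `NA`.
#'
#' @param D dosage matrix (individuals x SNPs).
#' @param snp_map data frame with `snp_id`, `chrom`.
#' @param stat `"r2"` (default) or `"abs_r"`.
#' @return named numeric vector over all SNPs.
#' @export
mean_linked_ld <- function(D, snp_map, stat = c("r2", "abs_r")) {
  stat <- match.arg(stat)
  stopifnot(identical(colnames(D), snp_map$snp_id))
  out <- rep(NA_real_, nrow(snp_map))
  names(out) <- snp_map$snp_id
  for (ch in setdiff(unique(snp_map$chrom), "unmapped")) {
    ix <- which(snp_map$chrom == ch)
    if (length(ix) < 2) next
    cl <- composite_ld_matrix(D[, ix, drop = FALSE])
    vals <- if (stat == "r2") cl$r2 else abs(cl$r)
    out[ix] <- rowMeans(vals, na.rm = TRUE)
    out[ix][rowSums(!is.na(vals)) == 0] <- NA_real_
  }
  out
}

#' Select SNPs under strong diapause-related selection
#'
#' Keeps SNPs that are significant in at least one of the three diapause
#' studies (eclosion GWAS, apple prewinter, hawthorn prewinter) and whose
#' absolute allele frequency difference reaches `min_diff` in at least one of
#' them.
#'
#' @param results named list of three data frames, each with `snp_id`,
#'   `significant` (logical) and `dp` (signed difference).
#' @param min_diff minimum absolute frequency difference (default 0.2).
#' @return character vector of retained SNP ids.
#' @export
select_strong_diapause_snps <- function(results, min_diff = 0.2) {
  if (length(results) < 1) stopf("study results are missing")
  ids <- results[[1]]$snp_id
  for (r in results) {
    if (!all(c("snp_id", "significant", "dp") %in% names(r)))
      stopf("each study result needs snp_id, significant, dp")
    if (!identical(r$snp_id, ids)) stopf("study results must share SNP ids")
  }
  sig <- Reduce(`|`, lapply(results, function(r) r$significant %in% TRUE))
  big <- Reduce(`|`, lapply(results, function(r)
    !is.na(r$dp) & abs(r$dp) >= min_diff))
  ids[sig & big]
}

#' Interchromosomal composite LD distributions
#'
#' For a set of SNPs spanning at least two chromosomes, computes composite LD
#' for every SNP pair on different chromosomes within each supplied sample
#' group (a population or a pool of populations), then averages per pair
#' across groups. Pools are built by the caller simply by concatenating
#' sample groups (see `pool` argument of [run_pipeline()] stages).
#'
#' @param dosage_list named list of dosage matrices (individuals x SNPs, all
#'   sharing columns); each element is one population or pool.
#' @param snp_map data frame with `snp_id`, `chrom`.
#' @param snp_ids SNPs to analyze (mapped, >= 2 chromosomes).
#' @return list with `pairs` (data frame: snp_i, snp_j, chrom_i, chrom_j,
#'   per-group delta/r means as `delta`, `r`) and `summary` (mean, sd,
#'   quantiles of the per-pair mean delta and r).
#' @export
interchromosomal_ld <- function(dosage_list, snp_map, snp_ids) {
  keep <- snp_map$snp_id %in% snp_ids & snp_map$chrom != "unmapped"
  map <- snp_map[keep, , drop = FALSE]
  if (length(unique(map$chrom)) < 2)
    stopf("SNP set must span at least two chromosomes")
  ix <- match(map$snp_id, colnames(dosage_list[[1]]))
  inter <- outer(map$chrom, map$chrom, `!=`) & upper.tri(diag(nrow(map)))
  pair_idx <- which(inter, arr.ind = TRUE)
  if (!nrow(pair_idx)) stopf("empty interchromosomal pair set")

  delta_acc <- r_acc <- matrix(0, nrow(pair_idx), length(dosage_list))
  for (g in seq_along(dosage_list)) {
    cl <- composite_ld_matrix(dosage_list[[g]][, ix, drop = FALSE])
    delta_acc[, g] <- cl$delta[pair_idx]
    r_acc[, g] <- cl$r[pair_idx]
  }
  pairs <- data.frame(
    snp_i = map$snp_id[pair_idx[, 1]], snp_j = map$snp_id[pair_idx[, 2]],
    chrom_i = map$chrom[pair_idx[, 1]], chrom_j = map$chrom[pair_idx[, 2]],
    delta = rowMeans(delta_acc, na.rm = TRUE),
    r = rowMeans(r_acc, na.rm = TRUE), stringsAsFactors = FALSE)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  summ <- list(
    n_pairs = nrow(pairs),
    delta_mean = mean(pairs$delta, na.rm = TRUE),
    delta_sd = stats::sd(pairs$delta, na.rm = TRUE),
    delta_quantiles = stats::quantile(pairs$delta, qs, na.rm = TRUE,
                                      names = TRUE),
    r_mean = mean(pairs$r, na.rm = TRUE),
    r_quantiles = stats::quantile(pairs$r, qs, na.rm = TRUE, names = TRUE))
  list(pairs = pairs, summary = summ)
}
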