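# Whole-genotype Monte Carlo resampling tests. Null distributions are built
# by drawing whole individuals (keeping their multi-locus genotypes and
# missingness patterns intact, which preserves LD) with replacement from the
# pool of the two samples under test. Per-individual genotype posteriors are
# computed once from the pooled sample; replicate allele frequencies are
# posterior-dosage means over the resampled individuals.

# Multiplicity matrix of `nc` bootstrap draws of `size` individuals from a
# pool of `n_pool` (columns are replicates).
count_matrix <- function(n_pool, size, nc) {
  idx <- sample.int(n_pool, size * nc, replace = TRUE)
  off <- rep(seq_len(nc) - 1L, each = size) * n_pool
  matrix(tabulate(idx + off, nbins = n_pool * nc), n_pool, nc)
}

# Replicate group frequencies: SNPs x nc matrix. Dz is the pooled posterior
# dosage matrix with NA as 0, Mn the 0/1 non-missing indicator.
resample_freqs <- function(Dz, Mn, size, nc) {
  W <- count_matrix(nrow(Dz), size, nc)
  num <- crossprod(Dz, W)
  den <- 2 * crossprod(Mn, W)
  p <- num / den
  p[den == 0] <- NA_real_
  p
}

#' Monte Carlo test of per-SNP allele frequency differences
#'
#' Tests every SNP for an allele frequency difference between two sample
#' groups against a null built by resampling whole individuals with
#' replacement from the pooled groups (sample sizes preserved). Per
#' replicate, group frequencies are recomputed and `|dp|` recorded; a SNP is
#' significant iff its observed `|dp|` strictly exceeds the `1 - alpha`
#' quantile (linear interpolation) of its own null draws. Per-SNP null
#' quantiles require at least 100 available draws. Observed and replicate
#' frequencies are both posterior-dosage means under the pooled-sample EM
#' frequency estimates, so observed and null statistics are exchangeable
#' under the null.
#'
#' @param gl a [gl_data()] object.
#' @param group1,group2 disjoint, non-empty sample-id vectors.
#' @param n_reps number of Monte Carlo replicates (>= 1).
#' @param alpha per-SNP test level (two-sided via `|dp|`).
#' @param seed integer seed.
#' @param retain_null keep the SNPs x reps null matrix (needed by
#'   [tablewise_excess_test()], which is run automatically; set `FALSE` to
#'   save memory afterwards).
#' @param chunk replicates per internal block.
#' @return object of class `mc_test`: `result` (snp_id, obs_dp, obs_abs,
#'   crit, significant), `tablewise` (observed %, 95th null quantile of
#'   replicate percentages, excess flag, p), and metadata.
#' @export
mc_difference_test <- function(gl, group1, group2, n_reps = 10000,
                               alpha = 0.05, seed = 1L, retain_null = TRUE,
                               chunk = 2000L) {
  if (n_reps < 1) stopf("n_reps must be >= 1")
  if (!length(group1) || !length(group2)) stopf("groups must be non-empty")
  if (length(intersect(group1, group2))) stopf("groups must be disjoint")
  set.seed(seed)

  pool <- c(group1, group2)
  glp <- gl_subset(gl, pool)
  freqs <- estimate_allele_freq(glp)
  Dpost <- posterior_dosages(glp, freqs)
  Mn <- 1 * !is.na(Dpost)
  Dz <- Dpost; Dz[Mn == 0] <- 0
  n1 <- length(group1); n2 <- length(group2)

  grp_freq <- function(rows) {
    den <- 2 * colSums(Mn[rows, , drop = FALSE])
    p <- colSums(Dz[rows, , drop = FALSE]) / den
    p[den == 0] <- NA_real_
    p
  }
  obs_dp <- grp_freq(seq_len(n1)) - grp_freq(n1 + seq_len(n2))
  obs_abs <- abs(obs_dp)

  S <- length(gl$snps)
  null_abs <- matrix(NA_real_, S, n_reps)
  done <- 0L
  while (done < n_reps) {
    nc <- min(chunk, n_reps - done)
    p1 <- resample_freqs(Dz, Mn, n1, nc)
    p2 <- resample_freqs(Dz, Mn, n2, nc)
    null_abs[, done + seq_len(nc)] <- abs(p1 - p2)
    done <- done + nc
  }

  crit <- col_quantile(t(null_abs), 1 - alpha, min_n = min(100L, n_reps))
  significant <- ifelse(is.na(crit) | is.na(obs_abs), NA, obs_abs > crit)
  result <- data.frame(snp_id = gl$snps, obs_dp = obs_dp, obs_abs = obs_abs,
                       crit = crit, significant = significant,
                       stringsAsFactors = FALSE)
  fit <- structure(list(result = result, null_abs = null_abs,
                        alpha = alpha, n_reps = n_reps, seed = seed,
                        groups = list(group1 = group1, group2 = group2)),
                   class = "mc_test")
  fit$tablewise <- tablewise_excess_test(fit)
  if (!retain_null) fit$null_abs <- NULL
  fit
}

#' Table-wise excess of significant SNPs
#'
#' Asks whether the overall percentage of significant SNPs exceeds chance:
#' per replicate, the percentage of SNPs whose null `|dp|` draw exceeds their
#' own critical value is computed; the observed percentage is deemed in
#' excess iff it strictly exceeds the 95th quantile of the replicate
#' percentages, and `p` is the fraction of replicate percentages at or above
#' the observed one.
#'
#' @param fit an `mc_test` with retained null draws.
#' @return list with `pct_sig`, `null_pct_95`, `excess`, `p`,
#'   `null_pct` (replicate percentages).
#' @export
tablewise_excess_test <- function(fit) {
  stopifnot(inherits(fit, "mc_test"))
  if (is.null(fit$null_abs)) stopf("per-SNP null draws were not retained")
  res <- fit$result
  use <- !is.na(res$crit) & !is.na(res$obs_abs)
  if (!any(use)) stopf("no testable SNPs")
  exceed <- fit$null_abs[use, , drop = FALSE] >
    res$crit[use]
  null_pct <- 100 * colMeans(exceed, na.rm = TRUE)
  pct_sig <- 100 * mean(res$significant[use])
  q95 <- stats::quantile(null_pct, 0.95, names = FALSE, type = 7)
  list(pct_sig = pct_sig, null_pct_95 = q95, excess = pct_sig > q95,
       p = mean(null_pct >= pct_sig), null_pct = null_pct)
}

#' @export
print.mc_test <- function(x, ...) {
  n_sig <- sum(x$result$significant, na.rm = TRUE)
  cat(sprintf(
    "Monte Carlo difference test: %d/%d SNPs significant (%.1f%%), table-wise p = %.4g (%d reps)\n",
    n_sig, nrow(x$result), x$tablewise$pct_sig, x$tablewise$p, x$n_reps))
  invisible(x)
}

#' Monte Carlo significance for a cross-experiment regression
#'
#' Regresses the observed per-SNP frequency difference of a response contrast
#' on a fixed per-SNP predictor vector, and assesses the r-squared against a
#' null in which the response contrast is rebuilt from whole individuals
#' resampled with replacement from the pooled contrast groups (the predictor,
#' which comes from an independent experiment, is held fixed). `p` is the
#' fraction of null r-squared values at or above the observed one.
#'
#' @param gl a [gl_data()] object holding the response contrast samples.
#' @param group1,group2 the response contrast groups.
#' @param predictor numeric per-SNP vector aligned with `gl$snps`.
#' @param n_reps Monte Carlo replicates.
#' @param seed integer seed.
#' @param chunk replicates per internal block.
#' @return list with `r`, `r2`, `p`, `n_snps`, `n_reps`, `seed`.
#' @export
mc_regression_significance <- function(gl, group1, group2, predictor,
                                       n_reps = 10000, seed = 1L,
                                       chunk = 2000L) {
  if (n_reps < 1) stopf("n_reps must be >= 1")
  stopifnot(length(predictor) == length(gl$snps))
  set.seed(seed)
  pool <- c(group1, group2)
  glp <- gl_subset(gl, pool)
  freqs <- estimate_allele_freq(glp)
  Dpost <- posterior_dosages(glp, freqs)
  Mn <- 1 * !is.na(Dpost)
  Dz <- Dpost; Dz[Mn == 0] <- 0
  n1 <- length(group1); n2 <- length(group2)

  den1 <- 2 * colSums(Mn[seq_len(n1), , drop = FALSE])
  den2 <- 2 * colSums(Mn[n1 + seq_len(n2), , drop = FALSE])
  p1 <- colSums(Dz[seq_len(n1), , drop = FALSE]) / ifelse(den1 == 0, NA, den1)
  p2 <- colSums(Dz[n1 + seq_len(n2), , drop = FALSE]) / ifelse(den2 == 0, NA, den2)
  dp <- p1 - p2
  ok <- !is.na(dp) & !is.na(predictor)
  if (sum(ok) < 3) stopf("fewer than 3 SNPs with complete data")
  r_obs <- stats::cor(predictor[ok], dp[ok])
  r2_obs <- r_obs^2

  r2_null <- numeric(n_reps)
  done <- 0L
  while (done < n_reps) {
    nc <- min(chunk, n_reps - done)
    dpn <- resample_freqs(Dz, Mn, n1, nc) - resample_freqs(Dz, Mn, n2, nc)
    rs <- suppressWarnings(
      stats::cor(predictor, dpn, use = "pairwise.complete.obs"))
    r2_null[done + seq_len(nc)] <- as.numeric(rs)^2
    done <- done + nc
  }
  list(r = r_obs, r2 = r2_obs, p = mean(r2_null >= r2_obs, na.rm = TRUE),
       n_snps = sum(ok), n_reps = n_reps, seed = seed)
}
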