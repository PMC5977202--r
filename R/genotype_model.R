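#' Genotype-likelihood container
#'
#' Holds per-individual, per-SNP likelihoods for the three diploid genotypes
#' (0, 1, 2 copies of the alternate allele). Likelihoods are stored on the
#' linear scale, normalized per entry so the maximum is 1; an entry missing
#' in all three matrices is a missing genotype (zero informative reads).
#'
#' @param L0,L1,L2 numeric matrices (individuals x SNPs) of likelihoods for
#'   genotypes 0, 1, 2.
#' @param samples,snps identifiers; must match the matrix dimensions.
#' @return an object of class `gl_data`.
#' @export
gl_data <- function(L0, L1, L2, samples = rownames(L0), snps = colnames(L0)) {
  dims <- dim(L0)
  if (!identical(dim(L1), dims) || !identical(dim(L2), dims))
    stopf("likelihood matrices must share dimensions")
  if (is.null(samples) || is.null(snps))
    stopf("sample and SNP identifiers are required")
  if (anyDuplicated(samples)) stopf("duplicate sample id")
  L <- list(L0, L1, L2)
  mx <- pmax(L0, L1, L2)
  obs <- !is.na(mx)
  if (any(mx[obs] <= 0) || any(!is.finite(mx[obs])))
    stopf("likelihoods must be non-negative, finite, and not all zero")
  for (g in 1:3) {
    L[[g]] <- L[[g]] / mx
    dimnames(L[[g]]) <- list(samples, snps)
  }
  structure(list(L0 = L[[1]], L1 = L[[2]], L2 = L[[3]],
                 samples = samples, snps = snps),
            class = "gl_data")
}

#' @export
print.gl_data <- function(x, ...) {
  miss <- mean(is.na(x$L0)) * 100
  cat(sprintf("gl_data: %d samples x %d SNPs (%.1f%% missing)\n",
              length(x$samples), length(x$snps), miss))
  invisible(x)
}

#' @export
dim.gl_data <- function(x) c(length(x$samples), length(x$snps))

# Row-subset a gl_data by sample ids (internal).
gl_subset <- function(gl, samples) {
  ix <- match(samples, gl$samples)
  if (anyNA(ix)) stopf("unknown sample id: %s", samples[which(is.na(ix))[1]])
  gl_data(gl$L0[ix, , drop = FALSE], gl$L1[ix, , drop = FALSE],
          gl$L2[ix, , drop = FALSE], samples = samples, snps = gl$snps)
}

#' Read a genotype-likelihood dataset from VCF + metadata + SNP map
#'
#' Parses a VCF 4.2 of biallelic SNPs carrying GL (log10 likelihoods) or PL
#' (phred-scaled) FORMAT fields, aligns it with a sample metadata table and a
#' SNP map table, and returns the three matched objects. Samples present in
#' the VCF but absent from the metadata are an error; SNPs absent from the
#' map are marked `unmapped`/`unassigned`.
#'
#' @param vcf_path path to the VCF (plain text or gzipped).
#' @param metadata_path TSV with columns `sample_id`, `host`, `site`,
#'   `site_order`, `group`.
#' @param snpmap_path TSV with columns `snp_id`, `chrom`, `pos` and
#'   optionally an LD-class column.
#' @return list with `gl` ([gl_data()]), `metadata`, `snp_map`.
#' @export
read_genotype_data <- function(vcf_path, metadata_path, snpmap_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (any(grepl(",", vcf@fix[, "ALT"], fixed = TRUE)))
    stopf("multi-allelic record in %s", vcf_path)
  fmt <- vcf@gt[, "FORMAT"]
  use_gl <- all(grepl("(^|:)GL(:|$)", fmt))
  use_pl <- all(grepl("(^|:)PL(:|$)", fmt))
  if (!use_gl && !use_pl) stopf("VCF carries neither GL nor PL FORMAT fields")
  field <- if (use_gl) "GL" else "PL"
  raw <- vcfR::extract.gt(vcf, element = field)  # SNPs x samples, strings
  samples <- colnames(raw)
  snps <- vcf@fix[, "ID"]
  if (anyDuplicated(samples)) stopf("duplicate sample id in VCF")

  parse_tri <- function(s) {
    out <- matrix(NA_real_, length(s), 3)
    ok <- !is.na(s) & s != "." & s != ".,.,."
    if (any(ok)) {
      sp <- strsplit(s[ok], ",", fixed = TRUE)
      out[ok, ] <- matrix(as.numeric(unlist(sp)), ncol = 3, byrow = TRUE)
    }
    out
  }
  n <- length(samples); S <- length(snps)
  L <- lapply(1:3, function(g) matrix(NA_real_, n, S))
  for (j in seq_len(S)) {
    tri <- parse_tri(raw[j, ])
    lik <- if (use_gl) 10^tri else 10^(-tri / 10)
    for (g in 1:3) L[[g]][, j] <- lik[, g]
  }
  gl <- gl_data(L[[1]], L[[2]], L[[3]], samples = samples, snps = snps)

  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (anyDuplicated(metadata$sample_id)) stopf("duplicate sample id in metadata")
  absent <- setdiff(samples, metadata$sample_id)
  if (length(absent))
    stopf("VCF sample missing from metadata: %s", absent[1])
  metadata <- metadata[match(samples, metadata$sample_id), ]

  snp_map <- utils::read.delim(snpmap_path, stringsAsFactors = FALSE)
  if (anyDuplicated(snp_map$snp_id)) stopf("duplicate snp id in SNP map")
  mi <- match(snps, snp_map$snp_id)
  snp_map <- data.frame(
    snp_id = snps,
    chrom = ifelse(is.na(mi), "unmapped", as.character(snp_map$chrom[mi])),
    pos = ifelse(is.na(mi), NA_integer_, snp_map$pos[mi]),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(utils::read.delim(snpmap_path, nrows = 1)),
                   c("snp_id", "chrom", "pos"))
  if (length(extra)) {
    full <- utils::read.delim(snpmap_path, stringsAsFactors = FALSE)
    for (cn in extra) snp_map[[cn]] <- full[[cn]][mi]
  }
  list(gl = gl, metadata = metadata, snp_map = snp_map)
}

# Informative entries: non-missing and not flat across the three genotypes.
gl_informative <- function(gl) {
  !is.na(gl$L0) & !(gl$L0 == gl$L1 & gl$L1 == gl$L2)
}

#' EM estimate of allele frequencies from genotype likelihoods
#'
#' Maximum-likelihood allele frequency under a Hardy-Weinberg prior,
#' estimated by EM jointly for all SNPs: posterior weights
#' \eqn{w_i(g) \propto L_i(g) \, \mathrm{HWE}(g \mid p)} and update
#' \eqn{p \leftarrow \sum_i \sum_g g \, w_i(g) / (2 n)}, iterated until the
#' largest per-SNP change falls below `tol` or `max_iter` is reached.
#' Frequencies are computed over informative individuals only (non-missing,
#' non-flat likelihoods); a SNP with no informative individuals is `NA`.
#' With certain likelihoods the estimate equals the allele-count estimator
#' exactly.
#'
#' @param gl a [gl_data()] object.
#' @param samples optional sample-id subset.
#' @param tol convergence tolerance on `|dp|` (default `1e-6`).
#' @param max_iter maximum EM iterations (default 100).
#' @return data frame with `snp_id`, `p_hat`, `n_eff` plus attribute
#'   `iterations`.
#' @export
estimate_allele_freq <- function(gl, samples = NULL, tol = 1e-6,
                                 max_iter = 100) {
  if (!is.null(samples)) gl <- gl_subset(gl, samples)
  inf <- gl_informative(gl)
  L0 <- ifelse(inf, gl$L0, NA_real_)
  L1 <- ifelse(inf, gl$L1, NA_real_)
  L2 <- ifelse(inf, gl$L2, NA_real_)
  n_eff <- colSums(inf)
  S <- length(gl$snps)
  p <- rep(0.5, S)
  active <- n_eff > 0
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pr0 <- (1 - p)^2; pr1 <- 2 * p * (1 - p); pr2 <- p^2
    w0 <- sweep(L0, 2, pr0, `*`)
    w1 <- sweep(L1, 2, pr1, `*`)
    w2 <- sweep(L2, 2, pr2, `*`)
    den <- w0 + w1 + w2
    dose <- (w1 + 2 * w2) / den
    p_new <- colSums(dose, na.rm = TRUE) / (2 * pmax(n_eff, 1))
    p_new[!active] <- p[!active]
    delta <- max(abs(p_new - p)[active], 0)
    p <- p_new
    if (delta < tol) break
  }
  p[!active] <- NA_real_
  out <- data.frame(snp_id = gl$snps, p_hat = p, n_eff = n_eff,
                    stringsAsFactors = FALSE)
  attr(out, "iterations") <- iter
  out
}

#' Observed-data log-likelihood of allele frequencies
#'
#' \eqn{\ell(p) = \sum_i \log \sum_g L_i(g)\,\mathrm{HWE}(g \mid p)} summed
#' over informative individuals, per SNP. Used to verify EM monotonicity.
#'
#' @param gl a [gl_data()] object.
#' @param p per-SNP frequency vector.
#' @return numeric vector of per-SNP log-likelihoods.
#' @export
gl_loglik <- function(gl, p) {
  inf <- gl_informative(gl)
  pr0 <- (1 - p)^2; pr1 <- 2 * p * (1 - p); pr2 <- p^2
  mix <- sweep(ifelse(inf, gl$L0, NA), 2, pr0, `*`) +
    sweep(ifelse(inf, gl$L1, NA), 2, pr1, `*`) +
    sweep(ifelse(inf, gl$L2, NA), 2, pr2, `*`)
  colSums(log(mix), na.rm = TRUE)
}

#' Posterior mean genotype dosages
#'
#' Expected alternate-allele dosage per entry under the HWE prior at the
#' supplied frequencies: \eqn{\sum_g g \, P(g \mid L, p)}. Missing entries
#' stay missing; flat-likelihood entries fall back to the prior mean `2p`.
#'
#' @param gl a [gl_data()] object.
#' @param p per-SNP allele frequencies (e.g., from
#'   [estimate_allele_freq()]); SNPs with `NA` frequency yield `NA` dosages.
#' @return numeric matrix (individuals x SNPs).
#' @export
posterior_dosages <- function(gl, p) {
  if (is.data.frame(p)) p <- p$p_hat
  stopifnot(length(p) == length(gl$snps))
  pr0 <- (1 - p)^2; pr1 <- 2 * p * (1 - p); pr2 <- p^2
  w0 <- sweep(gl$L0, 2, pr0, `*`)
  w1 <- sweep(gl$L1, 2, pr1, `*`)
  w2 <- sweep(gl$L2, 2, pr2, `*`)
  D <- (w1 + 2 * w2) / (w0 + w1 + w2)
  dimnames(D) <- list(gl$samples, gl$snps)
  D
}

#' Allele-frequency difference between two sample groups
#'
#' Per-SNP signed difference `p(group1) - p(group2)`, with frequencies
#' estimated independently in each group by [estimate_allele_freq()].
#' Antisymmetric under group swap; `NA` propagates from either group.
#'
#' @param gl a [gl_data()] object.
#' @param group1,group2 disjoint, non-empty sample-id vectors.
#' @param orientation free-text note recording what `group1 - group2` means.
#' @return data frame `snp_id`, `dp`, `p1`, `p2`, `n1`, `n2` with attribute
#'   `orientation`.
#' @export
frequency_difference <- function(gl, group1, group2,
                                 orientation = "group1 - group2") {
  if (!length(group1) || !length(group2)) stopf("groups must be non-empty")
  if (length(intersect(group1, group2))) stopf("groups must be disjoint")
  f1 <- estimate_allele_freq(gl, group1)
  f2 <- estimate_allele_freq(gl, group2)
  out <- data.frame(snp_id = gl$snps, dp = f1$p_hat - f2$p_hat,
                    p1 = f1$p_hat, p2 = f2$p_hat,
                    n1 = f1$n_eff, n2 = f2$n_eff, stringsAsFactors = FALSE)
  attr(out, "orientation") <- orientation
  out
}

#' Polarize frequencies to a reference population's major allele
#'
#' Re-signs a SNPs-by-populations frequency matrix so that the counted allele
#' at every SNP is the one more common in the reference population (frequency
#' exactly 0.5 is left unflipped). Applying the operation twice equals
#' applying it once.
#'
#' @param freqs numeric matrix (SNPs x populations) with column names.
#' @param reference reference population column name.
#' @return matrix of the same shape with attribute `flipped` (logical per
#'   SNP).
#' @export
polarize_to_reference <- function(freqs, reference) {
  if (!reference %in% colnames(freqs)) stopf("unknown reference population")
  flip <- !is.na(freqs[, reference]) & freqs[, reference] < 0.5
  out <- freqs
  out[flip, ] <- 1 - out[flip, ]
  attr(out, "flipped") <- flip
  out
}

#' Apply a polarization flip set to signed difference vectors
#'
#' @param dp numeric vector (or matrix) of per-SNP differences.
#' @param flip logical per-SNP flip set from [polarize_to_reference()].
#' @return re-signed values.
#' @export
polarize_differences <- function(dp, flip) {
  sgn <- ifelse(flip, -1, 1)
  if (is.matrix(dp)) dp * sgn else dp * sgn
}
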