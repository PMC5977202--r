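#' Configuration for the synthetic GBS cline simulator
#'
#' Builds the full parameterization of a synthetic reduced-representation
#' (GBS/ddRAD) study of two host races sampled at latitudinally ordered
#' sympatric sites. The simulated architecture has three ingredients:
#'
#' 1. **Clines.** Each SNP's true alternate-allele frequency in the population
#'    at site order \eqn{s} and host \eqn{h} is
#'    \eqn{\mathrm{logistic}(\alpha + \beta s + \gamma [h = \mathrm{apple}])}.
#'    Geography is an ordered 4-level transect, so the cline is logistic in
#'    site order rather than in kilometres.
#' 2. **Inversion-like LD blocks.** Each block has a single biallelic latent
#'    orientation whose frequency follows its own cline; member SNP alleles
#'    match the latent orientation per haplotype with probability \eqn{1 - m}.
#'    Small \eqn{m} produces tightly linked ("high LD") SNPs, larger \eqn{m}
#'    intermediate LD, and non-block SNPs are unlinked ("low LD").
#' 3. **Experiment responses.** Designated SNP sets carry planned allele
#'    frequency shifts \eqn{\delta} between the two groups of each paired
#'    experiment (early vs late eclosion; 7-day vs 32-day prewinter survivors
#'    in each race), applied as \eqn{\pm\delta/2} around the base population
#'    frequency (at block level for block SNPs, so within-block LD is
#'    preserved).
#'
#' @param n_sites number of latitudinally ordered sympatric sites.
#' @param hosts two host labels; the second is the ancestral reference host.
#' @param n_per_pop individuals sampled per host-by-site population.
#' @param n_snps total biallelic SNPs (mapped + unmapped).
#' @param mapped_fraction share of SNPs mapped to chromosomes 1-5.
#' @param chrom_weights relative sizes of the five chromosomes.
#' @param block_high,block_int fraction of each chromosome's SNPs belonging to
#'   its high-LD and intermediate-LD block.
#' @param m_high,m_int per-haplotype mismatch probability between a block
#'   SNP's allele and the latent inversion orientation, for high and
#'   intermediate blocks. Must lie in `[0, 0.5]`.
#' @param beta_block latitudinal slope (logit scale, per site-order step) of
#'   block latent orientations.
#' @param gamma_block host effect (logit scale) of block latent orientations.
#'   The default geographic span (3 steps x `beta_block`) is ~2.4x the host
#'   effect, emulating geographic divergence a few-fold larger than host
#'   divergence.
#' @param clinal_fraction_low fraction of non-block SNPs that are clinal.
#' @param beta_low,gamma_low slope and host effect for clinal non-block SNPs.
#' @param coupling_fraction share of clinal SNPs (and blocks) whose
#'   latitudinal slope and host effect share sign.
#' @param effect_size planned experiment response magnitude `|delta|`
#'   (allele frequency difference units) for effect SNPs/blocks; actual
#'   magnitudes are drawn uniformly from `effect_size * c(0.6, 1.4)`.
#' @param effect_snps optional named list (`eclosion`, `apple_prewinter`,
#'   `haw_prewinter`) of explicit SNP index vectors carrying responses; if
#'   `NULL`, sets are drawn in [simulate_truth()] from the default rules
#'   (eclosion: blocks on chromosomes 1-3; apple prewinter: blocks on
#'   chromosomes 2-3; hawthorn prewinter: a random 15% of non-block SNPs on
#'   chromosomes 3-5).
#' @param experiments list describing the paired experiments: each element has
#'   `host`, `site` (index of the base population), group labels, and group
#'   sizes (first group minus second is the recorded sign convention).
#' @param depth_mean Poisson mean per-entry read depth.
#' @param base_error symmetric per-read base miscall probability, in
#'   `[0, 0.5)`.
#' @param seed master integer seed; every stochastic stage derives its
#'   sub-stream from it.
#' @return an object of class `sim_config`.
#' @seealso [simulate_truth()], [simulate_study()]
#' @export
sim_config <- function(n_sites = 4,
                       hosts = c("apple", "hawthorn"),
                       n_per_pop = 30,
                       n_snps = 2000,
                       mapped_fraction = 4244 / 10241,
                       chrom_weights = c(949, 675, 996, 812, 812),
                       block_high = 0.35, block_int = 0.25,
                       m_high = 0.02, m_int = 0.13,
                       beta_block = 0.4, gamma_block = 0.5,
                       clinal_fraction_low = 0.15,
                       beta_low = 0.3, gamma_low = 0.35,
                       coupling_fraction = 0.5,
                       effect_size = 0.25,
                       effect_snps = NULL,
                       experiments = NULL,
                       depth_mean = 4, base_error = 0.01,
                       seed = 1L) {
  if (length(hosts) != 2L) stopf("exactly two host labels are required")
  if (m_high < 0 || m_high > 0.5 || m_int < 0 || m_int > 0.5)
    stopf("mismatch probabilities m must lie in [0, 0.5]")
  if (depth_mean < 0) stopf("depth_mean must be >= 0")
  if (base_error < 0 || base_error >= 0.5)
    stopf("base_error must lie in [0, 0.5)")
  if (n_sites < 2) stopf("at least two sites are required")

  n_mapped <- round(n_snps * mapped_fraction)
  w <- chrom_weights / sum(chrom_weights)
  chrom_lengths <- floor(n_mapped * w)
  # distribute rounding remainder to the largest chromosomes
  rem <- n_mapped - sum(chrom_lengths)
  if (rem > 0) {
    ord <- order(w, decreasing = TRUE)
    chrom_lengths[ord[seq_len(rem)]] <- chrom_lengths[ord[seq_len(rem)]] + 1L
  }
  names(chrom_lengths) <- as.character(1:5)
  chrom_lengths <- c(chrom_lengths, unmapped = n_snps - n_mapped)

  # contiguous high and intermediate blocks at the start of each chromosome
  blocks <- do.call(rbind, lapply(1:5, function(ch) {
    L <- chrom_lengths[[as.character(ch)]]
    nh <- floor(L * block_high)
    ni <- floor(L * block_int)
    data.frame(
      chrom = ch,
      from  = c(1L, nh + 1L),
      to    = c(nh, nh + ni),
      class = c("high", "intermediate"),
      m     = c(m_high, m_int),
      stringsAsFactors = FALSE
    )
  }))
  blocks <- blocks[blocks$to >= blocks$from, , drop = FALSE]
  blocks$block_id <- sprintf("chr%d_%s", blocks$chrom, substr(blocks$class, 1, 3))
  validate_blocks(blocks)

  site_names <- if (n_sites == 4) {
    c("Grant", "Fennville", "Dowagiac", "Urbana")
  } else {
    sprintf("Site%d", seq_len(n_sites))
  }

  if (is.null(experiments)) {
    experiments <- list(
      eclosion_apple = list(host = hosts[1], site = 2L,
                            groups = c("early", "late"), n = c(50L, 50L),
                            effect = "eclosion"),
      eclosion_haw   = list(host = hosts[2], site = 2L,
                            groups = c("early", "late"), n = c(50L, 50L),
                            effect = "eclosion"),
      apple_prewinter = list(host = hosts[1], site = 1L,
                             groups = c("pw7d", "pw32d"), n = c(48L, 41L),
                             effect = "apple_prewinter"),
      haw_prewinter   = list(host = hosts[2], site = 1L,
                             groups = c("pw7d", "pw32d"), n = c(48L, 41L),
                             effect = "haw_prewinter")
    )
    if (n_sites < 2) experiments <- list()
  }

  structure(list(
    n_sites = as.integer(n_sites), hosts = hosts,
    n_per_pop = as.integer(n_per_pop), n_snps = as.integer(n_snps),
    chrom_lengths = chrom_lengths, blocks = blocks,
    site_names = site_names,
    cline = list(beta_block = beta_block, gamma_block = gamma_block,
                 clinal_fraction_low = clinal_fraction_low,
                 beta_low = beta_low, gamma_low = gamma_low),
    coupling_fraction = coupling_fraction,
    effect_size = effect_size, effect_snps = effect_snps,
    experiments = experiments,
    depth_mean = depth_mean, base_error = base_error,
    seed = as.integer(seed)
  ), class = "sim_config")
}

validate_blocks <- function(blocks) {
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (nrow(b) < 2) next
    b <- b[order(b$from), , drop = FALSE]
    if (any(b$from[-1] <= b$to[-nrow(b)]))
      stopf("overlapping LD blocks on chromosome %s", ch)
  }
  if (any(blocks$m < 0 | blocks$m > 0.5))
    stopf("block mismatch probability m must lie in [0, 0.5]")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic GBS cline study configuration\n")
  cat(sprintf("  %d sites x %d hosts, %d individuals per population\n",
              x$n_sites, length(x$hosts), x$n_per_pop))
  cat(sprintf("  %d SNPs (%d mapped on 5 chromosomes), %d LD blocks\n",
              x$n_snps, sum(x$chrom_lengths[as.character(1:5)]),
              nrow(x$blocks)))
  cat(sprintf("  depth ~ Poisson(%g), base error %g, seed %d\n",
              x$depth_mean, x$base_error, x$seed))
  invisible(x)
}
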