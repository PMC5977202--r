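#' Simulate the true allele-frequency architecture of a cline study
#'
#' Draws the per-SNP cline parameters and returns the complete ground truth of
#' a synthetic study: true allele frequencies for every SNP in every
#' host-by-site population, latent inversion-orientation frequencies per LD
#' block, planned experiment responses, and true LD-class labels. All
#' downstream sampling (genotypes, reads, experiment groups) conditions on
#' this object, so recovery tests can compare estimates against known truth.
#'
#' Non-block SNPs follow \eqn{p(s, h) = \mathrm{logistic}(\alpha + \beta s +
#' \gamma [h = \mathrm{apple}])} with site order \eqn{s = 0, 1, \ldots}.
#' Block SNPs inherit the cline of their block's latent orientation: the
#' member-SNP frequency is \eqn{(1 - m) p_{lat} + m (1 - p_{lat})}.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_truth` with elements `snp_map`,
#'   `pops`, `p_pop` (SNPs x populations), `p_lat` (blocks x populations),
#'   `delta_snp` (SNPs x 3 planned responses), `delta_block`, and the drawn
#'   cline parameters.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, 1L))

  S <- config$n_snps
  cl <- config$chrom_lengths
  chrom <- c(rep(as.character(1:5), times = cl[as.character(1:5)]),
             rep("unmapped", cl[["unmapped"]]))
  idx_in_chrom <- unlist(lapply(cl, seq_len), use.names = FALSE)
  snp_id <- sprintf("snp%05d", seq_len(S))
  pos <- idx_in_chrom * 1000L

  blocks <- config$blocks
  block_id <- rep(NA_character_, S)
  true_class <- rep("low", S)
  m_snp <- numeric(S)
  for (b in seq_len(nrow(blocks))) {
    sel <- chrom == as.character(blocks$chrom[b]) &
      idx_in_chrom >= blocks$from[b] & idx_in_chrom <= blocks$to[b]
    block_id[sel] <- blocks$block_id[b]
    true_class[sel] <- blocks$class[b]
    m_snp[sel] <- blocks$m[b]
  }
  snp_map <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                        true_ld_class = true_class, block_id = block_id,
                        stringsAsFactors = FALSE)

  pops <- expand.grid(site = seq_len(config$n_sites), host = config$hosts,
                      stringsAsFactors = FALSE)
  pops <- pops[order(pops$host, pops$site), ]
  pops$site_name <- config$site_names[pops$site]
  pops$site_order <- pops$site
  pops$pop <- paste(pops$host, pops$site_name, sep = "_")
  rownames(pops) <- pops$pop
  P <- nrow(pops)
  s_ord <- pops$site_order - 1L
  is_apple <- as.integer(pops$host == config$hosts[1])

  # block latent-orientation clines
  nb <- nrow(blocks)
  b_alpha <- logit(runif(nb, 0.3, 0.7))
  b_sign <- sample(c(-1, 1), nb, replace = TRUE)
  b_beta <- config$cline$beta_block * b_sign
  b_coupled <- runif(nb) < config$coupling_fraction
  b_gamma <- config$cline$gamma_block * b_sign * ifelse(b_coupled, 1, -1)
  p_lat <- logistic(outer(b_alpha, rep(1, P)) + outer(b_beta, s_ord) +
                      outer(b_gamma, is_apple))
  dimnames(p_lat) <- list(blocks$block_id, pops$pop)

  # non-block SNP clines
  nonblock <- is.na(block_id)
  alpha <- logit(runif(S, 0.1, 0.9))
  beta <- gamma <- numeric(S)
  clinal <- nonblock & runif(S) < config$cline$clinal_fraction_low
  sgn <- sample(c(-1, 1), S, replace = TRUE)
  coupled <- runif(S) < config$coupling_fraction
  beta[clinal] <- config$cline$beta_low * sgn[clinal]
  gamma[clinal] <- config$cline$gamma_low * sgn[clinal] *
    ifelse(coupled[clinal], 1, -1)

  p_pop <- logistic(outer(alpha, rep(1, P)) + outer(beta, s_ord) +
                      outer(gamma, is_apple))
  # block members track the latent orientation with mismatch probability m
  for (b in seq_len(nb)) {
    sel <- which(block_id == blocks$block_id[b])
    m <- blocks$m[b]
    p_pop[sel, ] <- rep((1 - m) * p_lat[b, ] + m * (1 - p_lat[b, ]),
                        each = length(sel))
  }
  dimnames(p_pop) <- list(snp_id, pops$pop)
  if (any(p_pop <= 0 | p_pop >= 1))
    stopf("cline parameters imply frequencies outside (0, 1)")

  # planned experiment responses (block-level for block SNPs)
  eff <- config$effect_snps
  mag <- function(n) runif(n, 0.6, 1.4) * config$effect_size
  delta_block <- matrix(0, nb, 3, dimnames = list(
    blocks$block_id, c("eclosion", "apple_prewinter", "haw_prewinter")))
  delta_snp <- matrix(0, S, 3, dimnames = list(
    snp_id, c("eclosion", "apple_prewinter", "haw_prewinter")))

  if (is.null(eff)) {
    # The allele associated with later eclosion / 32-day survival is the one
    # rising toward the southern end of the transect. Under the recorded
    # orientations (early - late, 7d - 32d, first site - last site) both the
    # experiment responses and the geographic contrast then carry the sign
    # opposite to the latitudinal slope, making their association positive.
    bl_ecl <- blocks$chrom %in% 1:3
    bl_apw <- blocks$chrom %in% 2:3
    delta_block[bl_ecl, "eclosion"] <- -b_sign[bl_ecl] * mag(sum(bl_ecl))
    delta_block[bl_apw, "apple_prewinter"] <- -b_sign[bl_apw] * mag(sum(bl_apw))
    hpw_pool <- which(nonblock & chrom %in% as.character(3:5))
    hpw <- sample(hpw_pool, max(1L, round(0.15 * length(hpw_pool))))
    sg <- ifelse(beta[hpw] != 0, -sign(beta[hpw]),
                 sample(c(-1, 1), length(hpw), replace = TRUE))
    delta_snp[hpw, "haw_prewinter"] <- sg * mag(length(hpw))
  } else {
    for (k in seq_along(delta_snp[1, ])) {
      nm <- colnames(delta_snp)[k]
      ix <- eff[[nm]]
      if (is.null(ix)) next
      delta_snp[ix, k] <- sample(c(-1, 1), length(ix), TRUE) * mag(length(ix))
    }
  }
  # realized per-SNP response implied by a block-level shift
  for (b in seq_len(nb)) {
    sel <- which(block_id == blocks$block_id[b])
    if (!length(sel)) next
    shrink <- 1 - 2 * blocks$m[b]
    for (k in 1:3)
      if (delta_block[b, k] != 0) delta_snp[sel, k] <- shrink * delta_block[b, k]
  }

  structure(list(
    config = config, snp_map = snp_map, pops = pops,
    p_pop = p_pop, p_lat = p_lat,
    alpha = alpha, beta = beta, gamma = gamma,
    block_beta = b_beta, block_gamma = b_gamma,
    delta_snp = delta_snp, delta_block = delta_block
  ), class = "sim_truth")
}

# Draw unphased genotype dosages for n individuals of one population.
# Non-block SNPs are independent HWE draws at the population frequency;
# block SNPs are built from two latent orientation haplotypes per individual
# so that within-block LD is generated mechanically.
draw_dosages <- function(n, truth, p_snp, p_lat_pop) {
  S <- nrow(truth$snp_map)
  G <- matrix(0L, n, S)
  nonblock <- is.na(truth$snp_map$block_id)
  k <- sum(nonblock)
  G[, nonblock] <- matrix(
    rbinom(n * k, 2L, rep(p_snp[nonblock], each = n)), n, k)
  blocks <- truth$config$blocks
  for (b in seq_len(nrow(blocks))) {
    sel <- which(truth$snp_map$block_id == blocks$block_id[b])
    if (!length(sel)) next
    m <- blocks$m[b]
    z1 <- rbinom(n, 1L, p_lat_pop[b])
    z2 <- rbinom(n, 1L, p_lat_pop[b])
    k <- length(sel)
    flip1 <- matrix(rbinom(n * k, 1L, m), n, k)
    flip2 <- matrix(rbinom(n * k, 1L, m), n, k)
    G[, sel] <- abs(z1 - flip1) + abs(z2 - flip2)
  }
  colnames(G) <- truth$snp_map$snp_id
  G
}

#' Simulate sequencing reads and genotype likelihoods from true genotypes
#'
#' Per entry, depth is Poisson(`depth_mean`); the alternate-read count is
#' binomial with success probability `g/2` adjusted by the symmetric base
#' error (`e` for homozygous reference, `1 - e` for homozygous alternate,
#' `0.5` for heterozygotes). Genotype likelihoods are the binomial read
#' likelihoods under each genotype, normalized so the maximum is 1; zero
#' depth yields a missing entry.
#'
#' @param G integer dosage matrix (individuals x SNPs, values 0/1/2).
#' @param depth_mean Poisson mean read depth.
#' @param base_error per-read miscall probability in `[0, 0.5)`.
#' @param sample_ids row (sample) names for the result.
#' @return a [gl_data()] object.
#' @export
sim_reads_gl <- function(G, depth_mean, base_error,
                         sample_ids = sprintf("ind%04d", seq_len(nrow(G)))) {
  n <- nrow(G); S <- ncol(G)
  e <- base_error
  fg <- c(e, 0.5, 1 - e)
  D <- matrix(rpois(n * S, depth_mean), n, S)
  K <- matrix(rbinom(n * S, D, fg[G + 1L]), n, S)
  L <- lapply(0:2, function(g) matrix(dbinom(K, D, fg[g + 1L]), n, S))
  miss <- D == 0L
  for (g in 1:3) L[[g]][miss] <- NA_real_
  gl_data(L[[1]], L[[2]], L[[3]], samples = sample_ids,
          snps = colnames(G))
}

#' Simulate the geographic survey dataset
#'
#' Samples `n_per_pop` individuals from every host-by-site population,
#' simulates their genotypes and low-coverage reads, and returns genotype
#' likelihoods with aligned sample metadata and SNP map.
#'
#' @param truth a [simulate_truth()] object.
#' @param seed integer seed; defaults to a sub-stream of the config seed.
#' @return a list with `gl` ([gl_data()]), `metadata`, `snp_map`, and the
#'   simulated true dosage matrix `genotypes` (for recovery tests).
#' @export
simulate_survey <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  set.seed(seed %||% substream_seed(config$seed, 2L))
  n <- config$n_per_pop
  pops <- truth$pops
  G_list <- vector("list", nrow(pops))
  meta <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    G_list[[i]] <- draw_dosages(n, truth, truth$p_pop[, i], truth$p_lat[, i])
    meta[[i]] <- data.frame(
      sample_id = sprintf("%s_%03d", pops$pop[i], seq_len(n)),
      host = pops$host[i], site = pops$site_name[i],
      site_order = pops$site_order[i], group = "survey",
      pop = pops$pop[i], stringsAsFactors = FALSE)
  }
  G <- do.call(rbind, G_list)
  metadata <- do.call(rbind, meta)
  rownames(G) <- metadata$sample_id
  gl <- sim_reads_gl(G, config$depth_mean, config$base_error,
                     sample_ids = metadata$sample_id)
  list(gl = gl, metadata = metadata, snp_map = truth$snp_map, genotypes = G)
}

#' Simulate one paired experiment (two frequency-shifted groups)
#'
#' For the experiment's base population, group-specific frequencies are the
#' population truth shifted by plus/minus half the planned response (applied
#' at block level for block SNPs, preserving within-block LD), clipped to
#' `[0.005, 0.995]`. Individuals are then sampled and sequenced exactly as in
#' the survey. The recorded sign convention is first group minus second.
#'
#' @param truth a [simulate_truth()] object.
#' @param name name of the experiment in `config$experiments`.
#' @param seed integer seed.
#' @return list with `gl`, `metadata`, `genotypes`, `group_freq` (SNPs x 2
#'   realized group frequencies) and `planned_delta` (per-SNP, group1 -
#'   group2).
#' @export
simulate_experiment_groups <- function(truth, name, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  ex <- config$experiments[[name]]
  if (is.null(ex)) stopf("experiment '%s' is not defined in the config", name)
  k <- 2L + match(name, names(config$experiments))
  set.seed(seed %||% substream_seed(config$seed, k))

  pop <- paste(ex$host, config$site_names[ex$site], sep = "_")
  eff_col <- ex$effect
  d_snp <- truth$delta_snp[, eff_col]
  d_block <- truth$delta_block[, eff_col]
  p0 <- truth$p_pop[, pop]
  pl0 <- truth$p_lat[, pop]
  if (any(abs(d_snp) > 1) || any(abs(d_block) > 1))
    stopf("planned response pushes frequencies outside [0, 1] beyond tolerance")

  clip <- function(p) pmin(pmax(p, 0.005), 0.995)
  nonblock <- is.na(truth$snp_map$block_id)
  half <- ifelse(nonblock, d_snp / 2, 0)
  p_g <- cbind(clip(p0 + half), clip(p0 - half))
  pl_g <- cbind(clip(pl0 + d_block / 2), clip(pl0 - d_block / 2))

  G_list <- meta <- vector("list", 2L)
  for (g in 1:2) {
    ng <- ex$n[g]
    G_list[[g]] <- draw_dosages(ng, truth, p_g[, g], pl_g[, g])
    meta[[g]] <- data.frame(
      sample_id = sprintf("%s_%s_%03d", name, ex$groups[g], seq_len(ng)),
      host = ex$host, site = config$site_names[ex$site],
      site_order = ex$site, group = ex$groups[g], pop = pop,
      stringsAsFactors = FALSE)
  }
  G <- do.call(rbind, G_list)
  metadata <- do.call(rbind, meta)
  rownames(G) <- metadata$sample_id
  gl <- sim_reads_gl(G, config$depth_mean, config$base_error,
                     sample_ids = metadata$sample_id)
  planned <- p_g[, 1] - p_g[, 2]
  # block members inherit the (clipped) latent shift attenuated by 1 - 2m
  for (b in seq_len(nrow(config$blocks))) {
    sel <- which(truth$snp_map$block_id == config$blocks$block_id[b])
    if (!length(sel)) next
    planned[sel] <- (1 - 2 * config$blocks$m[b]) * (pl_g[b, 1] - pl_g[b, 2])
  }
  list(gl = gl, metadata = metadata, genotypes = G,
       group_freq = p_g, planned_delta = planned,
       groups = ex$groups, orientation = sprintf("%s - %s", ex$groups[1],
                                                 ex$groups[2]))
}

#' Simulate a complete synthetic study (survey + experiments)
#'
#' Convenience wrapper running [simulate_truth()], [simulate_survey()] and
#' [simulate_experiment_groups()] for every configured experiment, optionally
#' writing all artifacts (VCFs, metadata and SNP-map TSVs, truth JSON) to
#' disk.
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional directory for the written artifacts.
#' @return list with `truth`, `survey`, and `experiments` (named list).
#' @export
simulate_study <- function(config, out_dir = NULL) {
  truth <- simulate_truth(config)
  survey <- simulate_survey(truth)
  experiments <- lapply(names(config$experiments), function(nm)
    simulate_experiment_groups(truth, nm))
  names(experiments) <- names(config$experiments)
  study <- list(truth = truth, survey = survey, experiments = experiments,
                config = config)
  if (!is.null(out_dir)) write_study(study, out_dir)
  invisible(study)
}
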