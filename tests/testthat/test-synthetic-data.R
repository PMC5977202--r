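test_that("flat clines give identical population frequencies and positive slopes give monotone clines", {
  cfg <- sim_config(n_snps = 120, beta_block = 0, gamma_block = 0,
                    clinal_fraction_low = 0, seed = 3)
  tr <- simulate_truth(cfg)
  expect_true(all(abs(tr$p_pop - tr$p_pop[, 1]) < 1e-12))

  cfg2 <- sim_config(n_snps = 120, clinal_fraction_low = 1, seed = 4)
  tr2 <- simulate_truth(cfg2)
  haw <- tr2$pops$pop[tr2$pops$host == "hawthorn"][order(
    tr2$pops$site_order[tr2$pops$host == "hawthorn"])]
  nonblock <- is.na(tr2$snp_map$block_id)
  up <- which(nonblock & tr2$beta > 0)
  for (j in up[1:5]) {
    expect_true(all(diff(tr2$p_pop[j, haw]) > 0))
  }
  dn <- which(nonblock & tr2$beta < 0)
  expect_true(all(diff(tr2$p_pop[dn[1], haw]) < 0))
})

test_that("the same seed reproduces the truth and the sampled data exactly", {
  cfg <- sim_config(n_snps = 100, n_per_pop = 5, seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth$p_pop, s2$truth$p_pop)
  expect_identical(s1$survey$gl$L1, s2$survey$gl$L1)
  expect_identical(s1$experiments$apple_prewinter$metadata,
                   s2$experiments$apple_prewinter$metadata)
})

test_that("deep error-free coverage recovers the simulated genotypes almost everywhere", {
  tr <- one_pop_truth(n_snps = 150, seed = 5)
  G <- one_pop_genotypes(tr, 60)
  set.seed(9)
  gl <- sim_reads_gl(G, depth_mean = 100, base_error = 0)
  ml <- max.col(cbind(as.vector(gl$L0), as.vector(gl$L1), as.vector(gl$L2)),
                ties.method = "first") - 1L
  obs <- !is.na(as.vector(gl$L0))
  expect_gt(mean(ml[obs] == as.vector(G)[obs]), 0.999)
})

test_that("zero depth yields a fully missing dataset", {
  tr <- one_pop_truth(n_snps = 40, seed = 6)
  G <- one_pop_genotypes(tr, 8)
  gl <- sim_reads_gl(G, depth_mean = 0, base_error = 0.01)
  expect_true(all(is.na(gl$L0)))
})

test_that("empirical frequencies at large n match truth within binomial error", {
  tr <- one_pop_truth(n_snps = 300, seed = 7)
  n <- 200
  G <- one_pop_genotypes(tr, n)
  p_emp <- colMeans(G) / 2
  p_true <- tr$p_pop[, 1]
  se <- sqrt(p_true * (1 - p_true) / (2 * n))
  expect_gte(mean(abs(p_emp - p_true) <= 3 * se), 0.95)
})

test_that("experiment groups realize the planned frequency responses", {
  cfg <- sim_config(n_snps = 200, seed = 13, effect_size = 0.3,
                    depth_mean = 30)
  tr <- simulate_truth(cfg)
  ex <- simulate_experiment_groups(tr, "apple_prewinter")
  g1 <- ex$metadata$sample_id[ex$metadata$group == "pw7d"]
  g2 <- ex$metadata$sample_id[ex$metadata$group == "pw32d"]
  fd <- frequency_difference(ex$gl, g1, g2)
  eff <- abs(ex$planned_delta) > 0.15
  # estimated differences track planned ones at effect SNPs
  expect_lt(median(abs(fd$dp[eff] - ex$planned_delta[eff])), 0.1)
  # and are near zero where no response was planted
  expect_lt(mean(abs(fd$dp[!eff & ex$planned_delta == 0])), 0.08)

  # delta = 0 everywhere: group frequencies coincide exactly in truth
  cfg0 <- sim_config(n_snps = 100, seed = 14, effect_snps = list())
  tr0 <- simulate_truth(cfg0)
  ex0 <- simulate_experiment_groups(tr0, "haw_prewinter")
  expect_true(all(ex0$group_freq[, 1] == ex0$group_freq[, 2]))

  # identical seed, identical group draws
  exa <- simulate_experiment_groups(tr, "eclosion_apple", seed = 99)
  exb <- simulate_experiment_groups(tr, "eclosion_apple", seed = 99)
  expect_identical(exa$genotypes, exb$genotypes)
})

test_that("planted high-LD blocks produce high composite r2 between members", {
  tr <- one_pop_truth(n_snps = 250, seed = 21, block_high = 0.3,
                      m_high = 0.02)
  G <- one_pop_genotypes(tr, 200)
  bl <- tr$snp_map$block_id
  b1 <- which(!is.na(bl) & bl == "chr1_hig")
  cl <- composite_ld_matrix(G[, b1])
  ut <- upper.tri(cl$r2)
  expect_gte(mean(cl$r2[ut] > 0.6, na.rm = TRUE), 0.95)
})

test_that("population frequency differences recover the planted cline architecture", {
  cfg <- sim_config(n_snps = 500, n_per_pop = 50, seed = 23, depth_mean = 20)
  study <- simulate_study(cfg)
  tr <- study$truth
  sv <- study$survey
  h <- "hawthorn"
  g1 <- sv$metadata$sample_id[sv$metadata$host == h & sv$metadata$site_order == 1]
  g4 <- sv$metadata$sample_id[sv$metadata$host == h & sv$metadata$site_order == 4]
  fd <- frequency_difference(sv$gl, g4, g1)
  # true geographic contrast per SNP
  dtrue <- tr$p_pop[, paste0(h, "_Urbana")] - tr$p_pop[, paste0(h, "_Grant")]
  fit <- fit_simple_regression(fd$dp, dtrue)
  expect_gt(fit$r, 0.8)
  expect_gt(fit$coefficients["x", 1], 0.8)
})

test_that("overlapping blocks are rejected", {
  cfg <- sim_config(n_snps = 200, seed = 1)
  cfg$blocks$from[2] <- cfg$blocks$to[1]  # overlap on chromosome 1
  expect_error(racecline:::validate_blocks(cfg$blocks), "overlapping")
})

test_that("written VCFs round-trip through the reader without loss", {
  cfg <- sim_config(n_snps = 60, n_per_pop = 4, seed = 31)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  rt <- read_genotype_data(file.path(dir, "survey.vcf"),
                           file.path(dir, "survey_metadata.tsv"),
                           file.path(dir, "snp_map.tsv"))
  gl0 <- study$survey$gl
  expect_identical(rt$gl$samples, gl0$samples)
  expect_identical(rt$gl$snps, gl0$snps)
  expect_identical(is.na(rt$gl$L1), is.na(gl0$L1))
  # normalized likelihoods agree to GL text precision
  expect_lt(max(abs(rt$gl$L1 - gl0$L1), na.rm = TRUE), 2e-3)
  expect_lt(max(abs(rt$gl$L0 - gl0$L0), na.rm = TRUE), 2e-3)
  # frequencies estimated from the round-tripped file agree
  f0 <- estimate_allele_freq(gl0)
  f1 <- estimate_allele_freq(rt$gl)
  expect_lt(max(abs(f0$p_hat - f1$p_hat), na.rm = TRUE), 1e-3)
})
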