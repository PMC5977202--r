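test_that("a toy PL VCF is read into an aligned likelihood array", {
  dir <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(dir, "toy.vcf"))
  write_toy_tables(file.path(dir, "meta.tsv"), file.path(dir, "map.tsv"))
  d <- read_genotype_data(vcf, file.path(dir, "meta.tsv"),
                          file.path(dir, "map.tsv"))
  expect_identical(dim(d$gl), c(3L, 2L))
  expect_false(anyNA(d$gl$L0))
  # PL 0,30,60 -> normalized likelihoods 1, 1e-3, 1e-6
  expect_equal(d$gl$L0["s1", "snpA"], 1)
  expect_equal(d$gl$L1["s1", "snpA"], 1e-3)
  expect_identical(d$metadata$sample_id, c("s1", "s2", "s3"))
  expect_identical(d$snp_map$chrom, c("1", "2"))
})

test_that("missing PL entries become missing genotypes and absent metadata samples error", {
  dir <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(dir, "toy.vcf"), gt_missing = TRUE)
  write_toy_tables(file.path(dir, "meta.tsv"), file.path(dir, "map.tsv"))
  d <- read_genotype_data(vcf, file.path(dir, "meta.tsv"),
                          file.path(dir, "map.tsv"))
  expect_true(is.na(d$gl$L0["s2", "snpB"]))
  expect_false(is.na(d$gl$L0["s2", "snpA"]))

  write_toy_tables(file.path(dir, "meta2.tsv"), file.path(dir, "map.tsv"),
                   drop_sample = TRUE)
  expect_error(
    read_genotype_data(vcf, file.path(dir, "meta2.tsv"),
                       file.path(dir, "map.tsv")), "s2")
})

test_that("EM equals the allele-count estimator on certain likelihoods", {
  G <- matrix(c(rep(2L, 3), rep(0L, 7)), ncol = 1)
  f <- estimate_allele_freq(certain_gl(G))
  expect_equal(f$p_hat, 0.3)
  expect_equal(f$n_eff, 10L)

  # property: random certain-genotype samples match counting exactly
  set.seed(42)
  for (i in 1:20) {
    G <- matrix(sample(0:2, 30, replace = TRUE), ncol = 3)
    f <- estimate_allele_freq(certain_gl(G))
    expect_equal(f$p_hat, colMeans(G) / 2, tolerance = 1e-12)
  }
})

test_that("uninformative and missing data yield NA frequencies", {
  gl <- gl_data(matrix(1, 5, 2), matrix(1, 5, 2), matrix(1, 5, 2),
                samples = paste0("i", 1:5), snps = c("a", "b"))
  f <- estimate_allele_freq(gl)
  expect_true(all(is.na(f$p_hat)))
  expect_identical(f$n_eff, c(0, 0))
})

test_that("EM never decreases the observed-data log-likelihood", {
  tr <- one_pop_truth(n_snps = 50, seed = 8)
  G <- one_pop_genotypes(tr, 40)
  set.seed(3)
  gl <- sim_reads_gl(G, depth_mean = 3, base_error = 0.02)
  p <- rep(0.5, 50)
  ll_prev <- gl_loglik(gl, p)
  inf <- racecline:::gl_informative(gl)
  n_eff <- colSums(inf)
  for (it in 1:25) {
    pr0 <- (1 - p)^2; pr1 <- 2 * p * (1 - p); pr2 <- p^2
    w0 <- sweep(ifelse(inf, gl$L0, NA), 2, pr0, `*`)
    w1 <- sweep(ifelse(inf, gl$L1, NA), 2, pr1, `*`)
    w2 <- sweep(ifelse(inf, gl$L2, NA), 2, pr2, `*`)
    den <- w0 + w1 + w2
    p <- colSums((w1 + 2 * w2) / den, na.rm = TRUE) / (2 * pmax(n_eff, 1))
    ll <- gl_loglik(gl, p)
    expect_true(all(ll >= ll_prev - 1e-9))
    ll_prev <- ll
  }
})

test_that("mean posterior dosage equals twice the EM frequency at convergence", {
  tr <- one_pop_truth(n_snps = 80, seed = 9)
  G <- one_pop_genotypes(tr, 50)
  set.seed(4)
  gl <- sim_reads_gl(G, depth_mean = 4, base_error = 0.01)
  f <- estimate_allele_freq(gl, tol = 1e-10, max_iter = 500)
  D <- posterior_dosages(gl, f)
  inf <- racecline:::gl_informative(gl)
  D[!inf] <- NA  # self-consistency holds over the informative entries
  expect_equal(colMeans(D, na.rm = TRUE), 2 * f$p_hat,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("posterior dosages obey the certain and flat-likelihood closed forms", {
  G <- matrix(c(2L, 1L, 0L), ncol = 1)
  D <- posterior_dosages(certain_gl(G), p = 0.4)
  expect_equal(as.vector(D), c(2, 1, 0))
  # flat likelihood: HWE prior mean 2p
  gl <- gl_data(matrix(1, 2, 1), matrix(1, 2, 1), matrix(1, 2, 1),
                samples = c("i1", "i2"), snps = "a")
  expect_equal(as.vector(posterior_dosages(gl, p = 0.25)), c(0.5, 0.5))
})

test_that("frequency differences are zero on identical groups and antisymmetric", {
  tr <- one_pop_truth(n_snps = 60, seed = 10)
  G <- one_pop_genotypes(tr, 40)
  gl <- certain_gl(G)
  g1 <- gl$samples[1:20]; g2 <- gl$samples[21:40]
  fd <- frequency_difference(gl, g1, g2)
  fd_swap <- frequency_difference(gl, g2, g1)
  expect_equal(fd$dp, -fd_swap$dp)
  expect_error(frequency_difference(gl, g1, g1[1]), "disjoint")
  expect_error(frequency_difference(gl, character(0), g2), "non-empty")
  # same underlying frequencies: split halves of one group
  fd0 <- frequency_difference(gl, g1[1:10], g1[1:10 + 10])
  expect_true(all(abs(fd0$dp) <= 1))
})

test_that("polarization flips to the reference major allele and is idempotent", {
  freqs <- cbind(ref = c(0.7, 0.3, 0.5), other = c(0.6, 0.9, 0.2))
  pol <- polarize_to_reference(freqs, "ref")
  expect_equal(pol[, "ref"], c(0.7, 0.7, 0.5), ignore_attr = TRUE)
  expect_equal(pol[, "other"], c(0.6, 0.1, 0.2), ignore_attr = TRUE)
  expect_identical(attr(pol, "flipped"), c(FALSE, TRUE, FALSE))
  pol2 <- polarize_to_reference(pol, "ref")
  expect_equal(pol2, pol, ignore_attr = TRUE)
  dp <- c(0.1, -0.2, 0.3)
  expect_equal(polarize_differences(dp, attr(pol, "flipped")),
               c(0.1, 0.2, 0.3))
})
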