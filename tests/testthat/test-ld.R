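test_that("composite LD matches hand-evaluated and degenerate cases", {
  res <- composite_ld(c(2, 0), c(2, 0))
  expect_equal(res$delta, 0.5)
  expect_equal(res$r, 1)
  expect_true(is.na(composite_ld(c(1, 1, 1), c(0, 1, 2))$delta))
  expect_match(composite_ld(c(1, 1, 1), c(0, 1, 2))$reason, "monomorphic")
  expect_match(composite_ld(c(1, NA), c(0, 1))$reason, "fewer than 2")
})

test_that("composite LD equals the genotype-count formula and dosage Pearson correlation", {
  set.seed(7)
  for (i in 1:50) {
    x <- sample(0:2, 60, replace = TRUE)
    y <- sample(0:2, 60, replace = TRUE)
    res <- composite_ld(x, y)
    expect_equal(res$delta, as.numeric(brute_delta(x, y)), tolerance = 1e-12)
    expect_equal(res$r, cor(x, y), tolerance = 1e-12)
  }
})

test_that("the all-pairs LD matrix agrees with pairwise composite_ld under missingness", {
  set.seed(8)
  D <- matrix(sample(0:2, 200, replace = TRUE), 20, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  D[sample(length(D), 30)] <- NA
  m <- composite_ld_matrix(D)
  for (i in 1:9) for (j in (i + 1):10) {
    p <- composite_ld(D[, i], D[, j])
    if (is.na(p$delta)) {
      expect_true(is.na(m$delta[i, j]))
    } else {
      expect_equal(m$delta[i, j], p$delta, tolerance = 1e-12)
      expect_equal(m$r[i, j], p$r, tolerance = 1e-12)
      expect_equal(m$n[i, j], p$n, ignore_attr = TRUE)
    }
  }
})

test_that("sampling noise keeps composite LD of independent loci near zero", {
  set.seed(9)
  n <- 1000
  pairs <- replicate(200,
    composite_ld(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5))$delta)
  expect_gte(mean(abs(pairs) < 0.02), 0.95)
  x <- rbinom(10000, 2, 0.5); y <- rbinom(10000, 2, 0.5)
  expect_lt(abs(composite_ld(x, y)$delta), 0.02)
})

test_that("LD-class thresholds and tie rules follow the published definitions", {
  r2 <- matrix(c(NA, 0.7, 0.05,
                 0.7, NA, 0.03,
                 0.05, 0.03, NA), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  cl <- classify_ld_network(r2)
  expect_identical(cl$ld_class, c("high", "high", "low"))
  expect_identical(cl$component[1], cl$component[2])

  r2b <- matrix(c(NA, 0.3, 0.3, NA), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(classify_ld_network(r2b)$ld_class,
                   c("intermediate", "intermediate"))
  # boundary values 0.15 and 0.6 are intermediate (strict inequalities)
  r2c <- matrix(c(NA, 0.6, 0.6, NA), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(classify_ld_network(r2c)$ld_class[1], "intermediate")
  r2d <- matrix(c(NA, 0.15, 0.15, NA), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(classify_ld_network(r2d)$ld_class[1], "intermediate")
  # a SNP alone on its chromosome is low; an all-NA row is unassigned
  expect_identical(classify_ld_network(matrix(NA_real_, 1, 1,
    dimnames = list("a", "a")))$ld_class, "low")
  r2e <- matrix(c(NA, NA, NA, NA, NA, 0.7, NA, 0.7, NA), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_identical(classify_ld_network(r2e)$ld_class,
                   c("unassigned", "high", "high"))
})

test_that("mean linked LD averages within-chromosome r2 and handles edge cases", {
  # 3 SNPs on one chromosome, 1 alone on another
  set.seed(10)
  z <- rbinom(80, 2, 0.5)
  D <- cbind(s1 = z, s2 = z, s3 = rbinom(80, 2, 0.5), s4 = rbinom(80, 2, 0.4))
  map <- data.frame(snp_id = paste0("s", 1:4), chrom = c("1", "1", "1", "2"))
  mld <- mean_linked_ld(D, map)
  cl <- composite_ld_matrix(D[, 1:3])
  expect_equal(mld[["s1"]], mean(cl$r2[1, 2:3]))
  expect_true(is.na(mld[["s4"]]))  # alone on its chromosome
  # hand-built arithmetic case via classify inputs
  r2 <- c(0.8, 0.2)
  expect_equal(mean(r2), 0.5)
})

test_that("strong-diapause SNP selection applies the joint significance and effect-size rule", {
  ids <- paste0("s", 1:4)
  mk <- function(sig, dp) data.frame(snp_id = ids, significant = sig, dp = dp)
  res <- list(
    eclosion = mk(c(TRUE, TRUE, FALSE, FALSE), c(0.25, 0.15, 0.30, 0.10)),
    apple = mk(c(FALSE, FALSE, FALSE, TRUE), c(0.05, 0.10, 0.10, 0.15)),
    haw = mk(c(FALSE, FALSE, FALSE, FALSE), c(0.00, 0.05, 0.25, 0.10)))
  kept <- select_strong_diapause_snps(res, min_diff = 0.2)
  # s1: significant with |dp| 0.25 -> kept; s2: significant but max 0.15 -> out
  # s3: |dp| 0.30 but never significant -> out; s4: significant, max 0.15 -> out
  expect_identical(kept, "s1")
  expect_error(select_strong_diapause_snps(list()), "missing")
})

test_that("pooling shifted populations adds the closed-form admixture LD term", {
  set.seed(11)
  n <- 1000
  dA <- 0.3; dB <- 0.25  # planned frequency offsets at loci A and B
  pA <- c(0.5 + dA / 2, 0.5 - dA / 2)
  pB <- c(0.6 + dB / 2, 0.6 - dB / 2)
  X1 <- cbind(A = rbinom(n, 2, pA[1]), B = rbinom(n, 2, pB[1]),
              C = rbinom(n, 2, 0.5))
  X2 <- cbind(A = rbinom(n, 2, pA[2]), B = rbinom(n, 2, pB[2]),
              C = rbinom(n, 2, 0.5))
  d1 <- composite_ld(X1[, "A"], X1[, "B"])$delta
  d2 <- composite_ld(X2[, "A"], X2[, "B"])$delta
  dp <- composite_ld(c(X1[, "A"], X2[, "A"]), c(X1[, "B"], X2[, "B"]))$delta
  expect_equal(dp, mean(c(d1, d2)) + dA * dB / 2, tolerance = 0.015)
  # no offset at locus C: no pooling-induced shift at pairs involving C
  dC1 <- composite_ld(X1[, "A"], X1[, "C"])$delta
  dC2 <- composite_ld(X2[, "A"], X2[, "C"])$delta
  dCp <- composite_ld(c(X1[, "A"], X2[, "A"]), c(X1[, "C"], X2[, "C"]))$delta
  expect_equal(dCp, mean(c(dC1, dC2)), tolerance = 0.02)
})

test_that("interchromosomal LD distributions are centered at zero within an HWE population", {
  set.seed(12)
  n <- 500
  S <- 40
  D <- matrix(rbinom(n * S, 2, 0.5), n, S,
              dimnames = list(NULL, sprintf("s%02d", 1:S)))
  map <- data.frame(snp_id = colnames(D),
                    chrom = rep(c("1", "2"), each = S / 2))
  res <- interchromosomal_ld(list(pop = D), map, colnames(D))
  expect_equal(nrow(res$pairs), (S / 2)^2)
  expect_lt(abs(res$summary$delta_mean), 0.01)
  # pooling two identical populations leaves the distribution unchanged
  res2 <- interchromosomal_ld(list(pool = rbind(D, D)), map, colnames(D))
  expect_equal(res2$pairs$delta, res$pairs$delta, tolerance = 1e-12)
  expect_error(interchromosomal_ld(list(pop = D),
    data.frame(snp_id = colnames(D), chrom = "1"), colnames(D)),
    "two chromosomes")
})
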