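test_that("Nei distance matches the closed form and flags degenerate pairs", {
  f <- cbind(x = c(0.5, 0.5), y = c(0.5, 0.5))
  expect_equal(nei_distance(f)["x", "y"], 0)
  # one locus, alt frequencies 1.0 vs 0.5: I = 0.5/sqrt(1*0.5), D = 0.3466
  f2 <- cbind(x = 1.0, y = 0.5)
  expect_equal(nei_distance(f2)["x", "y"], -log(0.5 / sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(nei_distance(f2)["x", "y"], 0.34657, tolerance = 1e-4)
  # opposite fixation at every locus: infinite distance, flagged
  f3 <- cbind(x = c(1, 1), y = c(0, 0))
  D3 <- nei_distance(f3)
  expect_true(is.infinite(D3["x", "y"]))
  expect_true(attr(D3, "infinite"))
})

test_that("Nei distance is symmetric and monotone in a single locus's divergence", {
  set.seed(17)
  base <- runif(50, 0.2, 0.8)
  d_at <- function(delta) {
    y <- base; y[1] <- min(base[1] + delta, 0.999)
    nei_distance(cbind(x = base, y = y))["x", "y"]
  }
  ds <- vapply(c(0, 0.05, 0.1, 0.15, 0.19), d_at, numeric(1))
  expect_true(all(diff(ds) > 0))
  D <- nei_distance(cbind(a = base, b = runif(50, 0.2, 0.8)))
  expect_identical(D["a", "b"], D["b", "a"])
})

test_that("neighbor joining solves the three-point closed form and additive metrics exactly", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  v <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(v, c((5 + 9 - 10) / 2, (5 + 10 - 9) / 2, (9 + 10 - 5) / 2),
               tolerance = 1e-10)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  Dinf <- D; Dinf[1, 2] <- Dinf[2, 1] <- Inf
  expect_error(nj_tree(Dinf), "infinite")

  # additive 4-taxon metric from a known tree is recovered exactly
  set.seed(18)
  gen <- ape::rtree(4, br = function(n) runif(n, 0.5, 2))
  gen <- ape::unroot(gen)
  D4 <- ape::cophenetic.phylo(gen)
  rec <- nj_tree(D4)
  expect_equal(ape::dist.topo(ape::unroot(rec), gen), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-10)
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sister branch", {
  # classic non-additive matrix producing a negative NJ edge
  D <- matrix(c(0, 2, 3, 4,
                2, 0, 3, 4,
                3, 3, 0, 1.5,
                4, 4, 1.5, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  raw <- ape::nj(as.dist(D))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  if (any(raw$edge.length < 0)) {
    # total tree length preserved by clamp-and-transfer
    expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-12)
  }
})

test_that("bootstrap supports separate distinct clusters and stay binary with a single replicate", {
  set.seed(19)
  S <- 400
  base <- runif(S, 0.2, 0.8)
  shift <- 0.25 * sample(c(-1, 1), S, replace = TRUE)
  noise <- function() rnorm(S, sd = 0.01)
  f <- cbind(a1 = base + noise(), a2 = base + noise(),
             b1 = base + shift + noise(), b2 = base + shift + noise())
  f <- pmin(pmax(f, 0.01), 0.99)
  tr <- bootstrap_nj(f, n_reps = 200, seed = 20)
  expect_gte(max(tr$node.label), 99)  # the a|b bipartition
  tr1 <- bootstrap_nj(f, n_reps = 1, seed = 21)
  expect_true(all(tr1$node.label %in% c(0, 100)))
})

test_that("identical populations do not acquire systematically high bootstrap support", {
  set.seed(22)
  S <- 300
  f <- matrix(runif(S, 0.3, 0.7), S, 5) +
    matrix(rnorm(S * 5, sd = 0.02), S, 5)
  colnames(f) <- paste0("p", 1:5)
  f <- pmin(pmax(f, 0.01), 0.99)
  tr <- bootstrap_nj(f, n_reps = 200, seed = 23)
  expect_lt(median(tr$node.label), 70)
})

test_that("DAPC separates fixed differences, respects the k-1 bound, and returns proper memberships", {
  set.seed(24)
  G <- rbind(matrix(rbinom(20 * 50, 2, 0.95), 20, 50),
             matrix(rbinom(20 * 50, 2, 0.05), 20, 50))
  groups <- rep(c("g1", "g2"), each = 20)
  fit <- dapc_fit(G, groups, n_pca = 3)
  expect_gt(fit$assign_mean, 0.99)
  expect_length(fit$eig_shares, 1)  # k = 2 -> one discriminant function
  expect_equal(rowSums(fit$membership), rep(1, 40), tolerance = 1e-9)
  expect_error(dapc_fit(G, groups, n_pca = 0), "n_pca")
  expect_error(dapc_fit(G, rep("g1", 40), n_pca = 2), "2 groups")
})

test_that("an arbitrary split of one panmictic population shows no real discrimination", {
  set.seed(25)
  G <- matrix(rbinom(60 * 80, 2, 0.5), 60, 80)
  fit <- dapc_fit(G, rep(c("a", "b"), 30), n_pca = 1)
  expect_lt(abs(fit$assign_mean - 0.5), 0.1)
})

test_that("the a-score rewards real structure and hovers near zero on null data", {
  set.seed(26)
  G <- rbind(matrix(rbinom(25 * 60, 2, 0.9), 25, 60),
             matrix(rbinom(25 * 60, 2, 0.1), 25, 60))
  res <- optimize_a_score(G, rep(c("x", "y"), each = 25), m_grid = 1:8,
                          seed = 27)
  expect_gt(max(res$curve$a_score), 0.4)  # near 1 - 1/k for k = 2
  expect_lte(res$best_m, 4)
  # overfitting penalty: a-score at large m does not exceed the optimum
  expect_lte(res$curve$a_score[res$curve$m == 8],
             max(res$curve$a_score) + 1e-9)

  G0 <- matrix(rbinom(50 * 60, 2, 0.5), 50, 60)
  res0 <- optimize_a_score(G0, rep(c("x", "y"), each = 25), m_grid = 1:5,
                           seed = 28)
  expect_lt(abs(mean(res0$curve$a_score)), 0.1)
})

test_that("cluster significance is minimal for planted structure and calibrated on null labels", {
  set.seed(29)
  G <- rbind(matrix(rbinom(20 * 50, 2, 0.9), 20, 50),
             matrix(rbinom(20 * 50, 2, 0.1), 20, 50))
  fit <- dapc_fit(G, rep(c("x", "y"), each = 20), n_pca = 2)
  sig <- cluster_significance(fit, n_reps = 300, seed = 30)
  expect_equal(sig$p, 0)

  ps <- vapply(1:40, function(i) {
    G0 <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30)
    f0 <- dapc_fit(G0, rep(c("x", "y"), 20), n_pca = 2)
    cluster_significance(f0, n_reps = 99, seed = 200 + i)$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("predictor matrices encode latitudinal order and host identity", {
  pops <- data.frame(pop = c("apple_Grant", "haw_Grant", "haw_Urbana"),
                     site_order = c(1L, 1L, 4L),
                     host = c("apple", "hawthorn", "hawthorn"))
  pm <- build_predictor_matrices(pops)
  expect_equal(pm$geo["apple_Grant", "haw_Grant"], 0)
  expect_equal(pm$host["apple_Grant", "haw_Grant"], 1)
  expect_equal(pm$geo["haw_Grant", "haw_Urbana"], 3)
  expect_equal(pm$host["haw_Grant", "haw_Urbana"], 0)
  expect_equal(pm$geo["apple_Grant", "apple_Grant"], 0)
  expect_equal(pm$host["apple_Grant", "apple_Grant"], 0)
})

test_that("the Mantel test detects exact linear structure and agrees with an independent implementation", {
  pops <- data.frame(pop = paste0("p", 1:6), site_order = 1:6,
                     host = rep(c("a", "h"), 3))
  pm <- build_predictor_matrices(pops)
  gen <- pm$geo * 0.01
  res <- mantel_test(gen, pm$geo, n_perm = 300, seed = 31)
  expect_equal(res$r, 1)
  expect_lte(res$p, 2 / 300)
  expect_error(mantel_test(gen, matrix(1, 6, 6) - diag(6) * 0,
                           n_perm = 10), "constant")

  skip_if_not_installed("vegan")
  set.seed(32)
  gen2 <- as.matrix(dist(matrix(rnorm(18), 6)))
  dimnames(gen2) <- list(pops$pop, pops$pop)
  res2 <- mantel_test(gen2, pm$geo, n_perm = 500, seed = 33)
  veg <- vegan::mantel(as.dist(gen2), as.dist(pm$geo), permutations = 500)
  expect_equal(res2$r, unname(veg$statistic), tolerance = 1e-12)
  expect_lt(abs(res2$p - veg$signif), 0.12)
})
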