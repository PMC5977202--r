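# Shared fixture builders. Everything is generated in code; no stored data.

# gl_data with certain (0/1) likelihoods from a hard genotype matrix;
# NA entries become missing genotypes.
certain_gl <- function(G) {
  n <- nrow(G); S <- ncol(G)
  L <- lapply(0:2, function(g) {
    M <- matrix(0, n, S)
    M[!is.na(G) & G == g] <- 1
    M[is.na(G)] <- NA_real_
    M
  })
  sn <- colnames(G) %||% sprintf("s%03d", seq_len(S))
  id <- rownames(G) %||% sprintf("i%03d", seq_len(n))
  gl_data(L[[1]], L[[2]], L[[3]], samples = id, snps = sn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-population truth with simple structure: high blocks only (optional),
# used where a single panmictic sample is needed.
one_pop_truth <- function(n_snps = 200, seed = 1, block_int = 0,
                          block_high = 0.3, m_high = 0.02,
                          clinal_fraction_low = 0) {
  cfg <- sim_config(n_snps = n_snps, n_sites = 2, n_per_pop = 10,
                    block_high = block_high, block_int = block_int,
                    m_high = m_high,
                    clinal_fraction_low = clinal_fraction_low, seed = seed)
  simulate_truth(cfg)
}

# Hard genotypes for n individuals of the first population of a truth object.
one_pop_genotypes <- function(truth, n, pop = 1) {
  racecline:::draw_dosages(n, truth, truth$p_pop[, pop], truth$p_lat[, pop])
}

# Brute-force Burrows composite delta from genotype counts (independent
# oracle for composite_ld on hard genotypes).
brute_delta <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  counts <- table(factor(x, 0:2), factor(y, 0:2))
  pA <- mean(x) / 2
  pB <- mean(y) / 2
  (2 * counts["2", "2"] + counts["2", "1"] + counts["1", "2"] +
      0.5 * counts["1", "1"]) / n - 2 * pA * pB
}

# Tiny plain-text VCF with PL field, written to a temp file.
write_toy_vcf <- function(path, gt_missing = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="PL">',
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
            "s1","s2","s3"), collapse = "\t"),
    paste(c("1","100","snpA","A","T",".","PASS",".","GT:PL",
            "0/0:0,30,60", "0/1:30,0,30", "1/1:60,30,0"), collapse = "\t"),
    paste(c("2","200","snpB","G","C",".","PASS",".","GT:PL",
            "0/0:0,20,40", if (gt_missing) "./.:." else "0/1:20,0,20",
            "0/0:0,25,50"), collapse = "\t"))
  writeLines(lines, path)
  path
}

write_toy_tables <- function(meta_path, map_path, drop_sample = FALSE) {
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     host = c("apple", "apple", "hawthorn"),
                     site = "Grant", site_order = 1L, group = "survey")
  if (drop_sample) meta <- meta[-2, ]
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(snp_id = c("snpA", "snpB"), chrom = c("1", "2"),
                    pos = c(100L, 200L))
  write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
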