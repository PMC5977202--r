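# Plain-text writers for the simulator's artifacts. Reading goes through
# vcfR (see read_genotype_data); the writer is a direct VCF 4.2 emitter for
# biallelic SNPs with GT, GL and PL FORMAT fields.

#' Write a genotype-likelihood dataset as VCF 4.2
#'
#' Emits one biallelic record per SNP with FORMAT `GT:GL:PL`. GT is the
#' maximum-likelihood genotype (ties broken toward the reference), GL the
#' log10 likelihoods normalized to a maximum of 0, and PL the rounded
#' phred-scaled normalized likelihoods. Missing entries are written as
#' `./.:.:.`.
#'
#' @param gl a [gl_data()] object.
#' @param path output file path.
#' @param snp_map optional SNP map supplying `chrom` and `pos`; SNPs absent
#'   from it are written with CHROM `unmapped`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gl, path, snp_map = NULL) {
  S <- length(gl$snps); n <- length(gl$samples)
  if (is.null(snp_map)) {
    chrom <- rep("unmapped", S); pos <- seq_len(S)
  } else {
    mi <- match(gl$snps, snp_map$snp_id)
    chrom <- ifelse(is.na(mi), "unmapped", as.character(snp_map$chrom[mi]))
    pos <- ifelse(is.na(mi), seq_len(S), snp_map$pos[mi])
  }
  floor_gl <- -99  # stands in for log10(0)
  cap_pl <- 999L

  fmt_entry <- function(l0, l1, l2) {
    miss <- is.na(l0)
    gt <- c("0/0", "0/1", "1/1")[max.col(cbind(l0, l1, l2),
                                         ties.method = "first")]
    g <- cbind(l0, l1, l2)
    lg <- log10(g)
    lg[!is.finite(lg)] <- floor_gl
    pl <- pmin(round(-10 * lg), cap_pl)
    out <- sprintf("%s:%.4f,%.4f,%.4f:%d,%d,%d", gt,
                   lg[, 1], lg[, 2], lg[, 3], pl[, 1], pl[, 2], pl[, 3])
    out[miss] <- "./.:.:."
    out
  }

  body <- matrix("", S, n)
  for (i in seq_len(n))
    body[, i] <- fmt_entry(gl$L0[i, ], gl$L1[i, ], gl$L2[i, ])

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=racecline synthetic GBS simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10 genotype likelihoods">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gl$samples), collapse = "\t")
  ), con)
  fixed <- cbind(chrom, pos, gl$snps, "A", "T", ".", "PASS", ".", "GT:GL:PL")
  writeLines(apply(cbind(fixed, body), 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write every artifact of a simulated study to a directory
#'
#' Writes the survey and each experiment as VCF + metadata TSV, the SNP map
#' TSV (including the true LD class), and the ground truth as JSON.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_vcf(study$survey$gl, file.path(dir, "survey.vcf"), study$truth$snp_map)
  tsv(study$survey$metadata, "survey_metadata.tsv")
  tsv(study$truth$snp_map, "snp_map.tsv")
  for (nm in names(study$experiments)) {
    ex <- study$experiments[[nm]]
    write_vcf(ex$gl, file.path(dir, paste0(nm, ".vcf")), study$truth$snp_map)
    tsv(ex$metadata, paste0(nm, "_metadata.tsv"))
  }
  truth <- study$truth
  jsonlite::write_json(list(
    p_pop = truth$p_pop, p_lat = truth$p_lat,
    delta_snp = truth$delta_snp,
    true_ld_class = truth$snp_map$true_ld_class,
    seed = truth$config$seed
  ), file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
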