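#!/usr/bin/env Rscript
# Assign high / intermediate / low LD classes from within-chromosome
# composite r2 (threshold graph at 0.6 / 0.15), compute the mean-linked-LD
# covariate, and score recovery of the planted classes.

source("analysis/_common.R")

study <- get_study()
sv <- study$survey
map <- study$truth$snp_map

pooled_freq <- estimate_allele_freq(sv$gl)
D <- posterior_dosages(sv$gl, pooled_freq)
classes <- assign_ld_classes(D, map)
classes$true_ld_class <- map$true_ld_class
classes$mean_linked_ld <- mean_linked_ld(D, map)
tsv(classes, "03_ld_classes.tsv")

mapped <- map$chrom != "unmapped"
tab <- table(truth = map$true_ld_class[mapped], assigned = classes$ld_class[mapped])
message("Planted vs assigned classes (mapped SNPs, posterior dosages at ~4x):")
print(tab)
message("Note: soft posterior dosages at low coverage attenuate r2, so some")
message("true-high SNPs fall below the 0.6 threshold; on true genotypes the")
message("classes separate cleanly (see the package tests).")

blk <- !is.na(map$block_id)
message(sprintf("Mean linked LD: block SNPs %.3f, non-block mapped SNPs %.3f",
                mean(classes$mean_linked_ld[blk], na.rm = TRUE),
                mean(classes$mean_linked_ld[mapped & !blk], na.rm = TRUE)))
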