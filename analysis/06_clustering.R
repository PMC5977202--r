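#!/usr/bin/env Rscript
# Population clustering: Nei genetic distances, bootstrap NJ network, DAPC
# (a-score PC selection + permutation significance), and Mantel tests for
# isolation by distance and by ecology.

source("analysis/_common.R")

study <- get_study()
sv <- study$survey
pops <- study$truth$pops
sites <- study_config$site_names
seed_of <- function(k) substream_seed(analysis_config$seed, 200 + k)

p_hat <- sapply(pops$pop, function(p) estimate_allele_freq(
  sv$gl, sv$metadata$sample_id[sv$metadata$pop == p])$p_hat)
rownames(p_hat) <- sv$gl$snps

nei <- nei_distance(p_hat)
tsv(data.frame(pop = rownames(nei), round(nei, 6), check.names = FALSE),
    "06_nei_distances.tsv")
geo_d <- c(nei["apple_Grant", "apple_Urbana"],
           nei["hawthorn_Grant", "hawthorn_Urbana"])
host_d <- vapply(sites, function(s)
  nei[paste0("apple_", s), paste0("hawthorn_", s)], numeric(1))
message(sprintf(
  "Nei D: geographic extremes %.4f (apple) / %.4f (hawthorn); sympatric host pairs mean %.4f (ratio %.1f)",
  geo_d[1], geo_d[2], mean(host_d), mean(geo_d) / mean(host_d)))

njb <- bootstrap_nj(p_hat, n_reps = analysis_config$boot_reps,
                    seed = seed_of(1))
ape::write.tree(njb, file.path(RESULTS, "06_nj_network.nwk"))
message("NJ network (bootstrap % on nodes): ", ape::write.tree(njb))

message("\nDAPC (a-score-selected PCs, permutation significance):")
pooled_freq <- estimate_allele_freq(sv$gl)
D <- posterior_dosages(sv$gl, pooled_freq)
dapc_rows <- list()
k <- 1
run_dapc <- function(nm, ids, labels) {
  asc <- optimize_a_score(D[ids, ], labels, seed = seed_of(k <<- k + 1))
  fit <- dapc_fit(D[ids, ], labels, n_pca = asc$best_m)
  sig <- cluster_significance(fit, n_reps = analysis_config$dapc_reps,
                              seed = seed_of(k <<- k + 1))
  message(sprintf("  %-24s PCs = %2d, mean correct assignment = %.3f, p = %.4g",
                  nm, asc$best_m, fit$assign_mean, sig$p))
  data.frame(comparison = nm, n_pca = asc$best_m,
             assign_mean = fit$assign_mean, p = sig$p)
}
for (s in sites) {
  ids <- sv$metadata$sample_id[sv$metadata$site == s]
  dapc_rows[[s]] <- run_dapc(paste0("host pairs at ", s), ids,
                             sv$metadata$host[match(ids, sv$metadata$sample_id)])
}
ids <- sv$metadata$sample_id[sv$metadata$host == "hawthorn" &
                               sv$metadata$site %in% c("Grant", "Urbana")]
dapc_rows$geo <- run_dapc("hawthorn Grant vs Urbana", ids,
                          sv$metadata$site[match(ids, sv$metadata$sample_id)])
ids <- sv$metadata$sample_id[sv$metadata$site %in% c("Grant", "Urbana")]
dapc_rows$k4 <- run_dapc("both races, both extremes", ids,
                         sv$metadata$pop[match(ids, sv$metadata$sample_id)])
tsv(do.call(rbind, dapc_rows), "06_dapc.tsv")

pred <- build_predictor_matrices(pops)
ibd <- mantel_test(nei, pred$geo, n_perm = analysis_config$mantel_perms,
                   seed = seed_of(50))
ibe <- mantel_test(nei, pred$host, n_perm = analysis_config$mantel_perms,
                   seed = seed_of(51))
message(sprintf("\nMantel IBD: r = %+.3f, p = %.4g; IBE: r = %+.3f, p = %.4g",
                ibd$r, ibd$p, ibe$r, ibe$p))
json_out(list(ibd = ibd, ibe = ibe), "06_mantel.json")
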