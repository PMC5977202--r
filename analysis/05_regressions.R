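#!/usr/bin/env Rscript
# Cross-experiment associations and the multiple-regression models: how much
# of the geographic and host-related differentiation do the diapause
# experiments (plus mean linked LD) explain?

source("analysis/_common.R")

study <- get_study()
sv <- study$survey
ids <- function(meta, ...) racecline:::ids_of(meta, ...)
sites <- study_config$site_names
reps <- analysis_config$n_reps
seed_of <- function(k) substream_seed(analysis_config$seed, 100 + k)

# per-study response vectors (early - late; 7d - 32d)
dp_of <- function(ex, g) {
  e <- study$experiments[[ex]]
  frequency_difference(e$gl, ids(e$metadata, group = g[1]),
                       ids(e$metadata, group = g[2]))$dp
}
dp_eclosion <- (dp_of("eclosion_apple", c("early", "late")) +
                  dp_of("eclosion_haw", c("early", "late"))) / 2
dp_apple_pw <- dp_of("apple_prewinter", c("pw7d", "pw32d"))
dp_haw_pw <- dp_of("haw_prewinter", c("pw7d", "pw32d"))

# geographic responses (first site - last site) within each race
geo_groups <- function(h) list(
  g1 = ids(sv$metadata, host = h, site = sites[1]),
  g2 = ids(sv$metadata, host = h, site = sites[4]))
dp_geo <- lapply(c(apple = "apple", hawthorn = "hawthorn"), function(h) {
  g <- geo_groups(h)
  frequency_difference(sv$gl, g$g1, g$g2)$dp
})

message("Simple regressions with Monte Carlo significance:")
show <- function(nm, fit)
  message(sprintf("  %-36s r = %+.3f, r2 = %.3f, MC p = %.4g (n = %d SNPs)",
                  nm, fit$r, fit$r2, fit$p, fit$n_snps))
k <- 0
regs <- list()
regs$eclosion_vs_apple_pw <- mc_regression_significance(
  study$experiments$apple_prewinter$gl,
  ids(study$experiments$apple_prewinter$metadata, group = "pw7d"),
  ids(study$experiments$apple_prewinter$metadata, group = "pw32d"),
  predictor = dp_eclosion, n_reps = reps, seed = seed_of(k <- k + 1))
show("eclosion vs apple prewinter", regs$eclosion_vs_apple_pw)
for (h in c("apple", "hawthorn")) {
  g <- geo_groups(h)
  for (st in c("eclosion", "apple_pw", "haw_pw")) {
    x <- switch(st, eclosion = dp_eclosion, apple_pw = dp_apple_pw,
                haw_pw = dp_haw_pw)
    nm <- sprintf("geo_%s_vs_%s", h, st)
    regs[[nm]] <- mc_regression_significance(sv$gl, g$g1, g$g2, predictor = x,
                                             n_reps = reps,
                                             seed = seed_of(k <- k + 1))
    show(nm, regs[[nm]])
  }
}
json_out(regs, "05_simple_regressions.json")

# stepwise-AIC models over mapped SNPs (Table 2/3 analogues)
map <- study$truth$snp_map
pooled_freq <- estimate_allele_freq(sv$gl)
D <- posterior_dosages(sv$gl, pooled_freq)
mld <- mean_linked_ld(D, map)
mapped <- map$chrom != "unmapped"
X <- data.frame(eclosion = dp_eclosion, apple_prewinter = dp_apple_pw,
                haw_prewinter = dp_haw_pw, mean_linked_ld = mld)[mapped, ]

rows <- list()
message("\nStepwise-AIC multiple regressions (mapped SNPs):")
responses <- c(lapply(dp_geo, function(v) v[mapped]),
               setNames(lapply(sites, function(s) {
                 g1 <- ids(sv$metadata, host = "hawthorn", site = s)
                 g2 <- ids(sv$metadata, host = "apple", site = s)
                 frequency_difference(sv$gl, g1, g2)$dp[mapped]
               }), paste0("host_", sites)))
names(responses)[1:2] <- paste0("geo_", names(dp_geo))
for (nm in names(responses)) {
  fit <- stepwise_aic(responses[[nm]], X)
  message(sprintf("  %-14s adj R2 = %.3f, retained: %s", nm, fit$adj_r2,
                  paste(fit$retained, collapse = " + ")))
  co <- as.data.frame(fit$coefficients)
  rows[[nm]] <- data.frame(model = nm, term = rownames(co), co,
                           adj_r2 = fit$adj_r2, F = fit$f, model_p = fit$p,
                           row.names = NULL, check.names = FALSE)
}
tsv(do.call(rbind, rows), "05_stepwise_models.tsv")
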