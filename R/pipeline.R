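#' Configuration for a full pipeline run
#'
#' Bundles the simulation design with the Monte Carlo budgets of every stage.
#' Per-stage seeds are derived from the master seed with [substream_seed()],
#' so a rerun with the same config is numerically identical.
#'
#' @param sim a [sim_config()]; the synthetic study to analyze.
#' @param n_reps Monte Carlo replicates for difference tests and regression
#'   significance.
#' @param boot_reps locus-bootstrap replicates for the NJ network.
#' @param dapc_reps label permutations for DAPC cluster significance.
#' @param mantel_perms Mantel permutations.
#' @param alpha per-SNP test level.
#' @param min_diff strong-diapause SNP threshold on `|dp|`.
#' @param seed master seed for the analysis stages (the simulation uses
#'   `sim$seed`).
#' @param out_dir optional output directory for per-stage TSV/JSON files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_reps = 999,
                            boot_reps = 999, dapc_reps = 999,
                            mantel_perms = 999, alpha = 0.05,
                            min_diff = 0.2, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  needed <- c("eclosion_apple", "eclosion_haw", "apple_prewinter",
              "haw_prewinter")
  missing_ex <- setdiff(needed, names(sim$experiments))
  if (length(missing_ex))
    stopf("config does not define experiment group '%s'", missing_ex[1])
  if (sim$n_sites < 2) stopf("geographic contrast needs >= 2 sites")
  structure(list(sim = sim, n_reps = n_reps, boot_reps = boot_reps,
                 dapc_reps = dapc_reps, mantel_perms = mantel_perms,
                 alpha = alpha, min_diff = min_diff, seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

#' Stratify per-SNP test results by chromosome and LD class
#'
#' Percentage of significant SNPs per chromosome-by-LD-class cell, plus
#' per-chromosome totals, all-mapped totals per class, and the genome-wide
#' total (unmapped SNPs are excluded from chromosome cells but included in
#' the genome-wide row). Empty cells are `NA` with count 0.
#'
#' @param result data frame with `snp_id` and `significant`.
#' @param classes data frame with `snp_id`, `chrom`, `ld_class`.
#' @return data frame `chrom`, `ld_class`, `n`, `n_sig`, `pct_sig`.
#' @export
summarize_by_class <- function(result, classes) {
  m <- merge(result[, c("snp_id", "significant")],
             classes[, c("snp_id", "chrom", "ld_class")], by = "snp_id")
  if (!nrow(m)) stopf("results and map share no SNP ids")
  cell <- function(sel, chrom, cls) {
    n <- sum(sel)
    ns <- sum(m$significant[sel], na.rm = TRUE)
    data.frame(chrom = chrom, ld_class = cls, n = n, n_sig = ns,
               pct_sig = if (n) 100 * ns / sum(sel & !is.na(m$significant))
               else NA_real_, stringsAsFactors = FALSE)
  }
  mapped <- m$chrom != "unmapped"
  chroms <- sort(unique(m$chrom[mapped]))
  clss <- c("high", "intermediate", "low")
  out <- list()
  for (ch in chroms) {
    for (cl in clss)
      out[[length(out) + 1]] <- cell(m$chrom == ch & m$ld_class == cl, ch, cl)
    out[[length(out) + 1]] <- cell(m$chrom == ch & mapped, ch, "all")
  }
  for (cl in clss)
    out[[length(out) + 1]] <- cell(mapped & m$ld_class == cl, "1-5", cl)
  out[[length(out) + 1]] <- cell(mapped, "1-5", "all")
  out[[length(out) + 1]] <- cell(rep(TRUE, nrow(m)), "genome", "all")
  do.call(rbind, out)
}

# Sample ids of one survey population / experiment group (internal).
ids_of <- function(metadata, ...) {
  sel <- rep(TRUE, nrow(metadata))
  crit <- list(...)
  for (nm in names(crit)) sel <- sel & metadata[[nm]] == crit[[nm]]
  metadata$sample_id[sel]
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stages in dependency order: simulate, allele frequencies,
#' LD classes and mean linked LD, Monte Carlo difference tests for every
#' contrast (eclosion, both prewinter experiments, geographic extremes within
#' each race, host pairs at every site), class-stratified significance
#' summaries, cross-experiment and geography/host regressions with Monte
#' Carlo significance, stepwise-AIC multiple regressions, Nei distances,
#' bootstrap NJ network, DAPC with a-score selection and permutation
#' significance, Mantel isolation-by-distance and isolation-by-ecology tests,
#' and interchromosomal composite LD within and between pooled populations.
#' Deterministic given the config seeds.
#'
#' @param config a [pipeline_config()].
#' @param study optionally, a pre-simulated [simulate_study()] result to
#'   reuse (its config must match).
#' @return a report list with sections `design`, `frequencies`, `ld`,
#'   `mc_tests`, `class_summaries`, `regressions`, `stepwise`, `clustering`,
#'   `coupling`.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed_of <- function(k) substream_seed(config$seed, 10L + k)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...)
    message(sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, "secs"),
                    sprintf(fmt, ...)))

  ## stage: simulate -------------------------------------------------------
  log_stage("simulating study (seed %d)", config$sim$seed)
  study <- study %||% simulate_study(config$sim)
  sv <- study$survey
  map <- study$truth$snp_map
  pops <- study$truth$pops
  hosts <- config$sim$hosts            # hosts[1] = derived (apple-like)
  sites <- config$sim$site_names
  ends <- c(sites[1], sites[length(sites)])

  ## stage: frequencies ----------------------------------------------------
  log_stage("estimating per-population allele frequencies")
  pop_ids <- lapply(pops$pop, function(p) ids_of(sv$metadata, pop = p))
  names(pop_ids) <- pops$pop
  freq_tabs <- lapply(pop_ids, function(ids) estimate_allele_freq(sv$gl, ids))
  p_hat <- do.call(cbind, lapply(freq_tabs, `[[`, "p_hat"))
  dimnames(p_hat) <- list(sv$gl$snps, pops$pop)

  ## stage: LD classes -----------------------------------------------------
  log_stage("computing LD classes and mean linked LD")
  pooled_freq <- estimate_allele_freq(sv$gl)
  D_all <- posterior_dosages(sv$gl, pooled_freq)
  classes <- assign_ld_classes(D_all, map)
  mld <- mean_linked_ld(D_all, map)

  ## stage: MC difference tests -------------------------------------------
  mc <- list()
  run_mc <- function(name, gl, g1, g2, k) {
    log_stage("MC difference test: %s", name)
    mc_difference_test(gl, g1, g2, n_reps = config$n_reps,
                       alpha = config$alpha, seed = seed_of(k),
                       retain_null = FALSE)
  }
  exs <- study$experiments
  mc$eclosion_apple <- run_mc("eclosion (apple race)", exs$eclosion_apple$gl,
    ids_of(exs$eclosion_apple$metadata, group = "early"),
    ids_of(exs$eclosion_apple$metadata, group = "late"), 1)
  mc$eclosion_haw <- run_mc("eclosion (hawthorn race)", exs$eclosion_haw$gl,
    ids_of(exs$eclosion_haw$metadata, group = "early"),
    ids_of(exs$eclosion_haw$metadata, group = "late"), 2)
  mc$apple_prewinter <- run_mc("apple prewinter", exs$apple_prewinter$gl,
    ids_of(exs$apple_prewinter$metadata, group = "pw7d"),
    ids_of(exs$apple_prewinter$metadata, group = "pw32d"), 3)
  mc$haw_prewinter <- run_mc("hawthorn prewinter", exs$haw_prewinter$gl,
    ids_of(exs$haw_prewinter$metadata, group = "pw7d"),
    ids_of(exs$haw_prewinter$metadata, group = "pw32d"), 4)
  k <- 5
  for (h in hosts) {
    mc[[paste0("geo_", h)]] <- run_mc(
      sprintf("geographic extremes (%s race)", h), sv$gl,
      ids_of(sv$metadata, host = h, site = ends[1]),
      ids_of(sv$metadata, host = h, site = ends[2]), k)
    k <- k + 1
  }
  for (s in sites) {
    mc[[paste0("host_", s)]] <- run_mc(
      sprintf("host races at %s", s), sv$gl,
      ids_of(sv$metadata, host = hosts[2], site = s),
      ids_of(sv$metadata, host = hosts[1], site = s), k)
    k <- k + 1
  }

  # study-level response vectors (sign conventions: early - late,
  # 7d - 32d, first site - last site, hawthorn - apple)
  dp_eclosion <- (mc$eclosion_apple$result$obs_dp +
                    mc$eclosion_haw$result$obs_dp) / 2
  sig_eclosion <- (mc$eclosion_apple$result$significant %in% TRUE) |
    (mc$eclosion_haw$result$significant %in% TRUE)
  studies <- list(
    eclosion = data.frame(snp_id = sv$gl$snps, dp = dp_eclosion,
                          significant = sig_eclosion),
    apple_prewinter = data.frame(snp_id = sv$gl$snps,
                                 dp = mc$apple_prewinter$result$obs_dp,
                                 significant = mc$apple_prewinter$result$significant),
    haw_prewinter = data.frame(snp_id = sv$gl$snps,
                               dp = mc$haw_prewinter$result$obs_dp,
                               significant = mc$haw_prewinter$result$significant))

  ## stage: class-stratified summaries (geographic tests) ------------------
  class_summaries <- lapply(mc[paste0("geo_", hosts)], function(f)
    summarize_by_class(f$result, classes))
  names(class_summaries) <- paste0("geo_", hosts)

  ## stage: regressions ----------------------------------------------------
  log_stage("cross-experiment and geography/host regressions")
  geo_dp <- lapply(hosts, function(h) mc[[paste0("geo_", h)]]$result$obs_dp)
  names(geo_dp) <- hosts
  host_dp <- lapply(sites, function(s) mc[[paste0("host_", s)]]$result$obs_dp)
  names(host_dp) <- sites

  regressions <- list()
  # experiment vs experiment (Figure 1 analogue)
  regressions$eclosion_vs_apple_pw <- c(
    mc_regression_significance(exs$apple_prewinter$gl,
      ids_of(exs$apple_prewinter$metadata, group = "pw7d"),
      ids_of(exs$apple_prewinter$metadata, group = "pw32d"),
      predictor = dp_eclosion, n_reps = config$n_reps, seed = seed_of(20)))
  regressions$eclosion_vs_haw_pw <- c(
    mc_regression_significance(exs$haw_prewinter$gl,
      ids_of(exs$haw_prewinter$metadata, group = "pw7d"),
      ids_of(exs$haw_prewinter$metadata, group = "pw32d"),
      predictor = dp_eclosion, n_reps = config$n_reps, seed = seed_of(21)))
  # experiments vs geography within each race (Figure 3 analogue)
  kk <- 22
  for (h in hosts) {
    for (st in names(studies)) {
      nm <- sprintf("geo_%s_vs_%s", h, st)
      regressions[[nm]] <- c(mc_regression_significance(sv$gl,
        ids_of(sv$metadata, host = h, site = ends[1]),
        ids_of(sv$metadata, host = h, site = ends[2]),
        predictor = studies[[st]]$dp, n_reps = config$n_reps,
        seed = seed_of(kk)))
      kk <- kk + 1
    }
  }
  # host divergence at each site vs studies and geography (Figure 4 analogue)
  geo_mean_dp <- (geo_dp[[1]] + geo_dp[[2]]) / 2
  host_cor <- do.call(rbind, lapply(sites, function(s) {
    y <- host_dp[[s]]
    preds <- c(list(geography = geo_mean_dp),
               lapply(studies, `[[`, "dp"))
    data.frame(site = s, predictor = names(preds),
               r = vapply(preds, function(x) {
                 ok <- !is.na(x) & !is.na(y)
                 stats::cor(x[ok], y[ok])
               }, numeric(1)), row.names = NULL)
  }))

  ## stage: stepwise models (Tables 2/3 analogue) --------------------------
  log_stage("stepwise-AIC multiple regressions")
  mapped <- map$chrom != "unmapped"
  X <- data.frame(eclosion = studies$eclosion$dp,
                  apple_prewinter = studies$apple_prewinter$dp,
                  haw_prewinter = studies$haw_prewinter$dp,
                  mean_linked_ld = mld)[mapped, ]
  stepwise <- list()
  for (h in hosts)
    stepwise[[paste0("geo_", h)]] <- stepwise_aic(geo_dp[[h]][mapped], X)
  for (s in sites)
    stepwise[[paste0("host_", s)]] <- stepwise_aic(host_dp[[s]][mapped], X)

  ## stage: clustering -----------------------------------------------------
  log_stage("Nei distances, NJ bootstrap, DAPC, Mantel tests")
  nei_all <- nei_distance(p_hat)
  strong <- select_strong_diapause_snps(studies, min_diff = config$min_diff)
  nei_strong <- if (length(strong) >= 2)
    nei_distance(p_hat[strong, , drop = FALSE]) else NULL
  njb <- bootstrap_nj(p_hat, n_reps = config$boot_reps, seed = seed_of(30))

  pred <- build_predictor_matrices(pops)
  mantel <- list(
    ibd = mantel_test(nei_all, pred$geo, n_perm = config$mantel_perms,
                      seed = seed_of(31)),
    ibe = mantel_test(nei_all, pred$host, n_perm = config$mantel_perms,
                      seed = seed_of(32)))

  dapc <- list()
  kk <- 40
  run_dapc <- function(ids, labels, nm) {
    Dsub <- D_all[ids, , drop = FALSE]
    asc <- optimize_a_score(Dsub, labels, seed = seed_of(kk)); kk <<- kk + 1
    fit <- dapc_fit(Dsub, labels, n_pca = asc$best_m)
    sig <- cluster_significance(fit, n_reps = config$dapc_reps,
                                seed = seed_of(kk)); kk <<- kk + 1
    list(name = nm, n_pca = asc$best_m, a_score = asc$curve,
         assign_mean = fit$assign_mean, p = sig$p,
         eig_shares = fit$eig_shares)
  }
  for (s in sites) {
    ids <- ids_of(sv$metadata, site = s)
    dapc[[paste0("host_", s)]] <- run_dapc(
      ids, sv$metadata$host[match(ids, sv$metadata$sample_id)],
      sprintf("host races at %s", s))
  }
  ids <- c(ids_of(sv$metadata, host = hosts[2], site = ends[1]),
           ids_of(sv$metadata, host = hosts[2], site = ends[2]))
  dapc$geo_haw <- run_dapc(
    ids, sv$metadata$site[match(ids, sv$metadata$sample_id)],
    "hawthorn race, geographic extremes")
  ids <- unlist(lapply(ends, function(s) ids_of(sv$metadata, site = s)))
  dapc$k4 <- run_dapc(
    ids, sv$metadata$pop[match(ids, sv$metadata$sample_id)],
    "both races at the geographic extremes (k = 4)")

  ## stage: coupling LD ----------------------------------------------------
  log_stage("interchromosomal LD within and between pooled populations (%d strong SNPs)",
            length(strong))
  coupling <- NULL
  if (length(strong) >= 2 &&
      length(unique(map$chrom[map$snp_id %in% strong & mapped])) >= 2) {
    within_groups <- lapply(pop_ids, function(ids) D_all[ids, , drop = FALSE])
    host_pools <- lapply(sites, function(s)
      D_all[ids_of(sv$metadata, site = s), , drop = FALSE])
    names(host_pools) <- paste0("pooled_", sites)
    geo_pool <- list(pooled_haw_extremes = D_all[
      c(ids_of(sv$metadata, host = hosts[2], site = ends[1]),
        ids_of(sv$metadata, host = hosts[2], site = ends[2])), , drop = FALSE])
    coupling <- list(
      within = interchromosomal_ld(within_groups, map, strong),
      host_pooled = interchromosomal_ld(host_pools, map, strong),
      geo_pooled = interchromosomal_ld(geo_pool, map, strong))
  }

  report <- list(
    design = list(seed = config$seed, sim_seed = config$sim$seed,
                  n_reps = config$n_reps, alpha = config$alpha,
                  n_snps = config$sim$n_snps, pops = pops$pop),
    frequencies = list(p_hat = p_hat, tables = freq_tabs),
    ld = list(classes = classes, mean_linked_ld = mld),
    mc_tests = mc,
    studies = studies,
    class_summaries = class_summaries,
    regressions = regressions,
    host_correlations = host_cor,
    stepwise = stepwise,
    clustering = list(nei_all = nei_all, nei_strong = nei_strong,
                      nj = njb, mantel = mantel, dapc = dapc,
                      strong_snps = strong),
    coupling = coupling)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  log_stage("pipeline complete")
  invisible(report)
}

#' Write the machine-readable pieces of a pipeline report
#'
#' Emits per-stage TSV tables and a JSON summary under `dir`. Every number in
#' the summary is taken from a stage output, not recomputed.
#'
#' @param report result of [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(data.frame(snp_id = rownames(report$frequencies$p_hat),
                 report$frequencies$p_hat, check.names = FALSE),
      "allele_frequencies.tsv")
  tsv(report$ld$classes, "ld_classes.tsv")
  for (nm in names(report$mc_tests))
    tsv(report$mc_tests[[nm]]$result, sprintf("mc_%s.tsv", nm))
  for (nm in names(report$class_summaries))
    tsv(report$class_summaries[[nm]], sprintf("class_summary_%s.tsv", nm))
  tsv(report$host_correlations, "host_correlations.tsv")
  ape::write.tree(report$clustering$nj, file.path(dir, "nj_network.nwk"))
  tsv(as.data.frame(report$clustering$nei_all), "nei_distances.tsv")
  summary <- list(
    design = report$design,
    tablewise = lapply(report$mc_tests, function(f)
      f$tablewise[c("pct_sig", "p", "excess")]),
    regressions = report$regressions,
    stepwise = lapply(report$stepwise, function(s)
      s[c("retained", "adj_r2", "f", "p", "aic", "n")]),
    mantel = report$clustering$mantel,
    dapc = lapply(report$clustering$dapc, function(d)
      d[c("name", "n_pca", "assign_mean", "p")]),
    coupling = if (!is.null(report$coupling))
      lapply(report$coupling, `[[`, "summary"))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
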