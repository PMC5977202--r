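# Shared setup for the numbered analysis drivers. Everything is
# deterministic given the seeds below; drivers can be run in order or
# individually.

library(racecline)

SEED <- 20260101L
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

study_config <- sim_config(seed = SEED)   # default synthetic study design
analysis_config <- pipeline_config(
  sim = study_config,
  n_reps = 1999, boot_reps = 1999, dapc_reps = 1999, mantel_perms = 4999,
  seed = SEED + 1L)

# The simulated study (fast; regenerated identically in every driver).
get_study <- function() simulate_study(study_config)

tsv <- function(x, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}

json_out <- function(x, name) {
  path <- file.path(RESULTS, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  message("  wrote ", path)
}
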