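# Shared configuration for the analysis workflow.  Scripts 01..06 run in
# order; each caches its intermediates under scratch/ and writes its tables
# under results/.

library(rsaid)

demo_config <- cohort_config(
  n_participants = 12,   # desk-scale cohort; the study design uses 26
  n_scenarios = 20, n_runs = 5, n_attributes = 20,
  grid_dims = c(6, 6, 6), n_rois = 4,
  idiosyncrasy = 0.5,    # half of the scenario-latent variance is personal
  seed = 42)

scratch_dir <- "scratch"
results_dir <- "results"
dir.create(scratch_dir, showWarnings = FALSE)
dir.create(results_dir, showWarnings = FALSE)

cache_path <- function(name) file.path(scratch_dir, paste0(name, ".rds"))

load_cache <- function(name) {
  path <- cache_path(name)
  if (!file.exists(path)) {
    stop("missing ", path, ": run the earlier analysis scripts first")
  }
  readRDS(path)
}

write_tsv <- function(df, name) {
  path <- file.path(results_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
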