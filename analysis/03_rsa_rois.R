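#!/usr/bin/env Rscript
# Stage 3: voxel prep and ROI selection.
#
# For every participant: z-scored nuisance regression (6 motion parameters
# + linear trend) per run, averaging of the four volumes 5-15 s after each
# onset, inter-run stability scoring, top-100 stable voxels per ROI, and
# replicate-averaged normalized scenario patterns.  ROIs whose fMRI
# similarity structure matches the leave-one-out group-average models
# (one-tailed t over participants, FDR across ROIs) are selected for the
# person-specific analyses.

source("analysis/00_common.R")
cohort <- load_cache("cohort")
models <- load_cache("models")
mm <- lapply(models, `[[`, "multimodal")
group_sims <- lapply(seq_along(mm), function(p) group_average_loo(mm, p))
saveRDS(group_sims, cache_path("group_sims"))

message("preparing scenario patterns (stability-selected voxels, k = 100)")
prep <- lapply(cohort$runs, function(pr) {
  prepare_participant(pr, cohort$roi_labels, cohort$config$n_scenarios,
                      tr_seconds = cohort$config$tr_seconds, voxel_k = 100)
})
fmri_sims <- lapply(prep, function(pr) {
  lapply(pr$roi_patterns, function(sp) {
    similarity_vector(sp$patterns, source = "fmri")
  })
})
saveRDS(fmri_sims, cache_path("fmri_sims"))

sel <- select_rois_group_model(fmri_sims, group_sims, fdr_q = 0.05)
message("ROIs selected against G-1 models: ",
        paste(sel$selected, collapse = ", "))
print(sel$table, digits = 3)
write_tsv(sel$table, "roi_selection.tsv")
saveRDS(sel, cache_path("roi_selection"))
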