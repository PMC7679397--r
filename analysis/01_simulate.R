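#!/usr/bin/env Rscript
# Stage 1: simulate the cohort.
#
# Generates a synthetic imagined-scenario cohort in which every
# participant's scenario geometry is half group-common and half personal
# (idiosyncrasy 0.5), with voxel runs, motion tables, Likert attribute
# ratings and word-list descriptions, then reports the generator's ground
# truth.  The cohort is cached for the later stages and also exported to
# disk in standard formats as a demonstration of the real-data layout.

source("analysis/00_common.R")

message("generating cohort: ", demo_config$n_participants,
        " participants x ", demo_config$n_scenarios, " scenarios x ",
        demo_config$n_runs, " runs")
cohort <- generate_cohort(demo_config)
saveRDS(cohort, cache_path("cohort"))

truth <- ground_truth_report(cohort)
message(sprintf("ground truth: lambda = %.2f, voxel-channel SNR = %.3f, rating-channel SNR = %.2f",
                truth$idiosyncrasy, truth$snr[["voxel"]], truth$snr[["rating"]]))

# how similar are participants' true scenario geometries?
pairs <- combn(demo_config$n_participants, 2)
truth_agreement <- mean(vapply(seq_len(ncol(pairs)), function(k) {
  cor(truth$participant_similarity[[pairs[1, k]]],
      truth$participant_similarity[[pairs[2, k]]])
}, numeric(1)))
message(sprintf("mean true inter-participant geometry correlation: %.3f", truth_agreement))

export_dir <- file.path(scratch_dir, "cohort_on_disk")
write_cohort(cohort, export_dir)
message("exported NIfTI/TSV/text copy to ", export_dir)
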