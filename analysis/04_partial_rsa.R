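#!/usr/bin/env Rscript
# Stage 4: partial RSA.
#
# In each selected ROI, correlates every participant's fMRI similarity
# vector with their own multimodal model while controlling for the
# leave-one-out group-average model (Spearman partial correlation), tests
# each coefficient with the residual-shuffle permutation scheme (1000
# shuffles), and summarizes across participants with a one-tailed t-test
# (Cohen's d = t / sqrt(n)), FDR over ROIs, and the cumulative binomial
# count of individually significant participants.

source("analysis/00_common.R")
cohort <- load_cache("cohort")
models <- load_cache("models")
fmri_sims <- load_cache("fmri_sims")
group_sims <- load_cache("group_sims")
sel <- load_cache("roi_selection")
mm <- lapply(models, `[[`, "multimodal")
P <- cohort$config$n_participants

rows <- lapply(sel$selected, function(roi) {
  per_p <- lapply(seq_len(P), function(p) {
    partial_rsa_permutation_test(fmri_sims[[p]][[roi]], mm[[p]],
                                 group_sims[[p]], n_perm = 1000,
                                 seed = 42000 + p)
  })
  z <- vapply(per_p, `[[`, numeric(1), "z")
  p_perm <- vapply(per_p, `[[`, numeric(1), "p_perm")
  gt <- one_sample_group_test(z)
  n_sig <- sum(p_perm < 0.05)
  data.frame(roi = roi, mean_z = mean(z), t = gt$t, p_raw = gt$p,
             cohens_d = gt$cohens_d, n_individually_significant = n_sig,
             binomial_tail = binomial_tail(P, 0.05, n_sig))
})
tab <- do.call(rbind, rows)
tab$p_fdr <- fdr_adjust(tab$p_raw)

message("partial RSA (personal model vs fMRI, controlling G-1):")
print(tab, digits = 3)
write_tsv(tab, "partial_rsa.tsv")
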