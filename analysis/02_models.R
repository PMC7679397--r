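#!/usr/bin/env Rscript
# Stage 2: personal models.
#
# Builds each participant's verbal model (additive composition of word
# embeddings over the content words of their descriptions) and attribute
# model (within-participant standardized Likert ratings), fuses them into
# multimodal similarity vectors, and quantifies how much representational
# structure participants share (all-pairs Spearman RSA between personal
# multimodal models).

source("analysis/00_common.R")
cohort <- load_cache("cohort")

models <- build_personal_models(cohort$ratings, cohort$descriptions,
                                cohort$vocab)
saveRDS(models, cache_path("models"))
mm <- lapply(models, `[[`, "multimodal")

agreement <- cross_participant_model_agreement(mm)
message(sprintf(
  "cross-participant model agreement: mean rho = %.3f +/- %.3f over %d pairs (t = %.1f, p = %.2g)",
  agreement$mean_rho, agreement$sd_rho, agreement$n_pairs, agreement$t,
  agreement$p))

write_tsv(data.frame(mean_rho = agreement$mean_rho,
                     sd_rho = agreement$sd_rho, t = agreement$t,
                     p = agreement$p, n_pairs = agreement$n_pairs),
          "model_agreement.tsv")
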