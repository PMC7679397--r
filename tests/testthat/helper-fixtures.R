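# Shared fixtures: tiny seeded cohorts and similarity-vector sets built in
# code at test time.

# A small, fast cohort configuration; individual tests override fields.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 6, n_scenarios = 10, n_runs = 3,
                   n_attributes = 12, grid_dims = c(4, 4, 4), n_rois = 2,
                   latent_dim = 4, vocab_size = 40, embed_dim = 12,
                   words_per_description = 5, seed = 1)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# Random similarity vectors of a valid triangle length, seeded.
random_sims <- function(n, s = 10, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) stats::rnorm(s * (s - 1) / 2))
  })
}

# Similarity vectors derived from random pattern matrices (guaranteed to be
# genuine correlation triangles).
pattern_sims <- function(n, s = 10, f = 8, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      similarity_vector(matrix(stats::rnorm(s * f), s))
    })
  })
}

# Spearman via explicit rank-then-Pearson, as an independent route.
spearman_oracle <- function(a, b) {
  stats::cor(rank(a), rank(b), method = "pearson")
}
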