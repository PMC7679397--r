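test_that("configuration invariants are enforced", {
  expect_s3_class(small_config(), "cohort_config")
  expect_error(small_config(idiosyncrasy = 1.2), "\\[0, 1\\]")
  expect_error(small_config(n_scenarios = 2), "at least 3")
  expect_error(small_config(n_runs = 1), "at least 2")
  expect_error(small_config(vocab_size = 2, latent_dim = 4), "latent_dim")
  expect_error(small_config(n_rois = 40), "slabs")
  expect_error(small_config(signal_rois = 5), "signal_rois")
  expect_error(small_config(noise_sd = -1), "non-negative")
})

test_that("the vocabulary embedding is topic-structured and seeded", {
  v1 <- generate_vocabulary_embedding(100, 8, n_topics = 4, seed = 1)
  v2 <- generate_vocabulary_embedding(100, 8, n_topics = 4, seed = 1)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  expect_true(all(sqrt(rowSums(v1^2)) > 0))

  # exhaustive pairwise check on a 20-word vocabulary: every within-topic
  # cosine exceeds every across-topic cosine
  v <- generate_vocabulary_embedding(20, 8, n_topics = 4, seed = 2)
  topic <- attr(v, "topic")
  vn <- v / sqrt(rowSums(v^2))
  cos <- tcrossprod(vn)
  within <- cos[outer(topic, topic, `==`) & upper.tri(cos)]
  across <- cos[outer(topic, topic, `!=`) & upper.tri(cos)]
  expect_gt(min(within), max(across))

  expect_error(generate_vocabulary_embedding(0, 8), "positive")
  expect_error(generate_vocabulary_embedding(10, 1), "at least 2")
  expect_error(generate_vocabulary_embedding(3, 8, n_topics = 5), ">= n_topics")
})

test_that("cohorts are bitwise reproducible from their seed", {
  cf <- small_config(seed = 9)
  c1 <- generate_cohort(cf)
  c2 <- generate_cohort(cf)
  expect_identical(c1$runs, c2$runs)
  expect_identical(c1$ratings, c2$ratings)
  expect_identical(c1$descriptions, c2$descriptions)
  expect_identical(c1$vocab, c2$vocab)
  # a different seed changes the data
  c3 <- generate_cohort(small_config(seed = 10))
  expect_false(identical(c1$runs[[1]][[1]]$data, c3$runs[[1]][[1]]$data))
})

test_that("generated channels satisfy their structural invariants", {
  cf <- small_config(seed = 3)
  co <- generate_cohort(cf)
  for (p in seq_len(cf$n_participants)) {
    rat <- co$ratings[[p]]
    expect_true(all(rat == round(rat) & rat >= 0 & rat <= 6))
    expect_true(all(nzchar(co$descriptions[[p]])))
    for (r in seq_len(cf$n_runs)) {
      on <- co$runs[[p]][[r]]$onsets
      # a valid randomized order of all scenarios within the run
      expect_setequal(on$scenario, seq_len(cf$n_scenarios))
      expect_true(all(diff(on$volume) > 0))
      expect_equal(nrow(co$runs[[p]][[r]]$motion),
                   nrow(co$runs[[p]][[r]]$data))
    }
  }
  expect_length(co$roi_labels, prod(cf$grid_dims))
  expect_setequal(unique(co$roi_labels), seq_len(cf$n_rois))

  # dropping the initial presentation removes one replicate in run 1 only
  cod <- generate_cohort(small_config(seed = 3, drop_first_presentation = TRUE))
  expect_equal(nrow(cod$runs[[1]][[1]]$onsets), cf$n_scenarios - 1L)
  expect_equal(nrow(cod$runs[[1]][[2]]$onsets), cf$n_scenarios)
})

test_that("idiosyncrasy controls how much participants share", {
  # lambda = 0, noiseless: all participants carry identical latents and
  # identical behavioral channels; model agreement is exactly 1
  cf0 <- small_config(idiosyncrasy = 0, noise_sd = 0, rating_noise_sd = 0,
                      embed_noise_sd = 0, motion_sd = 0, drift_slope = 0,
                      seed = 5)
  co0 <- generate_cohort(cf0)
  expect_equal(co0$truth$participant_latents[[1]],
               co0$truth$participant_latents[[2]])
  expect_identical(co0$ratings[[1]], co0$ratings[[2]])
  expect_identical(co0$descriptions[[1]], co0$descriptions[[2]])
  tr0 <- ground_truth_report(co0)
  expect_equal(cor(tr0$participant_similarity[[1]],
                   tr0$participant_similarity[[3]]), 1)

  # lambda = 1: personal latents are independent; the average cross-
  # participant similarity-structure correlation is near zero
  cf1 <- small_config(idiosyncrasy = 1, n_participants = 10,
                      n_scenarios = 15, seed = 6)
  tr1 <- ground_truth_report(generate_cohort(cf1))
  pairs <- combn(10, 2)
  agree <- mean(vapply(seq_len(ncol(pairs)), function(k) {
    cor(tr1$participant_similarity[[pairs[1, k]]],
        tr1$participant_similarity[[pairs[2, k]]])
  }, numeric(1)))
  expect_lt(abs(agree), 0.12)
})

test_that("the ground-truth report matches independent recomputation", {
  cf <- small_config(seed = 7)
  co <- generate_cohort(cf)
  rep_ <- ground_truth_report(co)
  expect_equal(rep_$idiosyncrasy, cf$idiosyncrasy)

  # group latent similarity triangle via an explicit pair loop
  g <- co$truth$group_latent
  s <- nrow(g)
  oracle <- c()
  for (j in 1:(s - 1)) for (i in (j + 1):s) {
    oracle <- c(oracle, cor(g[i, ], g[j, ]))
  }
  expect_equal(rep_$group_similarity, oracle, tolerance = 1e-12)

  # noiseless voxel channel: SNR flagged infinite
  co_inf <- generate_cohort(small_config(noise_sd = 0, seed = 7))
  expect_true(is.infinite(ground_truth_report(co_inf)$snr[["voxel"]]))
  expect_error(ground_truth_report(list()), "generate_cohort")
})

test_that("decoding accuracy grows with the idiosyncrasy share", {
  lams <- c(0, 0.5, 1)
  mean_acc <- vapply(lams, function(lam) {
    accs <- vapply(1:6, function(s) {
      cf <- small_config(n_participants = 6, idiosyncrasy = lam,
                         seed = 100 + s)
      co <- generate_cohort(cf)
      models <- build_personal_models(co$ratings, co$descriptions, co$vocab)
      mm <- lapply(models, `[[`, "multimodal")
      prep <- lapply(co$runs, function(pr) {
        prepare_participant(pr, co$roi_labels, cf$n_scenarios, voxel_k = 100)
      })
      fmri <- lapply(prep, function(pr) {
        similarity_vector(pr$roi_patterns[[1]]$patterns)
      })
      decode_cohort(mm, fmri)$accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) > 0))
  expect_gt(mean_acc[3], 60)
})
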