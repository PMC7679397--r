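# End-to-end orchestration: one participant's voxel prep, the personal and
# group model construction, and the full cohort analysis (ROI selection,
# partial RSA, decoding, optional searchlight) over either a generated
# cohort or data read from disk.

#' Prepare one participant's scenario patterns
#'
#' Runs the voxel-level pipeline for a single participant: nuisance
#' regression per run, response-window averaging per presentation,
#' inter-run stability scoring, top-k voxel selection per ROI, and
#' replicate-averaged normalized scenario patterns per ROI.  Stability is
#' computed over the scenarios present in every run (all of them unless a
#' presentation was dropped with the initial volumes).
#'
#' @param p_runs list over runs: each `list(data, motion, onsets)`.
#' @param roi_labels integer voxel -> ROI map.
#' @param n_scenarios total number of scenarios.
#' @param tr_seconds repetition time (s).
#' @param window response window in seconds (default `c(5, 15)`).
#' @param voxel_k stable voxels kept per ROI (default 100).
#' @param keep_full also return the normalized full-grid pattern matrix
#'   (needed for searchlight analyses).
#' @param stability_undefined policy for undefined stability correlations
#'   (see [voxel_stability()]).
#' @return list with `roi_patterns` (per-ROI `scenario_patterns`),
#'   `stability`, `selected`, and optionally `full_patterns`.
#' @export
prepare_participant <- function(p_runs, roi_labels, n_scenarios,
                                tr_seconds = 2.5, window = c(5, 15),
                                voxel_k = 100, keep_full = FALSE,
                                stability_undefined = "zero") {
  pres <- lapply(p_runs, function(run) {
    res <- regress_nuisance(run$data, run$motion)
    average_scenario_window(res, run$onsets, tr_seconds, window)
  })
  scen_lists <- lapply(pres, `[[`, "scenario")
  common <- Reduce(intersect, scen_lists)
  if (length(common) < 3) stop("fewer than 3 scenarios shared across runs")
  run_mats <- lapply(pres, function(x) {
    x$patterns[match(common, x$scenario), , drop = FALSE]
  })
  stab <- voxel_stability(run_mats, undefined = stability_undefined)
  selected <- select_stable_voxels(stab, roi_labels, k = voxel_k)
  all_pres <- do.call(rbind, lapply(pres, `[[`, "patterns"))
  all_scen <- unlist(scen_lists, use.names = FALSE)
  levels <- seq_len(n_scenarios)
  roi_patterns <- lapply(names(selected), function(roi) {
    build_scenario_patterns(all_pres, all_scen, voxels = selected[[roi]],
                            roi_id = roi, scenario_levels = levels)
  })
  names(roi_patterns) <- names(selected)
  out <- list(roi_patterns = roi_patterns, stability = stab,
              selected = selected)
  if (keep_full) {
    out$full_patterns <- build_scenario_patterns(
      all_pres, all_scen, roi_id = "full", scenario_levels = levels)$patterns
  }
  out
}

#' Build the personal model similarity vectors for every participant
#'
#' For each participant: ratings are standardized within participant and
#' the verbal matrix is composed from the descriptions, then each channel
#' is taken to similarity space and the two are fused into the multimodal
#' model.
#'
#' @param ratings list of per-participant S x A raw rating matrices.
#' @param descriptions list of per-participant character vectors (one
#'   description per scenario).
#' @param lexicon word-embedding matrix.
#' @param stoplist stopword vector for content-word extraction.
#' @return list per participant with `attribute`, `verbal`, `multimodal`
#'   similarity vectors and the underlying `attribute_matrix`,
#'   `verbal_matrix`.
#' @export
build_personal_models <- function(ratings, descriptions, lexicon,
                                  stoplist = default_stoplist()) {
  P <- length(ratings)
  if (length(descriptions) != P) stop("ratings/descriptions misaligned")
  lapply(seq_len(P), function(p) {
    am <- normalize_attribute_ratings(ratings[[p]])
    vm <- verbal_matrix(descriptions[[p]], lexicon, stoplist)$values
    a_sim <- similarity_vector(am, source = "attribute")
    v_sim <- similarity_vector(vm, source = "verbal")
    list(attribute = a_sim, verbal = v_sim,
         multimodal = fuse_multimodal(v_sim, a_sim),
         attribute_matrix = am, verbal_matrix = vm)
  })
}

# Hash of an R object via its canonical JSON serialization; identifies a
# configuration in manifests and output tables.
.hash_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# The shared analysis core behind run_synthetic_demo() and run_real().
.run_pipeline <- function(data, voxel_k, window, n_perm_rsa, n_perm_decode,
                          fdr_q, seed, searchlight, searchlight_radius,
                          searchlight_min_voxels = 10) {
  cf <- data$config
  P <- cf$n_participants
  S <- cf$n_scenarios
  if (is.null(seed)) seed <- (if (!is.null(cf$seed)) cf$seed else 0) + 10000L
  seed <- as.integer(seed %% .Machine$integer.max)

  message("stage: personal models (", P, " participants)")
  models <- build_personal_models(data$ratings, data$descriptions, data$vocab)
  mm_sims <- lapply(models, `[[`, "multimodal")
  group_sims <- lapply(seq_len(P), function(p) {
    group_average_loo(mm_sims, exclude = p)
  })

  message("stage: voxel prep and fMRI similarity vectors")
  prep <- lapply(seq_len(P), function(p) {
    prepare_participant(data$runs[[p]], data$roi_labels, S,
                        tr_seconds = cf$tr_seconds, window = window,
                        voxel_k = voxel_k, keep_full = searchlight)
  })
  fmri_sims <- lapply(prep, function(pr) {
    lapply(pr$roi_patterns, function(sp) {
      similarity_vector(sp$patterns, source = "fmri")
    })
  })
  fmri_corr <- lapply(prep, function(pr) {
    lapply(pr$roi_patterns, function(sp) stats::cor(t(sp$patterns)))
  })

  message("stage: ROI selection against G-1 models")
  roi_sel <- select_rois_group_model(fmri_sims, group_sims, fdr_q = fdr_q)
  sel_rois <- roi_sel$selected

  message("stage: partial RSA in ", length(sel_rois), " selected ROI(s)")
  partial <- lapply(sel_rois, function(roi) {
    per_p <- lapply(seq_len(P), function(p) {
      partial_rsa_permutation_test(
        fmri_sims[[p]][[roi]], mm_sims[[p]], group_sims[[p]],
        n_perm = n_perm_rsa, seed = seed + p)
    })
    z <- vapply(per_p, `[[`, numeric(1), "z")
    p_perm <- vapply(per_p, `[[`, numeric(1), "p_perm")
    gt <- one_sample_group_test(z)
    n_sig <- sum(p_perm < 0.05)
    list(roi = roi, z = z, p_perm = p_perm, group = gt,
         n_individually_significant = n_sig,
         binomial_tail = binomial_tail(P, 0.05, n_sig))
  })
  names(partial) <- sel_rois
  partial_table <- do.call(rbind, lapply(partial, function(x) {
    data.frame(roi = x$roi, t = x$group$t, p_raw = x$group$p,
               cohens_d = x$group$cohens_d,
               n_individually_significant = x$n_individually_significant,
               binomial_tail = x$binomial_tail)
  }))
  if (!is.null(partial_table)) {
    partial_table$p_fdr <- fdr_adjust(partial_table$p_raw)
  }

  message("stage: pairwise identity decoding")
  decoding <- lapply(sel_rois, function(roi) {
    roi_fmri <- lapply(fmri_sims, `[[`, roi)
    decoding_permutation_test(mm_sims, roi_fmri, n_perm = n_perm_decode,
                              seed = seed + 5000L)
  })
  names(decoding) <- sel_rois
  model_only <- model_only_decode(lapply(models, `[[`, "verbal"),
                                  lapply(models, `[[`, "attribute"))
  agreement <- cross_participant_model_agreement(mm_sims)

  maps <- NULL
  if (searchlight) {
    message("stage: searchlight maps (radius ", searchlight_radius, ")")
    full <- lapply(prep, `[[`, "full_patterns")
    grid_dims <- cf$grid_dims
    mask <- which(data$roi_labels != 0)
    g_map <- searchlight_map(full, group_sims, grid_dims, mask = mask,
                             radius = searchlight_radius, mode = "rsa_group",
                             min_voxels = searchlight_min_voxels,
                             fdr_q = fdr_q)
    p_map <- searchlight_map(full, mm_sims, grid_dims, mask = mask,
                             radius = searchlight_radius,
                             mode = "rsa_personal",
                             min_voxels = searchlight_min_voxels,
                             fdr_q = fdr_q)
    pt_map <- if (length(g_map$significant) > 0) {
      searchlight_map(full, mm_sims, grid_dims, mask = mask,
                      radius = searchlight_radius, mode = "partial",
                      group_sims = group_sims,
                      restrict_to = g_map$significant,
                      min_voxels = searchlight_min_voxels, fdr_q = fdr_q)
    }
    maps <- list(group = g_map, personal = p_map, partial = pt_map)
  }

  params <- list(voxel_k = voxel_k, window = window,
                 n_perm_rsa = n_perm_rsa, n_perm_decode = n_perm_decode,
                 fdr_q = fdr_q, seed = seed, searchlight = searchlight,
                 searchlight_radius = searchlight_radius)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rsaid")),
    config_hash = .hash_obj(cf), params_hash = .hash_obj(params),
    params = params)
  list(models = models, group_sims = group_sims, fmri_sims = fmri_sims,
       fmri_corr = fmri_corr, prep = prep, roi_selection = roi_sel,
       partial = partial, partial_table = partial_table,
       decoding = decoding, model_only = model_only, agreement = agreement,
       searchlight = maps, manifest = manifest)
}

#' Run the full analysis on a synthetic cohort
#'
#' Generates (or takes) a synthetic cohort and runs every stage: personal
#' model construction, voxel prep, ROI selection against leave-one-out
#' group-average models, partial RSA with its residual-shuffle permutation
#' test in the selected ROIs, pairwise identity decoding with its
#' permutation test, the model-only decoding context analysis,
#' cross-participant model agreement, and (optionally) the searchlight
#' maps.  Progress is logged to stderr per stage.
#'
#' @param config a [cohort_config()], or an already generated
#'   `synthetic_cohort`.
#' @param voxel_k stable voxels per ROI (default 100).
#' @param window response window in seconds.
#' @param n_perm_rsa permutations for the (partial) RSA tests (default
#'   1000).
#' @param n_perm_decode permutations for the decoding test (default
#'   10,000).
#' @param fdr_q FDR threshold for selection/inference (default 0.05).
#' @param searchlight run the searchlight stage (default FALSE).
#' @param searchlight_radius cube radius in voxels (default 3).
#' @param searchlight_min_voxels smallest in-mask cube analyzed (default 10).
#' @param seed base seed for the permutation tests; defaults to a value
#'   derived from the cohort seed so reruns are identical.
#' @param out_dir if given, result tables and the manifest are written
#'   there via [write_results()].
#' @return the result bundle (a list; see [.run_pipeline] components), with
#'   `cohort` attached.
#' @export
run_synthetic_demo <- function(config = cohort_config(), voxel_k = 100,
                               window = c(5, 15), n_perm_rsa = 1000,
                               n_perm_decode = 10000, fdr_q = 0.05,
                               searchlight = FALSE, searchlight_radius = 3,
                               searchlight_min_voxels = 10,
                               seed = NULL, out_dir = NULL) {
  cohort <- if (inherits(config, "synthetic_cohort")) config else {
    message("stage: generating synthetic cohort")
    generate_cohort(config)
  }
  bundle <- .run_pipeline(cohort, voxel_k = voxel_k, window = window,
                          n_perm_rsa = n_perm_rsa,
                          n_perm_decode = n_perm_decode, fdr_q = fdr_q,
                          seed = seed, searchlight = searchlight,
                          searchlight_radius = searchlight_radius,
                          searchlight_min_voxels = searchlight_min_voxels)
  bundle$cohort <- cohort
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' Run the full analysis on data read from disk
#'
#' Same stage sequence as [run_synthetic_demo()], on inputs laid out as
#' described in [read_cohort_data()] (preprocessed 4D runs, motion tables,
#' events, atlas, ratings, descriptions, embedding table).
#'
#' @param data_dir data directory.
#' @param n_participants,n_runs expected counts.
#' @param tr_seconds repetition time of the runs.
#' @inheritParams run_synthetic_demo
#' @return the result bundle.
#' @export
run_real <- function(data_dir, n_participants, n_runs, tr_seconds = 2.5,
                     voxel_k = 100, window = c(5, 15), n_perm_rsa = 1000,
                     n_perm_decode = 10000, fdr_q = 0.05,
                     searchlight = FALSE, searchlight_radius = 3,
                     searchlight_min_voxels = 10,
                     seed = NULL, out_dir = NULL) {
  message("stage: reading cohort data from ", data_dir)
  data <- read_cohort_data(data_dir, n_participants, n_runs, tr_seconds)
  bundle <- .run_pipeline(data, voxel_k = voxel_k, window = window,
                          n_perm_rsa = n_perm_rsa,
                          n_perm_decode = n_perm_decode, fdr_q = fdr_q,
                          seed = seed, searchlight = searchlight,
                          searchlight_radius = searchlight_radius,
                          searchlight_min_voxels = searchlight_min_voxels)
  bundle$data = data
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' Write the result tables of an analysis bundle
#'
#' Exports the per-ROI selection table, the partial-RSA summary, the
#' decoding summaries, the model agreement summary and the manifest.  Every
#' table carries the configuration hash in a leading comment line.
#'
#' @param bundle a result bundle from [run_synthetic_demo()] or
#'   [run_real()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s params_hash=%s",
                   bundle$manifest$config_hash,
                   bundle$manifest$params_hash)
  put <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
  }
  put(bundle$roi_selection$table, "roi_selection.tsv")
  if (!is.null(bundle$partial_table)) {
    put(bundle$partial_table, "partial_rsa.tsv")
  }
  if (length(bundle$decoding) > 0) {
    dec <- do.call(rbind, lapply(names(bundle$decoding), function(roi) {
      d <- bundle$decoding[[roi]]
      data.frame(roi = roi, accuracy = d$accuracy, p_perm = d$p_perm,
                 n_pairs = d$n_pairs, n_perm = d$n_perm)
    }))
    put(dec, "decoding.tsv")
  }
  put(data.frame(accuracy = bundle$model_only$accuracy,
                 n_pairs = bundle$model_only$n_pairs), "model_only.tsv")
  ag <- bundle$agreement
  put(data.frame(mean_rho = ag$mean_rho, sd_rho = ag$sd_rho, t = ag$t,
                 p = ag$p, n_pairs = ag$n_pairs), "model_agreement.tsv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
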