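#' Configuration for a synthetic imagined-scenario cohort
#'
#' Collects the design parameters of a simulated study: 26 participants
#' imagining 20 scenarios over 5 runs at TR 2.5 s with 3 stimulus volumes
#' followed by 3 fixation volumes, rating each scenario on 20 experiential
#' attributes (0--6 Likert) and describing it in words drawn from a small
#' synthetic vocabulary.  Every participant's scenario representation is a
#' mixture of a group-common latent geometry and a person-specific one:
#'
#'   latent_p = (1 - lambda) * group + lambda * personal_p
#'
#' where `idiosyncrasy` (lambda) in \[0, 1\] sets the person-specific share.
#' All three data channels (voxel responses, attribute ratings, verbal
#' descriptions) derive from the same participant latents, so identity
#' signal flows to the decoder only through lambda.
#'
#' The voxel grid is small by design (the generator emulates statistical
#' structure, not anatomy); ROIs are contiguous slabs along the third grid
#' axis.  Voxel responses follow a boxcar delayed `response_delay_volumes`
#' after onset and lasting `response_duration_volumes`, plus
#' motion-correlated artifact, a linear scanner drift, and white noise of
#' SD `noise_sd`.
#'
#' @param n_participants,n_scenarios,n_runs,n_attributes cohort design
#'   counts.
#' @param grid_dims integer length-3 voxel grid extents.
#' @param n_rois number of ROI slabs.
#' @param tr_seconds repetition time (s).
#' @param stimulus_volumes,gap_volumes stimulus-on and fixation volumes per
#'   presentation.
#' @param latent_dim dimensionality of the scenario latents.
#' @param idiosyncrasy lambda in \[0, 1\]: person-specific signal share.
#' @param noise_sd white-noise SD of the voxel channel.
#' @param motion_sd scale of the motion-coupled voxel artifact.
#' @param drift_slope scale of the per-voxel linear drift.
#' @param rating_noise_sd SD of rating noise before Likert quantization.
#' @param embed_noise_sd SD of noise on the latent-to-embedding projection
#'   before nearest-word lookup.
#' @param vocab_size,embed_dim synthetic vocabulary size and embedding
#'   dimension; the vocabulary is organized around `latent_dim` topic
#'   centroids, so `vocab_size >= latent_dim` and
#'   `embed_dim >= latent_dim`.
#' @param words_per_description nearest vocabulary words per description.
#' @param response_delay_volumes,response_duration_volumes boxcar response
#'   delay and duration in volumes.
#' @param signal_rois integer ROI labels that carry latent-linked signal
#'   (default all); other ROIs contain only noise, drift and motion
#'   artifact -- used to plant recoverable signal.
#' @param drop_first_presentation if TRUE, the first presentation of run 1
#'   is dropped for every participant, emulating discarded initial volumes
#'   (one scenario then has one fewer replicate).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants = 26, n_scenarios = 20, n_runs = 5,
                          n_attributes = 20, grid_dims = c(6, 6, 6),
                          n_rois = 4, tr_seconds = 2.5,
                          stimulus_volumes = 3, gap_volumes = 3,
                          latent_dim = 30, idiosyncrasy = 0.5,
                          noise_sd = 4, motion_sd = 0.5, drift_slope = 1,
                          rating_noise_sd = 1, embed_noise_sd = 0.5,
                          vocab_size = 120, embed_dim = 50,
                          words_per_description = 8,
                          response_delay_volumes = 2,
                          response_duration_volumes = 4,
                          signal_rois = NULL,
                          drop_first_presentation = FALSE,
                          seed = 1) {
  counts <- list(n_participants = n_participants, n_scenarios = n_scenarios,
                 n_runs = n_runs, n_attributes = n_attributes,
                 n_rois = n_rois, latent_dim = latent_dim,
                 vocab_size = vocab_size, embed_dim = embed_dim,
                 words_per_description = words_per_description,
                 stimulus_volumes = stimulus_volumes,
                 gap_volumes = gap_volumes,
                 response_delay_volumes = response_delay_volumes,
                 response_duration_volumes = response_duration_volumes)
  for (nm in names(counts)) {
    if (!.is_count(counts[[nm]])) stop(nm, " must be a positive count")
  }
  if (n_scenarios < 3) stop("n_scenarios must be at least 3")
  if (n_runs < 2) stop("n_runs must be at least 2")
  if (!is.numeric(idiosyncrasy) || idiosyncrasy < 0 || idiosyncrasy > 1) {
    stop("idiosyncrasy must lie in [0, 1]")
  }
  if (length(grid_dims) != 3 || any(grid_dims < 1)) {
    stop("grid_dims must be 3 positive extents")
  }
  if (n_rois > grid_dims[3]) {
    stop("n_rois (", n_rois, ") exceeds third grid extent (", grid_dims[3],
         "): ROI slabs would be empty")
  }
  if (vocab_size < latent_dim) stop("vocab_size must be >= latent_dim topics")
  if (embed_dim < max(2, latent_dim)) {
    stop("embed_dim must be >= max(2, latent_dim)")
  }
  if (embed_dim < 2) stop("embed_dim must be at least 2")
  if (is.null(signal_rois)) signal_rois <- seq_len(n_rois)
  if (!all(signal_rois %in% seq_len(n_rois))) {
    stop("signal_rois outside 1..n_rois")
  }
  for (nm in c("noise_sd", "motion_sd", "drift_slope", "rating_noise_sd",
               "embed_noise_sd")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || val < 0) {
      stop(nm, " must be a non-negative scalar")
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_scenarios = as.integer(n_scenarios), n_runs = as.integer(n_runs),
    n_attributes = as.integer(n_attributes),
    grid_dims = as.integer(grid_dims), n_rois = as.integer(n_rois),
    tr_seconds = tr_seconds,
    stimulus_volumes = as.integer(stimulus_volumes),
    gap_volumes = as.integer(gap_volumes),
    latent_dim = as.integer(latent_dim), idiosyncrasy = idiosyncrasy,
    noise_sd = noise_sd, motion_sd = motion_sd, drift_slope = drift_slope,
    rating_noise_sd = rating_noise_sd, embed_noise_sd = embed_noise_sd,
    vocab_size = as.integer(vocab_size), embed_dim = as.integer(embed_dim),
    words_per_description = as.integer(words_per_description),
    response_delay_volumes = as.integer(response_delay_volumes),
    response_duration_volumes = as.integer(response_duration_volumes),
    signal_rois = as.integer(signal_rois),
    drop_first_presentation = isTRUE(drop_first_presentation),
    seed = as.integer(seed)), class = "cohort_config")
}

#' Generate a topic-structured synthetic vocabulary embedding
#'
#' Builds a stand-in for a distributional word-embedding table: words are
#' scattered around `n_topics` mutually orthogonal topic centroids, so words
#' from the same topic have higher cosine similarity than words from
#' different topics, and additive composition of a word list recovers the
#' topic geometry.
#'
#' @param vocab_size number of words (>= n_topics).
#' @param embed_dim embedding dimensionality (>= max(2, n_topics)).
#' @param n_topics number of topic clusters.
#' @param seed optional RNG seed; NULL uses the current stream.
#' @return numeric vocab_size x embed_dim matrix, words as rownames, with
#'   attribute `topic` (integer topic per word) and `centroids`
#'   (n_topics x embed_dim).
#' @export
generate_vocabulary_embedding <- function(vocab_size, embed_dim,
                                          n_topics = min(8, vocab_size),
                                          seed = NULL) {
  if (!.is_count(vocab_size) || !.is_count(embed_dim) || !.is_count(n_topics)) {
    stop("vocab_size, embed_dim and n_topics must be positive counts")
  }
  if (embed_dim < 2) stop("embed_dim must be at least 2")
  if (vocab_size < n_topics) stop("vocab_size must be >= n_topics")
  if (embed_dim < n_topics) stop("embed_dim must be >= n_topics")
  .with_seed(seed, {
    # Orthonormal centroid directions, scaled well above the word scatter so
    # within-topic cosine dominates across-topic cosine.
    q <- qr.Q(qr(matrix(stats::rnorm(embed_dim * n_topics), embed_dim)))
    centroids <- t(q) * (3 * sqrt(embed_dim))
    topic <- rep_len(seq_len(n_topics), vocab_size)
    words <- centroids[topic, , drop = FALSE] +
      matrix(stats::rnorm(vocab_size * embed_dim), vocab_size)
    rownames(words) <- sprintf("word%03d", seq_len(vocab_size))
    attr(words, "topic") <- topic
    attr(words, "centroids") <- centroids
    words
  })
}

# ROI slab label for each voxel of a grid: contiguous blocks of slices
# along the third axis.
.roi_slab_labels <- function(grid_dims, n_rois) {
  slab <- ceiling(seq_len(grid_dims[3]) * n_rois / grid_dims[3])
  rep(slab, each = grid_dims[1] * grid_dims[2])
}

#' Generate a synthetic cohort
#'
#' Simulates every data channel of an imagined-scenario study under the
#' latent-mixture model described in [cohort_config()]: per-run 4D voxel
#' time series with a randomized scenario order per run, motion-parameter
#' tables, 0--6 Likert attribute ratings, bag-of-words descriptions over a
#' topic-structured vocabulary, and the ground-truth latents.
#'
#' Voxel time series are built as an ROI-specific linear readout of the
#' active scenario's latent, on during a delayed boxcar window, plus a
#' motion-coupled artifact, a per-voxel linear drift, and white noise.
#' ROIs not listed in `signal_rois` get no latent readout (pure nuisance),
#' which plants recoverable signal for selection tests.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `config`, `vocab`,
#'   `roi_labels`, `scenario_names`, `runs` (per participant, per run:
#'   `data` time x voxel, `motion` time x 6, `onsets` data frame),
#'   `ratings`, `descriptions`, `snr`, and `truth` (group/personal/mixed
#'   latents and lambda).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  cf <- config
  P <- cf$n_participants; S <- cf$n_scenarios; R <- cf$n_runs
  L <- cf$latent_dim; lam <- cf$idiosyncrasy
  V <- prod(cf$grid_dims)
  roi_labels <- .roi_slab_labels(cf$grid_dims, cf$n_rois)
  spacing <- cf$stimulus_volumes + cf$gap_volumes
  run_len <- S * spacing + cf$response_delay_volumes +
    cf$response_duration_volumes
  withr::with_seed(cf$seed, {
    vocab <- generate_vocabulary_embedding(cf$vocab_size, cf$embed_dim,
                                           n_topics = L)
    centroids <- attr(vocab, "centroids")
    group_latent <- matrix(stats::rnorm(S * L), S, L)
    # Shared linear structure: voxel readouts per ROI, attribute directions,
    # motion loadings, drift coefficients.
    readout <- matrix(0, L, V)
    for (roi in cf$signal_rois) {
      idx <- which(roi_labels == roi)
      readout[, idx] <- stats::rnorm(L * length(idx)) / sqrt(L)
    }
    attr_dirs <- matrix(stats::rnorm(L * cf$n_attributes), L)
    motion_load <- matrix(stats::rnorm(6 * V), 6) / sqrt(6)
    drift_coef <- stats::rnorm(V)
    scenario_names <- sprintf("scenario_%02d", seq_len(S))

    runs <- vector("list", P)
    ratings <- vector("list", P)
    descriptions <- vector("list", P)
    personal_latents <- vector("list", P)
    participant_latents <- vector("list", P)
    sig_var_acc <- 0; sig_n <- 0
    for (p in seq_len(P)) {
      personal <- matrix(stats::rnorm(S * L), S, L)
      latent_p <- (1 - lam) * group_latent + lam * personal
      personal_latents[[p]] <- personal
      participant_latents[[p]] <- latent_p

      # --- voxel channel -------------------------------------------------
      amp_p <- latent_p %*% readout            # S x V response amplitudes
      p_runs <- vector("list", R)
      for (r in seq_len(R)) {
        ord <- sample.int(S)
        onset_vol <- (seq_len(S) - 1L) * spacing
        signal <- matrix(0, run_len, V)
        for (k in seq_len(S)) {
          rows <- onset_vol[k] + cf$response_delay_volumes +
            seq_len(cf$response_duration_volumes)
          signal[rows, ] <- signal[rows, ] +
            matrix(amp_p[ord[k], ], cf$response_duration_volumes, V,
                   byrow = TRUE)
        }
        motion <- apply(matrix(stats::rnorm(run_len * 6, sd = 0.02),
                               run_len, 6), 2L, cumsum)
        drift <- cf$drift_slope *
          outer(seq(-0.5, 0.5, length.out = run_len), drift_coef)
        noise <- matrix(stats::rnorm(run_len * V, sd = cf$noise_sd),
                        run_len, V)
        data <- signal + cf$motion_sd * (motion %*% motion_load) +
          drift + noise
        onsets <- data.frame(volume = onset_vol, scenario = ord)
        if (cf$drop_first_presentation && r == 1L) onsets <- onsets[-1L, ]
        p_runs[[r]] <- list(data = data, motion = motion, onsets = onsets)
        sig_var_acc <- sig_var_acc + stats::var(as.numeric(signal))
        sig_n <- sig_n + 1
      }
      runs[[p]] <- p_runs

      # --- attribute channel ---------------------------------------------
      score <- latent_p %*% attr_dirs +
        matrix(stats::rnorm(S * cf$n_attributes, sd = cf$rating_noise_sd),
               S)
      rat <- pmin(6L, pmax(0L, as.integer(round(3 + 1.8 * score / sqrt(L)))))
      rat <- matrix(rat, S, cf$n_attributes,
                    dimnames = list(scenario_names,
                                    sprintf("attr%02d", seq_len(cf$n_attributes))))
      ratings[[p]] <- rat

      # --- verbal channel -------------------------------------------------
      desc <- character(S)
      vocab_norm <- vocab / sqrt(rowSums(vocab^2))
      for (s in seq_len(S)) {
        target <- as.numeric(latent_p[s, ] %*% centroids) +
          stats::rnorm(cf$embed_dim, sd = cf$embed_noise_sd *
                         sqrt(cf$embed_dim))
        sim <- as.numeric(vocab_norm %*% (target / sqrt(sum(target^2))))
        nearest <- order(-sim)[seq_len(cf$words_per_description)]
        desc[s] <- paste(rownames(vocab)[nearest], collapse = " ")
      }
      names(desc) <- scenario_names
      descriptions[[p]] <- desc
    }
    voxel_snr <- if (cf$noise_sd == 0) Inf else
      (sig_var_acc / sig_n) / cf$noise_sd^2
    rating_snr <- if (cf$rating_noise_sd == 0) Inf else
      mean(apply(group_latent %*% attr_dirs, 2L, stats::var)) /
        cf$rating_noise_sd^2
    structure(list(
      config = cf, vocab = vocab, roi_labels = roi_labels,
      scenario_names = scenario_names, runs = runs, ratings = ratings,
      descriptions = descriptions,
      snr = c(voxel = voxel_snr, rating = rating_snr),
      truth = list(idiosyncrasy = lam, group_latent = group_latent,
                   personal_latents = personal_latents,
                   participant_latents = participant_latents)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cf <- x$config
  cat("synthetic_cohort: ", cf$n_participants, " participants x ",
      cf$n_scenarios, " scenarios x ", cf$n_runs, " runs, lambda = ",
      cf$idiosyncrasy, ", grid ", paste(cf$grid_dims, collapse = "x"),
      " (", cf$n_rois, " ROIs)\n", sep = "")
  invisible(x)
}

#' Ground-truth report of a synthetic cohort
#'
#' Summarizes the generative state retained by [generate_cohort()] for test
#' assertions: the idiosyncrasy lambda, the group-latent inter-scenario
#' similarity triangle (raw Pearson, lower triangle), the per-participant
#' latent similarity triangles, and the per-channel signal-to-noise ratios
#' (infinite for a noiseless channel).
#'
#' @param cohort a `synthetic_cohort`.
#' @return list with `idiosyncrasy`, `group_similarity`,
#'   `participant_similarity`, `snr`.
#' @export
ground_truth_report <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("cohort must come from generate_cohort()")
  }
  tr <- cohort$truth
  list(idiosyncrasy = tr$idiosyncrasy,
       group_similarity = .tri_vec(stats::cor(t(tr$group_latent))),
       participant_similarity = lapply(tr$participant_latents, function(m) {
         .tri_vec(stats::cor(t(m)))
       }),
       snr = cohort$snr)
}
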