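#' Congruent-versus-incongruent decoding of one participant pair
#'
#' Given two participants' model similarity vectors and their fMRI
#' similarity vectors, computes the four model-to-brain Spearman
#' correlations, Fisher-z transforms them, and scores 1 when the congruent
#' sum z(i,i) + z(j,j) exceeds the incongruent sum z(i,j) + z(j,i): the
#' participants are told apart when each person's own model fits their own
#' brain data better.  An exact tie scores 0 under the conservative default
#' (`ties = "half"` gives half credit instead).
#'
#' @param model_i,model_j model similarity vectors of the two participants.
#' @param fmri_i,fmri_j fMRI similarity vectors of the two participants.
#' @param ties `"zero"` (default) or `"half"`.
#' @return 0, 1 (or 0.5 under `ties = "half"`).
#' @export
pair_decode <- function(model_i, model_j, fmri_i, fmri_j,
                        ties = c("zero", "half")) {
  ties <- match.arg(ties)
  z <- function(a, b) .fisher_z(rsa_spearman(a, b))
  congruent <- z(model_i, fmri_i) + z(model_j, fmri_j)
  incongruent <- z(model_i, fmri_j) + z(model_j, fmri_i)
  if (congruent > incongruent) 1 else
    if (congruent == incongruent && ties == "half") 0.5 else 0
}

# All-pairs Spearman cross-correlation of two aligned lists of similarity
# vectors, Fisher-z transformed: Z[i, j] = z(spearman(models[[i]],
# fmri[[j]])).  Precomputing this makes the permutation test cheap.
.cross_z <- function(models, fmri) {
  rank_mat <- function(lst) vapply(lst, function(v) rank(as.numeric(v)),
                                   numeric(length(models[[1L]])))
  rm_ <- rank_mat(models)
  rf_ <- rank_mat(fmri)
  .fisher_z(stats::cor(rm_, rf_))
}

# Decoding accuracy (percent) for a given participant -> fMRI assignment,
# from the precomputed cross z matrix.
.accuracy_from_z <- function(z, assign = seq_len(nrow(z)), ties = "zero") {
  zp <- z[, assign, drop = FALSE]
  d <- diag(zp)
  margin <- outer(d, d, `+`) - (zp + t(zp))   # congruent - incongruent
  m <- margin[upper.tri(margin)]
  score <- sum(m > 0) + if (ties == "half") 0.5 * sum(m == 0) else 0
  100 * score / length(m)
}

#' Pairwise identity decoding across a cohort
#'
#' Runs [pair_decode()] for every unordered pair of participants (325 pairs
#' for 26) and reports the mean outcome as a percentage.  With no
#' participant-specific model-to-brain relationship the expected accuracy
#' is 50%.
#'
#' @param models list of per-participant model similarity vectors.
#' @param fmri list of per-participant fMRI similarity vectors, aligned
#'   with `models`.
#' @param ties tie policy passed to [pair_decode()].
#' @return list with `pair_outcomes` (named vector over pairs), `accuracy`
#'   (percent), `n_pairs`.
#' @export
decode_cohort <- function(models, fmri, ties = c("zero", "half")) {
  ties <- match.arg(ties)
  P <- length(models)
  if (P < 2) stop("need at least 2 participants")
  if (length(fmri) != P) stop("misaligned participant sets")
  len <- length(models[[1L]])
  if (!all(lengths(models) == len) || !all(lengths(fmri) == len)) {
    stop("similarity vectors differ in length")
  }
  z <- .cross_z(models, fmri)
  d <- diag(z)
  margin <- outer(d, d, `+`) - (z + t(z))
  pairs <- which(upper.tri(margin), arr.ind = TRUE)
  m <- margin[upper.tri(margin)]
  outcomes <- as.numeric(m > 0)
  if (ties == "half") outcomes[m == 0] <- 0.5
  names(outcomes) <- paste0("p", pairs[, 1L], "_p", pairs[, 2L])
  list(pair_outcomes = outcomes, accuracy = 100 * mean(outcomes),
       n_pairs = length(outcomes))
}

#' Permutation test of the cohort decoding accuracy
#'
#' Null distribution obtained by randomly reassigning the fMRI similarity
#' vectors to participants (full random permutations; fixed points allowed)
#' and re-running the entire pairwise decoding, `n_perm` times (default
#' 10,000).  The p-value is the fraction of null accuracies greater than or
#' equal to the observed accuracy.
#'
#' @inheritParams decode_cohort
#' @param n_perm number of reassignments.
#' @param seed optional RNG seed.
#' @param estimator `"fraction"` or `"add_one"` (see
#'   [rsa_permutation_test()]).
#' @return list with `accuracy`, `p_perm`, `n_perm`, `n_pairs`.
#' @export
decoding_permutation_test <- function(models, fmri, n_perm = 10000,
                                      seed = NULL, ties = c("zero", "half"),
                                      estimator = c("fraction", "add_one")) {
  ties <- match.arg(ties)
  estimator <- match.arg(estimator)
  if (!.is_count(n_perm)) stop("n_perm must be a positive count")
  P <- length(models)
  if (length(fmri) != P || P < 2) stop("misaligned participant sets")
  z <- .cross_z(models, fmri)
  observed <- .accuracy_from_z(z, ties = ties)
  null_acc <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      .accuracy_from_z(z, assign = sample.int(P), ties = ties)
    }, numeric(1))
  })
  list(accuracy = observed,
       p_perm = .perm_p(null_acc, observed, estimator),
       n_perm = n_perm, n_pairs = P * (P - 1) / 2)
}

#' Model-only identity decoding (no fMRI)
#'
#' Context analysis for the neural decoding accuracy: the same pairwise
#' congruent-versus-incongruent algorithm with one behavioral channel (the
#' verbal model) playing "model" and the other (the attribute model)
#' playing "data".
#'
#' @param verbal_sims,attribute_sims lists of per-participant similarity
#'   vectors for the two behavioral channels.
#' @inheritParams decode_cohort
#' @return as [decode_cohort()].
#' @export
model_only_decode <- function(verbal_sims, attribute_sims,
                              ties = c("zero", "half")) {
  decode_cohort(verbal_sims, attribute_sims, ties = ties)
}
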