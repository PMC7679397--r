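#' One-sample group test on Fisher-z RSA coefficients
#'
#' One-tailed (greater) one-sample t-test of per-participant Fisher-z
#' coefficients against zero, anticipating positive model-to-brain
#' correlation, with Cohen's d computed as t / sqrt(n).
#'
#' @param z_values numeric vector of per-participant arctanh-transformed
#'   coefficients.
#' @param alternative test direction (default `"greater"`).
#' @return list with `t`, `p`, `cohens_d`, `n`, `mean_z`.
#' @export
one_sample_group_test <- function(z_values, alternative = "greater") {
  z_values <- as.numeric(z_values)
  n <- length(z_values)
  if (n < 2) stop("need at least 2 participants")
  if (stats::var(z_values) == 0) stop("zero variance across participants")
  ht <- stats::t.test(z_values, mu = 0, alternative = alternative)
  t_stat <- unname(ht$statistic)
  list(t = t_stat, p = unname(ht$p.value), cohens_d = t_stat / sqrt(n),
       n = n, mean_z = mean(z_values))
}

#' False discovery rate adjustment of p-values
#'
#' Benjamini--Hochberg step-up adjusted p-values (monotone, capped at 1).
#' `method = "BY"` gives the Benjamini--Yekutieli variant valid under
#' arbitrary dependence.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p-values, same length.
#' @export
fdr_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

# Per-ROI one-tailed group tests + FDR over ROIs; shared by both selection
# procedures.  `z_matrix` is participants x ROI.
.roi_group_table <- function(z_matrix, fdr_q, method = "BH") {
  rois <- colnames(z_matrix)
  if (is.null(rois)) rois <- as.character(seq_len(ncol(z_matrix)))
  tests <- lapply(seq_len(ncol(z_matrix)), function(j) {
    one_sample_group_test(z_matrix[, j])
  })
  tab <- data.frame(
    roi = rois,
    t = vapply(tests, `[[`, numeric(1), "t"),
    p_raw = vapply(tests, `[[`, numeric(1), "p"),
    cohens_d = vapply(tests, `[[`, numeric(1), "cohens_d"),
    n = vapply(tests, `[[`, numeric(1), "n"))
  tab$p_fdr <- fdr_adjust(tab$p_raw, method = method)
  tab$selected <- tab$p_fdr < fdr_q
  tab
}

#' Select ROIs whose activity reflects group-average model structure
#'
#' For every ROI, each participant's fMRI similarity vector is correlated
#' (Spearman) with the leave-one-out group-average model similarity vector,
#' the coefficients are Fisher-z transformed and tested against zero with a
#' one-tailed one-sample t-test, and the resulting p-values are FDR
#' corrected across ROIs.  ROIs with adjusted p below `fdr_q` are selected.
#'
#' @param fmri_sims list over participants of lists over ROIs of fMRI
#'   similarity vectors.
#' @param group_sims list over participants of G-1 model similarity
#'   vectors (each excluding that participant).
#' @param fdr_q selection threshold on adjusted p (default 0.05).
#' @param method FDR variant passed to [fdr_adjust()].
#' @return list with `table` (per-ROI stats data frame), `selected` (ROI
#'   names), `z` (participants x ROI coefficient matrix).
#' @export
select_rois_group_model <- function(fmri_sims, group_sims, fdr_q = 0.05,
                                    method = "BH") {
  P <- length(fmri_sims)
  if (P < 2) stop("need at least 2 participants")
  roi_names <- names(fmri_sims[[1L]])
  z <- t(vapply(seq_len(P), function(p) {
    vapply(fmri_sims[[p]], function(sv) {
      .fisher_z(rsa_spearman(sv, group_sims[[p]]))
    }, numeric(1))
  }, numeric(length(roi_names))))
  colnames(z) <- roi_names
  tab <- .roi_group_table(z, fdr_q, method)
  list(table = tab, selected = tab$roi[tab$selected], z = z)
}

#' Select ROIs for one participant from the other participants' data
#'
#' To choose regions for a target participant without touching their data,
#' RSA is run between every *other* participant's fMRI similarity vector
#' and that participant's own personal model; per ROI, the n-1 Fisher-z
#' coefficients are tested against zero (one-tailed) and FDR corrected
#' across ROIs.  ROIs with adjusted p below `fdr_q` are selected for the
#' target.
#'
#' @param fmri_sims list over participants of lists over ROIs of fMRI
#'   similarity vectors.
#' @param personal_sims list over participants of personal model similarity
#'   vectors.
#' @param target index of the participant being selected for (excluded
#'   from all tests).
#' @inheritParams select_rois_group_model
#' @return list with `table`, `selected`, `z` (held-out participants x ROI).
#' @export
select_rois_loo_personal <- function(fmri_sims, personal_sims, target,
                                     fdr_q = 0.05, method = "BH") {
  P <- length(fmri_sims)
  if (P < 3) stop("need at least 3 participants")
  if (!.is_count(target) || target > P) stop("invalid target participant")
  keep <- setdiff(seq_len(P), target)
  roi_names <- names(fmri_sims[[1L]])
  z <- t(vapply(keep, function(p) {
    vapply(fmri_sims[[p]], function(sv) {
      .fisher_z(rsa_spearman(sv, personal_sims[[p]]))
    }, numeric(1))
  }, numeric(length(roi_names))))
  colnames(z) <- roi_names
  tab <- .roi_group_table(z, fdr_q, method)
  list(table = tab, selected = tab$roi[tab$selected], z = z)
}

#' Cross-participant agreement of personal model representations
#'
#' Spearman RSA between every unordered pair of participants' model
#' similarity vectors (325 pairs for 26 participants): quantifies how much
#' scenario representational structure people share.  The mean and SD of
#' the raw coefficients are reported, and the Fisher-z coefficients are
#' tested against zero with a one-sample t-test.
#'
#' @param model_sims list of per-participant model similarity vectors.
#' @return list with `mean_rho`, `sd_rho`, `t`, `p`, `n_pairs`, `rho`
#'   (per-pair coefficients).
#' @export
cross_participant_model_agreement <- function(model_sims) {
  P <- length(model_sims)
  if (P < 2) stop("need at least 2 participants")
  pairs <- utils::combn(P, 2L)
  rho <- vapply(seq_len(ncol(pairs)), function(k) {
    rsa_spearman(model_sims[[pairs[1L, k]]], model_sims[[pairs[2L, k]]])
  }, numeric(1))
  z <- .fisher_z(rho)
  if (stats::var(z) == 0) {
    ht <- list(statistic = Inf, p.value = 0)
  } else {
    ht <- stats::t.test(z, mu = 0, alternative = "greater")
  }
  list(mean_rho = mean(rho), sd_rho = stats::sd(rho),
       t = unname(ht$statistic), p = unname(ht$p.value),
       n_pairs = ncol(pairs), rho = rho)
}

#' Upper-tail cumulative binomial probability
#'
#' P(X >= k) for X ~ Binomial(n, p0), by direct summation of the mass
#' function.  Used to summarize how surprising it is to see k or more
#' participants individually significant at level p0 in one region.
#'
#' @param n number of trials (participants).
#' @param p0 per-trial success probability.
#' @param k threshold count.
#' @return P(X >= k).
#' @export
binomial_tail <- function(n, p0, k) {
  if (!.is_count(n) || !.is_count(k, min = 0L) || k > n) {
    stop("need 0 <= k <= n with integer n, k")
  }
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (k == 0L) return(1)
  sum(stats::dbinom(k:n, n, p0))
}

# Integer voxel indices of the cube of given radius around a center voxel,
# intersected with the grid.
.cube_indices <- function(center, grid_dims, radius) {
  cx <- ((center - 1L) %% grid_dims[1]) + 1L
  cy <- (((center - 1L) %/% grid_dims[1]) %% grid_dims[2]) + 1L
  cz <- ((center - 1L) %/% (grid_dims[1] * grid_dims[2])) + 1L
  xs <- max(1L, cx - radius):min(grid_dims[1], cx + radius)
  ys <- max(1L, cy - radius):min(grid_dims[2], cy + radius)
  zs <- max(1L, cz - radius):min(grid_dims[3], cz + radius)
  grid <- expand.grid(x = xs, y = ys, z = zs)
  (grid$z - 1L) * grid_dims[1] * grid_dims[2] +
    (grid$y - 1L) * grid_dims[1] + grid$x
}

#' Searchlight RSA / partial-RSA map
#'
#' Repeats the ROI analysis in a moving cubic neighborhood: a cube of
#' radius `radius` voxels (side 2*radius + 1) is centered on every voxel of
#' the common mask, the in-mask cube voxels form the searchlight ROI, each
#' participant's similarity vector over those voxels is correlated with
#' their model (Spearman, or Spearman partial controlling the G-1 model),
#' the Fisher-z coefficient is assigned to the center, a one-tailed
#' one-sample t-test is applied per center across participants, and the
#' resulting p-values are FDR corrected across centers (separately per
#' map).
#'
#' @param patterns list over participants of S x V normalized full-grid
#'   pattern matrices (all sharing the voxel grid).
#' @param model_sims list over participants of model similarity vectors
#'   (personal models for `mode = "rsa_personal"` / `"partial"`, G-1 models
#'   for `mode = "rsa_group"`).
#' @param grid_dims integer length-3 grid extents.
#' @param mask logical or integer vector of analyzed voxels (common to all
#'   participants); default all.
#' @param radius cube radius in voxels (default 3, side 7).
#' @param mode `"rsa_personal"`, `"rsa_group"`, or `"partial"`.
#' @param group_sims per-participant G-1 similarity vectors, required for
#'   `mode = "partial"`.
#' @param restrict_to optional integer vector of center voxels to analyze
#'   (e.g. the centers significant in a group-model map, mirroring the
#'   restriction of the partial test to regions that carry group
#'   structure); default all mask voxels.
#' @param min_voxels centers whose in-mask cube has fewer voxels are
#'   skipped (default 10).
#' @param fdr_q significance threshold on adjusted p (default 0.05).
#' @return object of class `searchlight_map`: list with `t_map` and
#'   `p_fdr_map` (3D arrays, NA where not analyzed), `centers`,
#'   `significant` (center indices with adjusted p < fdr_q), `radius`,
#'   `mask`, `table`.
#' @export
searchlight_map <- function(patterns, model_sims, grid_dims,
                            mask = NULL, radius = 3,
                            mode = c("rsa_personal", "rsa_group", "partial"),
                            group_sims = NULL, restrict_to = NULL,
                            min_voxels = 10, fdr_q = 0.05) {
  mode <- match.arg(mode)
  if (mode == "partial" && is.null(group_sims)) {
    stop("partial mode needs group_sims")
  }
  V <- prod(grid_dims)
  if (is.null(mask)) mask <- seq_len(V)
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0L) stop("empty mask")
  centers <- if (is.null(restrict_to)) mask else intersect(restrict_to, mask)
  P <- length(patterns)
  t_vec <- rep(NA_real_, length(centers))
  for (ci in seq_along(centers)) {
    roi_idx <- intersect(.cube_indices(centers[ci], grid_dims, radius), mask)
    if (length(roi_idx) < min_voxels) next
    z <- vapply(seq_len(P), function(p) {
      sv <- similarity_vector(patterns[[p]][, roi_idx, drop = FALSE])
      rho <- if (mode == "partial") {
        partial_rsa(sv, model_sims[[p]], group_sims[[p]])
      } else {
        rsa_spearman(sv, model_sims[[p]])
      }
      .fisher_z(rho)
    }, numeric(1))
    t_vec[ci] <- one_sample_group_test(z)$t
  }
  analyzed <- which(!is.na(t_vec))
  p_raw <- stats::pt(t_vec[analyzed], df = P - 1, lower.tail = FALSE)
  p_fdr <- fdr_adjust(p_raw)
  t_map <- array(NA_real_, grid_dims)
  p_map <- array(NA_real_, grid_dims)
  t_map[centers[analyzed]] <- t_vec[analyzed]
  p_map[centers[analyzed]] <- p_fdr
  structure(list(
    t_map = t_map, p_fdr_map = p_map,
    centers = centers[analyzed],
    significant = centers[analyzed][p_fdr < fdr_q],
    radius = radius, mask = mask, mode = mode,
    table = data.frame(center = centers[analyzed], t = t_vec[analyzed],
                       p_raw = p_raw, p_fdr = p_fdr)),
    class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat("searchlight_map (", x$mode, "): ", length(x$centers),
      " centers analyzed, ", length(x$significant),
      " significant, radius ", x$radius, "\n", sep = "")
  invisible(x)
}
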