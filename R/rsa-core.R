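#' Inter-scenario similarity vector of a pattern matrix
#'
#' Re-represents a set of scenario patterns in similarity space: the Pearson
#' correlation between every pair of scenario rows is computed over the
#' feature dimension, Fisher z (arctanh) transformed, and the below-diagonal
#' triangle of the resulting S x S matrix is vectorized.  For S = 20
#' scenarios this gives the 190-entry similarity vector in which brain and
#' model representations are compared.
#'
#' Correlations are clipped to +/-(1 - 1e-7) before arctanh so identical
#' patterns map to a large finite value rather than infinity.  The triangle
#' is traversed in R's column-major `lower.tri()` order; every similarity
#' vector produced by this package uses the same traversal, so entries are
#' directly comparable across sources.
#'
#' @param patterns numeric S x F matrix, one row per scenario.
#' @param source tag recording where the patterns came from, e.g. `"fmri"`,
#'   `"verbal"`, `"attribute"`.
#' @return numeric vector of length S(S-1)/2 with attributes `n_scenarios`
#'   and `source`.
#' @export
similarity_vector <- function(patterns, source = "unspecified") {
  patterns <- as.matrix(patterns)
  s <- nrow(patterns)
  if (s < 3) stop("need at least 3 scenarios, got ", s)
  row_var <- apply(patterns, 1L, stats::var)
  if (any(row_var == 0)) {
    stop("zero-variance scenario pattern in row(s) ",
         paste(which(row_var == 0), collapse = ", "))
  }
  r <- stats::cor(t(patterns))
  v <- .fisher_z(.tri_vec(r))
  attr(v, "n_scenarios") <- s
  attr(v, "source") <- source
  v
}

#' Fuse verbal and attribute similarity vectors into a multimodal model
#'
#' Each input similarity vector is z-scored over its entries (mean
#' subtracted, divided by the standard deviation across entries) and the two
#' standardized vectors are summed pointwise.  The result is the
#' participant's multimodal model representation.
#'
#' @param verbal,attribute similarity vectors of equal length over the same
#'   scenario ordering.
#' @return numeric similarity vector tagged `"multimodal"`.
#' @export
fuse_multimodal <- function(verbal, attribute) {
  if (length(verbal) != length(attribute)) {
    stop("similarity vectors differ in length: ", length(verbal), " vs ",
         length(attribute))
  }
  v <- .zscore(as.numeric(verbal)) + .zscore(as.numeric(attribute))
  attr(v, "n_scenarios") <- .n_from_tri(length(v))
  attr(v, "source") <- "multimodal"
  v
}

#' Leave-one-out group-average model representation (G-1)
#'
#' Builds the group-average model for one test participant from everyone
#' else's data.  In `"similarity"` space (the default) the remaining
#' participants' similarity vectors are pointwise averaged.  In `"feature"`
#' space the remaining participants' model feature matrices are averaged
#' first and the similarity vector of the mean matrix is returned.
#'
#' @param sims list of per-participant similarity vectors.
#' @param exclude index of the held-out test participant.
#' @param space `"similarity"` or `"feature"`.
#' @param features list of per-participant S x F feature matrices; required
#'   for `space = "feature"`.
#' @return a similarity vector tagged `"group_average"`.
#' @export
group_average_loo <- function(sims, exclude, space = c("similarity", "feature"),
                              features = NULL) {
  space <- match.arg(space)
  n <- length(sims)
  if (n < 2) stop("need at least 2 participants")
  if (!.is_count(exclude) || exclude > n) stop("invalid participant index")
  keep <- setdiff(seq_len(n), exclude)
  if (space == "similarity") {
    v <- rowMeans(vapply(sims[keep], as.numeric, numeric(length(sims[[1L]]))))
  } else {
    if (is.null(features)) stop("feature-space averaging needs `features`")
    mean_feat <- Reduce(`+`, features[keep]) / length(keep)
    v <- as.numeric(similarity_vector(mean_feat))
  }
  attr(v, "n_scenarios") <- .n_from_tri(length(v))
  attr(v, "source") <- "group_average"
  v
}

#' Spearman RSA coefficient between two similarity vectors
#'
#' Spearman rank correlation (average ranks for ties) between a model and a
#' brain similarity vector.
#'
#' @param a,b similarity vectors of equal length (>= 3 entries).
#' @return the Spearman rho.
#' @export
rsa_spearman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need at least 3 entries")
  if (stats::var(a) == 0 || stats::var(b) == 0) stop("constant input")
  stats::cor(a, b, method = "spearman")
}

# Shared permutation p-value estimator.  The default is the plain fraction
# of null statistics >= observed; "add_one" gives the (b+1)/(B+1) variant
# that cannot return exactly zero.
.perm_p <- function(null_stats, observed, estimator) {
  b <- sum(null_stats >= observed)
  if (estimator == "add_one") (b + 1) / (length(null_stats) + 1) else
    b / length(null_stats)
}

#' Row/column-shuffle permutation test for an RSA correlation
#'
#' Tests a single participant's model-to-brain RSA coefficient against a
#' null in which scenario identity is broken: scenario order is randomly
#' shuffled and the rows and columns of the fMRI correlation matrix (but not
#' the model matrix) are rearranged accordingly; the shuffled lower triangle
#' is then re-correlated (Spearman) with the model similarity vector.  The
#' p-value is the fraction of null coefficients greater than or equal to the
#' observed one.
#'
#' @param fmri_corr S x S symmetric inter-scenario correlation matrix of the
#'   fMRI patterns (raw Pearson; the Fisher transform is monotone so it does
#'   not affect Spearman).
#' @param model_sim model similarity vector of length S(S-1)/2.
#' @param n_perm number of shuffles (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @param estimator `"fraction"` (plain fraction, can be 0) or `"add_one"`
#'   for the (b+1)/(B+1) estimator.
#' @return list with `rho`, `z` (arctanh rho), `p_perm`, `n_perm`.
#' @export
rsa_permutation_test <- function(fmri_corr, model_sim, n_perm = 1000,
                                 seed = NULL,
                                 estimator = c("fraction", "add_one")) {
  estimator <- match.arg(estimator)
  fmri_corr <- as.matrix(fmri_corr)
  s <- nrow(fmri_corr)
  if (s != ncol(fmri_corr) || max(abs(fmri_corr - t(fmri_corr)), na.rm = TRUE) > 1e-8) {
    stop("fmri_corr must be a symmetric square matrix")
  }
  if (!.is_count(n_perm)) stop("n_perm must be a positive count")
  model_sim <- as.numeric(model_sim)
  if (length(model_sim) != s * (s - 1) / 2) stop("model similarity length mismatch")
  observed <- rsa_spearman(.tri_vec(fmri_corr), model_sim)
  null_stats <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(s)
      stats::cor(.tri_vec(fmri_corr[p, p]), model_sim, method = "spearman")
    }, numeric(1))
  })
  list(rho = observed, z = .fisher_z(observed),
       p_perm = .perm_p(null_stats, observed, estimator), n_perm = n_perm)
}

# Pearson partial correlation of x and y given z, via residuals of an
# ordinary least-squares fit on [1, z].
.partial_pearson <- function(x, y, z) {
  xm <- cbind(1, z)
  bx <- solve(crossprod(xm), crossprod(xm, cbind(x, y)))
  res <- cbind(x, y) - xm %*% bx
  sx <- sqrt(sum(res[, 1]^2)); sy <- sqrt(sum(res[, 2]^2))
  if (sx < 1e-12 || sy < 1e-12) {
    stop("zero residual variance after controlling: collinear inputs")
  }
  sum(res[, 1] * res[, 2]) / (sx * sy)
}

#' Spearman partial RSA coefficient
#'
#' Partial correlation between a participant's fMRI similarity vector and
#' their personal model similarity vector while controlling for the
#' leave-one-out group-average similarity vector.  All three vectors are
#' ranked (average ranks for ties) and the Pearson partial correlation of
#' the ranks is returned: this isolates person-specific representational
#' structure over and above what the group shares.
#'
#' @param fmri,personal,group similarity vectors of equal length.
#' @return the Spearman partial rho.
#' @export
partial_rsa <- function(fmri, personal, group) {
  fmri <- as.numeric(fmri); personal <- as.numeric(personal)
  group <- as.numeric(group)
  len <- length(fmri)
  if (length(personal) != len || length(group) != len) stop("length mismatch")
  rf <- rank(fmri); rp <- rank(personal); rg <- rank(group)
  if (stats::var(rf) == 0 || stats::var(rp) == 0 || stats::var(rg) == 0) {
    stop("constant input after ranking")
  }
  if (abs(stats::cor(rp, rg)) > 1 - 1e-12) {
    stop("personal and group similarity vectors are rank-identical: ",
         "partial correlation is degenerate")
  }
  .partial_pearson(rf, rp, rg)
}

#' Residual-shuffle permutation test for the partial RSA coefficient
#'
#' Significance of the Spearman partial RSA under a null that breaks only
#' the person-specific association, leaving the group-average component
#' intact (a Freedman--Lane style scheme).  Each permutation runs:
#' (A) rank the fMRI, personal and group similarity vectors;
#' (B) regress the ranked fMRI vector on the ranked group vector (with
#' intercept); (C) place the residuals back into their S x S triangle
#' positions and shuffle rows and columns by one random scenario order;
#' (D) form the fitted group component from the step-B coefficients;
#' (E) add the fitted component onto the shuffled residuals;
#' (F) partial-correlate the result with the ranked personal vector,
#' controlling for the ranked group vector.  The p-value is the fraction of
#' null coefficients greater than or equal to the observed partial rho.
#' With no shuffle, steps B--E reproduce the ranked fMRI vector exactly, so
#' the identity permutation returns the observed coefficient.
#'
#' @inheritParams partial_rsa
#' @inheritParams rsa_permutation_test
#' @return list with `rho`, `z`, `p_perm`, `n_perm`.
#' @export
partial_rsa_permutation_test <- function(fmri, personal, group,
                                         n_perm = 1000, seed = NULL,
                                         estimator = c("fraction", "add_one")) {
  estimator <- match.arg(estimator)
  if (!.is_count(n_perm)) stop("n_perm must be a positive count")
  fmri <- as.numeric(fmri); personal <- as.numeric(personal)
  group <- as.numeric(group)
  s <- .n_from_tri(length(fmri))
  observed <- partial_rsa(fmri, personal, group)
  rf <- rank(fmri); rp <- rank(personal); rg <- rank(group)
  xm <- cbind(1, rg)
  beta <- solve(crossprod(xm), crossprod(xm, rf))
  fitted <- as.numeric(xm %*% beta)
  res <- rf - fitted
  res_mat <- .tri_mat(res, s)
  null_stats <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(s)
      shuffled <- .tri_vec(res_mat[p, p])
      .partial_pearson(fitted + shuffled, rp, rg)
    }, numeric(1))
  })
  list(rho = observed, z = .fisher_z(observed),
       p_perm = .perm_p(null_stats, observed, estimator), n_perm = n_perm)
}
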