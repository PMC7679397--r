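#' Regress nuisance signals out of a run time series
#'
#' Within one run, every voxel time course and every nuisance regressor (six
#' head-motion parameters plus a linear trend) is z-scored, then each voxel
#' is fit by ordinary least squares on the nuisance design and the residuals
#' are returned.  Residuals are exactly orthogonal to every regressor.
#'
#' A constant nuisance column (e.g. a motionless axis) has nothing to
#' regress out and is dropped from the design; a duplicated non-constant
#' column makes the design genuinely rank-deficient and is an error.
#'
#' @param data numeric time x voxel matrix.
#' @param motion numeric time x 6 motion-parameter matrix, rows aligned 1:1
#'   with `data`.
#' @return time x voxel residual matrix.
#' @export
regress_nuisance <- function(data, motion) {
  data <- as.matrix(data); motion <- as.matrix(motion)
  tlen <- nrow(data)
  if (nrow(motion) != tlen) stop("motion rows must align with data rows")
  if (ncol(motion) != 6) stop("expected 6 motion parameters, got ", ncol(motion))
  if (tlen < 8) stop("need at least 8 time points (6 motion + trend + intercept)")
  y <- .zscore_cols(data)
  nuis <- .zscore_cols(cbind(motion, seq_len(tlen)))
  nuis <- nuis[, colSums(abs(nuis)) > 0, drop = FALSE]  # constant -> dropped
  x <- cbind(1, nuis)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    stop("rank-deficient nuisance design: duplicated nuisance column")
  }
  y - x %*% qr.coef(qr_x, y)
}

# Map a window in seconds to whole-volume offsets from onset.  Volumes are
# indexed 0-based from run start; the volume at index j covers
# [j*TR, (j+1)*TR).  A window (start, end] keeps volumes fully inside it:
# offsets start/TR .. end/TR - 1.  For TR 2.5 s and window (5, 15] that is
# +2, +3, +4, +5 -- four volumes.
.window_offsets <- function(window, tr_seconds) {
  off <- window / tr_seconds
  if (any(abs(off - round(off)) > 1e-9)) {
    stop("window (", window[1], ", ", window[2],
         "] s is not expressible in whole volumes at TR ", tr_seconds, " s")
  }
  seq.int(round(off[1]), round(off[2]) - 1L)
}

#' Average residual volumes over the post-onset response window
#'
#' For each scenario presentation, averages the residual volumes falling in
#' the response window after stimulus onset (default (5, 15] seconds, i.e.
#' four volumes at TR 2.5 s, chosen to straddle hemodynamic peaks without
#' assuming a canonical response shape).  Presentations whose window runs
#' past the end of the run are truncated to the available volumes with a
#' warning.
#'
#' @param residuals time x voxel matrix (typically from
#'   [regress_nuisance()]).
#' @param onsets data frame with columns `volume` (0-based onset volume
#'   index) and `scenario` (label).
#' @param tr_seconds repetition time in seconds.
#' @param window numeric length-2, response window (start, end] in seconds
#'   after onset; both ends must be whole multiples of the TR.
#' @return list with `patterns` (presentation x voxel matrix of window
#'   means) and `scenario` (label per presentation).
#' @export
average_scenario_window <- function(residuals, onsets, tr_seconds = 2.5,
                                    window = c(5, 15)) {
  residuals <- as.matrix(residuals)
  offs <- .window_offsets(window, tr_seconds)
  tlen <- nrow(residuals)
  if (!all(diff(onsets$volume) > 0)) stop("onsets must be strictly increasing")
  out <- vapply(seq_len(nrow(onsets)), function(i) {
    vols <- onsets$volume[i] + offs + 1L  # to 1-based row indices
    if (any(vols > tlen)) {
      warning("response window truncated at run end for presentation ", i)
      vols <- vols[vols <= tlen]
    }
    if (length(vols) == 0L) stop("window entirely past run end at presentation ", i)
    colMeans(residuals[vols, , drop = FALSE])
  }, numeric(ncol(residuals)))
  patterns <- if (is.matrix(out)) t(out) else matrix(out, ncol = 1L)
  list(patterns = patterns, scenario = onsets$scenario)
}

#' Inter-run voxel stability scores
#'
#' For every voxel, the Pearson correlation of its S-scenario response
#' profile is computed between each pair of runs (10 coefficients for 5
#' runs), each coefficient is Fisher z (arctanh) transformed, and the
#' stability score is the mean.  High positive scores mark voxels that
#' respond reproducibly to the scenarios.
#'
#' A voxel with zero variance within a run has undefined correlations for
#' the pairs involving that run; those pairs contribute 0 to the mean under
#' the default policy, or are dropped from the mean with
#' `undefined = "drop"` (a voxel undefined in every pair scores 0 either
#' way).
#'
#' @param run_patterns list of R numeric S x V matrices, one per run, rows
#'   in a common scenario order.
#' @param undefined `"zero"` (default) or `"drop"`.
#' @return numeric length-V vector of stability scores.
#' @export
voxel_stability <- function(run_patterns, undefined = c("zero", "drop")) {
  undefined <- match.arg(undefined)
  r <- length(run_patterns)
  if (r < 2) stop("need at least 2 runs")
  s <- nrow(run_patterns[[1L]])
  if (s < 3) stop("need at least 3 scenarios")
  if (!all(vapply(run_patterns, nrow, 1L) == s)) stop("runs differ in scenario count")
  v <- ncol(run_patterns[[1L]])
  zs <- lapply(run_patterns, .zscore_cols)      # zero columns where variance 0
  flat <- lapply(run_patterns, function(m) apply(m, 2L, stats::var) == 0)
  pairs <- utils::combn(r, 2L)
  zsum <- numeric(v)
  nok <- numeric(v)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    rho <- colSums(zs[[i]] * zs[[j]]) / s       # Pearson via standardized cols
    bad <- flat[[i]] | flat[[j]]
    z <- .fisher_z(rho)
    z[bad] <- 0
    zsum <- zsum + z
    nok <- nok + !bad
  }
  n_pairs <- ncol(pairs)
  if (undefined == "zero") {
    zsum / n_pairs
  } else {
    out <- ifelse(nok > 0, zsum / pmax(nok, 1), 0)
    out
  }
}

#' Select the most stable voxels within each region of interest
#'
#' Ranks voxels by stability within each ROI and keeps the top `k`, or the
#' whole ROI when it has fewer than `k` voxels.  Ties are broken by
#' ascending voxel index so selection is deterministic.
#'
#' @param stability length-V stability vector (e.g. [voxel_stability()]).
#' @param roi_labels integer length-V vector of ROI labels; label 0 is
#'   treated as background and ignored.
#' @param k voxels to keep per ROI (default 100).
#' @return named list mapping ROI label to sorted integer voxel indices.
#' @export
select_stable_voxels <- function(stability, roi_labels, k = 100) {
  if (!.is_count(k)) stop("k must be a positive count")
  if (length(stability) != length(roi_labels)) stop("length mismatch")
  rois <- sort(unique(roi_labels[roi_labels != 0]))
  out <- list()
  for (roi in rois) {
    idx <- which(roi_labels == roi)
    if (length(idx) == 0L) {
      warning("empty ROI ", roi, " skipped")
      next
    }
    ord <- idx[order(-stability[idx], idx)]
    out[[as.character(roi)]] <- sort(ord[seq_len(min(k, length(ord)))])
  }
  out
}

#' Build a normalized scenario-pattern matrix for one ROI
#'
#' Averages the per-presentation voxel vectors of each scenario (its
#' replicates across runs), restricts to the selected voxels, then z-scores
#' each voxel across the S scenarios.  A voxel constant across scenarios is
#' zeroed with a warning.  Replicate counts per scenario are recorded: with
#' 5 runs this is 5 everywhere except a scenario losing its first
#' presentation to discarded initial volumes, which has 4.
#'
#' @param presentations presentation x voxel matrix (rows pooled across
#'   runs, e.g. stacked [average_scenario_window()] outputs).
#' @param scenario label per presentation row.
#' @param voxels integer voxel indices to retain (e.g. one entry of
#'   [select_stable_voxels()]); defaults to all.
#' @param roi_id label carried into the result.
#' @param scenario_levels optional scenario ordering for the rows of the
#'   result; defaults to the sorted unique labels.
#' @return object of class `scenario_patterns`: list with `patterns` (S x V
#'   normalized matrix), `roi_id`, `voxel_index`, `replicate_counts`,
#'   `scenarios`.
#' @export
build_scenario_patterns <- function(presentations, scenario,
                                    voxels = seq_len(ncol(presentations)),
                                    roi_id = NA,
                                    scenario_levels = NULL) {
  presentations <- as.matrix(presentations)
  if (nrow(presentations) != length(scenario)) stop("label/row mismatch")
  if (is.null(scenario_levels)) scenario_levels <- sort(unique(scenario))
  if (!all(scenario %in% scenario_levels)) stop("unknown scenario label")
  counts <- as.integer(table(factor(scenario, levels = scenario_levels)))
  if (any(counts == 0L)) {
    stop("scenario(s) with no presentations: ",
         paste(scenario_levels[counts == 0L], collapse = ", "))
  }
  sub <- presentations[, voxels, drop = FALSE]
  avg <- t(vapply(scenario_levels, function(sc) {
    colMeans(sub[scenario == sc, , drop = FALSE])
  }, numeric(ncol(sub))))
  col_var <- apply(avg, 2L, stats::var)
  if (any(col_var == 0)) {
    warning("zero-variance voxel(s) across scenarios zeroed: ",
            paste(voxels[col_var == 0], collapse = ", "))
  }
  norm <- .zscore_cols(avg)
  rownames(norm) <- as.character(scenario_levels)
  structure(list(patterns = norm, roi_id = roi_id,
                 voxel_index = voxels,
                 replicate_counts = stats::setNames(counts,
                                                    as.character(scenario_levels)),
                 scenarios = scenario_levels),
            class = "scenario_patterns")
}

#' @export
print.scenario_patterns <- function(x, ...) {
  cat("scenario_patterns: ", nrow(x$patterns), " scenarios x ",
      ncol(x$patterns), " voxels (ROI ", x$roi_id, ")\n", sep = "")
  invisible(x)
}

#' Read a motion-parameter table
#'
#' Six whitespace-separated columns (x/y/z translation, yaw/pitch/roll), one
#' row per volume, no header.
#'
#' @param path file path.
#' @return numeric time x 6 matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) {
    stop("motion file ", path, " has ", ncol(m), " columns, expected 6")
  }
  dimnames(m) <- NULL
  m
}

#' Write a motion-parameter table
#'
#' @param motion numeric time x 6 matrix.
#' @param path output file path.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion, scientific = FALSE, digits = 9),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
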