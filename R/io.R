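# On-disk layout shared by the writer and the real-data reader:
#   <dir>/embeddings.txt                word-embedding text table
#   <dir>/atlas.nii.gz                  integer ROI label volume
#   <dir>/sub-XX/run-Y_bold.nii.gz      4D time series
#   <dir>/sub-XX/run-Y_motion.txt       6-column motion table
#   <dir>/sub-XX/run-Y_events.tsv       onset volume + scenario per row
#   <dir>/sub-XX/ratings.tsv            scenario x attribute ratings
#   <dir>/sub-XX/descriptions.txt       one description line per scenario

# time x voxel matrix <-> 4D (x, y, z, t) array, voxel linear index with x
# fastest (matching the grid/ROI indexing used throughout).
.mat_to_vol4d <- function(data, grid_dims) {
  array(as.vector(t(data)), c(grid_dims, nrow(data)))
}

.vol4d_to_mat <- function(vol) {
  d <- dim(vol)
  if (length(d) != 4) stop("expected a 4D volume, got ", length(d), "D")
  t(matrix(as.vector(vol), prod(d[1:3]), d[4]))
}

.sub_dir <- function(p) sprintf("sub-%02d", p)

#' Write a synthetic cohort to disk in standard formats
#'
#' Exports every channel of a cohort: one 4D NIfTI plus motion table plus
#' events table per run per participant, a ratings TSV and a descriptions
#' text file per participant, the vocabulary embedding in plain-text
#' dialect, and the ROI atlas as an integer NIfTI label volume.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  cf <- cohort$config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_embeddings(cohort$vocab, file.path(dir, "embeddings.txt"))
  atlas <- array(as.integer(cohort$roi_labels), cf$grid_dims)
  RNifti::writeNifti(RNifti::asNifti(atlas), file.path(dir, "atlas.nii.gz"))
  for (p in seq_len(cf$n_participants)) {
    pd <- file.path(dir, .sub_dir(p))
    dir.create(pd, showWarnings = FALSE)
    for (r in seq_len(cf$n_runs)) {
      run <- cohort$runs[[p]][[r]]
      vol <- RNifti::asNifti(.mat_to_vol4d(run$data, cf$grid_dims))
      RNifti::writeNifti(vol, file.path(pd, sprintf("run-%d_bold.nii.gz", r)))
      write_motion(run$motion, file.path(pd, sprintf("run-%d_motion.txt", r)))
      ev <- data.frame(volume = run$onsets$volume,
                       scenario = run$onsets$scenario,
                       scenario_name = cohort$scenario_names[run$onsets$scenario])
      utils::write.table(ev, file.path(pd, sprintf("run-%d_events.tsv", r)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_ratings_tsv(cohort$ratings[[p]], file.path(pd, "ratings.tsv"))
    writeLines(cohort$descriptions[[p]], file.path(pd, "descriptions.txt"),
               useBytes = TRUE)
  }
  invisible(dir)
}

#' Read an on-disk cohort into the in-memory structure the pipeline uses
#'
#' Reads the layout written by [write_cohort()] (or assembled by hand from
#' real preprocessed data).  Every file is validated as it is read: a
#' missing motion or events file is reported with the participant and run
#' it belongs to, and a run volume whose grid does not match the atlas is
#' reported with both shapes.
#'
#' @param dir data directory.
#' @param n_participants,n_runs how many participants / runs to expect.
#' @param tr_seconds repetition time of the runs (not recoverable from the
#'   text tables; default 2.5).
#' @return list structured like a `synthetic_cohort` (minus `truth` and
#'   `snr`), class `cohort_data`.
#' @export
read_cohort_data <- function(dir, n_participants, n_runs, tr_seconds = 2.5) {
  need <- function(path, what) {
    if (!file.exists(path)) stop("missing ", what, ": ", path)
    path
  }
  vocab <- read_embeddings(need(file.path(dir, "embeddings.txt"),
                                "embedding table"))
  atlas <- RNifti::readNifti(need(file.path(dir, "atlas.nii.gz"),
                                  "atlas label volume"))
  grid_dims <- dim(atlas)[1:3]
  roi_labels <- as.integer(round(as.vector(atlas)))
  runs <- vector("list", n_participants)
  ratings <- vector("list", n_participants)
  descriptions <- vector("list", n_participants)
  scenario_names <- NULL
  for (p in seq_len(n_participants)) {
    pd <- file.path(dir, .sub_dir(p))
    p_runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      tag <- paste0("participant ", p, " run ", r)
      vol <- RNifti::readNifti(need(
        file.path(pd, sprintf("run-%d_bold.nii.gz", r)),
        paste0("bold volume for ", tag)))
      vd <- dim(vol)
      if (length(vd) != 4 || !all(vd[1:3] == grid_dims)) {
        stop("grid mismatch for ", tag, ": volume ",
             paste(vd[1:3], collapse = "x"), " vs atlas ",
             paste(grid_dims, collapse = "x"))
      }
      motion <- read_motion(need(
        file.path(pd, sprintf("run-%d_motion.txt", r)),
        paste0("motion table for ", tag)))
      ev <- utils::read.delim(need(
        file.path(pd, sprintf("run-%d_events.tsv", r)),
        paste0("events table for ", tag)))
      if (!all(c("volume", "scenario") %in% names(ev))) {
        stop("events table for ", tag, " lacks volume/scenario columns")
      }
      p_runs[[r]] <- list(data = .vol4d_to_mat(vol), motion = motion,
                          onsets = ev[c("volume", "scenario")])
      if (is.null(scenario_names) && "scenario_name" %in% names(ev)) {
        scenario_names <- ev$scenario_name[order(ev$scenario)]
      }
    }
    runs[[p]] <- p_runs
    ratings[[p]] <- read_ratings_tsv(need(file.path(pd, "ratings.tsv"),
                                          paste0("ratings for participant ", p)))
    descriptions[[p]] <- readLines(need(file.path(pd, "descriptions.txt"),
                                        paste0("descriptions for participant ", p)),
                                   warn = FALSE, encoding = "UTF-8")
  }
  n_scenarios <- max(vapply(runs[[1L]], function(r) max(r$onsets$scenario), 0))
  if (is.null(scenario_names)) {
    scenario_names <- sprintf("scenario_%02d", seq_len(n_scenarios))
  }
  structure(list(
    config = list(n_participants = n_participants, n_runs = n_runs,
                  n_scenarios = as.integer(n_scenarios),
                  grid_dims = as.integer(grid_dims),
                  tr_seconds = tr_seconds),
    vocab = vocab, roi_labels = roi_labels,
    scenario_names = scenario_names, runs = runs, ratings = ratings,
    descriptions = descriptions), class = "cohort_data")
}

#' Write a searchlight map as NIfTI images
#'
#' Writes the t map and the FDR-adjusted p map of a [searchlight_map()]
#' result as 3D NIfTI volumes.
#'
#' @param map a `searchlight_map`.
#' @param prefix output path prefix; `_t.nii.gz` and `_pfdr.nii.gz` are
#'   appended.
#' @param reference optional NIfTI image supplying the affine/header.
#' @return the two paths, invisibly.
#' @export
write_searchlight_nifti <- function(map, prefix, reference = NULL) {
  paths <- paste0(prefix, c("_t.nii.gz", "_pfdr.nii.gz"))
  imgs <- list(map$t_map, map$p_fdr_map)
  for (i in 1:2) {
    img <- if (is.null(reference)) RNifti::asNifti(imgs[[i]]) else
      RNifti::asNifti(imgs[[i]], reference = reference)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Export a similarity vector as TSV
#'
#' Writes the entries together with their scenario-pair indices and a
#' header comment recording S, the traversal convention, and the source
#' tag, so exports from different tools can be aligned.
#'
#' @param sim a similarity vector (as produced by [similarity_vector()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  s <- attr(sim, "n_scenarios")
  if (is.null(s)) s <- .n_from_tri(length(sim))
  src <- attr(sim, "source")
  if (is.null(src)) src <- "unspecified"
  idx <- which(lower.tri(matrix(0, s, s)), arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_scenarios=%d ordering=lower_tri_column_major source=%s",
                       s, src),
               "row\tcol\tvalue"), con)
  utils::write.table(data.frame(row = idx[, 1L], col = idx[, 2L],
                                value = as.numeric(sim)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a similarity vector written by [write_similarity_tsv()]
#'
#' @param path file path.
#' @return numeric similarity vector with `n_scenarios` and `source`
#'   attributes restored.
#' @export
read_similarity_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.delim(path, comment.char = "#", header = TRUE)
  v <- df$value
  s <- as.integer(sub(".*n_scenarios=([0-9]+).*", "\\1", header))
  attr(v, "n_scenarios") <- s
  attr(v, "source") <- sub(".*source=([^ ]+).*", "\\1", header)
  if (length(v) != s * (s - 1) / 2) stop("corrupt similarity TSV: ", path)
  v
}
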