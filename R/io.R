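# Plain-text exchange of trial patterns, and NIfTI export of simulated
# series: one matrix file per participant x region with a sidecar label
# table, plus a JSON manifest echoing generator parameters.

pattern_stem <- function(roi, participant) {
  sprintf("%s_p%02d", roi, as.integer(participant))
}

#' Export or import trial-pattern sets as TSV
#'
#' Each participant x region pattern set becomes two tab-separated
#' files in `dir`: `<roi>_p<participant>_patterns.tsv` (trials x voxels
#' matrix, no header) and `<roi>_p<participant>_labels.tsv` (columns
#' `memory_id`, `accurate`).  A `patterns_manifest.json` records the
#' stored sets and, when supplied, the generator parameters and seed.
#'
#' @param x A pattern tibble (with `participant`, `roi`, `pattern_set`
#'   columns) or a single `ps_pattern_set`.
#' @param dir Output directory (created if missing).
#' @param parameters Optional list echoed into the manifest.
#' @return `write_patterns` returns `dir` invisibly; `read_patterns`
#'   returns a pattern tibble.
#' @export
write_patterns <- function(x, dir, parameters = NULL) {
  if (inherits(x, "ps_pattern_set")) {
    x <- tibble::tibble(participant = x$participant, roi = x$roi,
                        pattern_set = list(x))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::pmap(x, function(participant, roi, pattern_set, ...) {
    stem <- pattern_stem(roi, participant)
    utils::write.table(pattern_set$patterns,
                       file.path(dir, paste0(stem, "_patterns.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    readr::write_tsv(tibble::tibble(memory_id = pattern_set$labels,
                                    accurate = pattern_set$accurate),
                     file.path(dir, paste0(stem, "_labels.tsv")))
    list(participant = participant, roi = roi, stem = stem,
         n_trials = nrow(pattern_set$patterns),
         n_voxels = ncol(pattern_set$patterns))
  })
  jsonlite::write_json(list(sets = entries, parameters = parameters),
                       file.path(dir, "patterns_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(dir) {
  mpath <- file.path(dir, "patterns_manifest.json")
  if (!file.exists(mpath)) {
    ps_abort("io", sprintf("No patterns_manifest.json found in %s.", dir))
  }
  manifest <- jsonlite::read_json(mpath)
  rows <- lapply(manifest$sets, function(e) {
    pats <- as.matrix(utils::read.table(
      file.path(dir, paste0(e$stem, "_patterns.tsv")), sep = "\t"))
    dimnames(pats) <- NULL
    lab <- readr::read_tsv(file.path(dir, paste0(e$stem, "_labels.tsv")),
                           show_col_types = FALSE, progress = FALSE)
    tibble::tibble(
      participant = e$participant, roi = e$roi,
      pattern_set = list(pattern_set(pats, lab$memory_id, lab$accurate,
                                     participant = e$participant,
                                     roi = e$roi)))
  })
  dplyr::bind_rows(rows)
}

#' Export a simulated time series as 4-D NIfTI plus events TSV
#'
#' Voxels are laid out along the first spatial axis of a
#' `n_voxels x 1 x 1 x timepoints` volume; the companion events table
#' is written with [write_events()].
#'
#' @param ts A `ps_timeseries` from [simulate_timeseries()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param events_path Optional path for the companion events TSV.
#' @return `path` invisibly.
#' @export
write_timeseries <- function(ts, path, events_path = NULL) {
  stopifnot(inherits(ts, "ps_timeseries"))
  arr <- aperm(array(ts$series, dim = c(nrow(ts$series), ncol(ts$series), 1L, 1L)),
               c(1L, 3L, 4L, 2L))
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  if (!is.null(events_path)) write_events(ts$design, events_path)
  invisible(path)
}

#' @rdname write_timeseries
#' @param tr Repetition time attached to the returned object, seconds.
#' @export
read_timeseries <- function(path, events_path = NULL, tr = 2) {
  arr <- as.array(RNifti::readNifti(path))
  series <- matrix(arr, dim(arr)[1], dim(arr)[4])
  design <- if (!is.null(events_path)) read_events(events_path) else NULL
  structure(list(series = series, tr = tr, design = design),
            class = "ps_timeseries")
}
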