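# Region-of-interest masks, voxel-pattern extraction and the
# voxel-count control.

#' Construct an ROI mask
#'
#' @param grid Logical (or coercible) 3-D array; `TRUE` marks voxels
#'   inside the region.
#' @param affine 4x4 voxel-to-world transform (default identity).
#' @param name Region identifier, e.g. `"HC"`, `"EC"`, `"PRC"`, `"PHC"`.
#' @return A `ps_roi_mask` with `name`, `grid`, `affine`, `voxel_size`.
#' @export
roi_mask <- function(grid, affine = diag(4), name = "ROI") {
  grid <- array(as.logical(grid), dim = dim(grid))
  if (length(dim(grid)) != 3L) {
    ps_abort("invalid_parameter", "`grid` must be a 3-D array.")
  }
  if (!any(grid, na.rm = TRUE)) {
    ps_abort("empty_mask", sprintf("Mask '%s' contains no voxels.", name))
  }
  grid[is.na(grid)] <- FALSE
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) {
    ps_abort("invalid_parameter", "`affine` must be a 4x4 matrix.")
  }
  structure(list(name = name, grid = grid, affine = affine,
                 voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "ps_roi_mask")
}

#' @export
print.ps_roi_mask <- function(x, ...) {
  cat(sprintf("<ps_roi_mask> %s: %d voxels in a %s grid\n", x$name,
              sum(x$grid), paste(dim(x$grid), collapse = "x")))
  invisible(x)
}

#' Read or write an ROI mask as NIfTI
#'
#' Any nonzero voxel is taken as inside the region; the affine is
#' preserved.
#'
#' @param path A `.nii` or `.nii.gz` file.
#' @param name Region identifier (defaults to the file stem).
#' @param mask A `ps_roi_mask` (for `write_mask`).
#' @return `read_mask` returns a `ps_roi_mask`; `write_mask` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, name = NULL) {
  if (!file.exists(path)) {
    ps_abort("io", sprintf("Mask file not found: %s", path))
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) ps_abort("io", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
  name <- name %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  roi_mask(arr != 0, affine = RNifti::xform(img), name = name)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ps_roi_mask"))
  img <- RNifti::asNifti(array(as.numeric(mask$grid), dim = dim(mask$grid)))
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract masked voxel patterns from 4-D trial volumes
#'
#' Columns are the masked voxels in ascending linear (array) index
#' order — a fixed, reproducible scan order; rows are trials.
#'
#' @param tmaps A 4-D array (x, y, z, trial), e.g. per-trial t-maps, or
#'   a path to a 4-D NIfTI file.
#' @param mask A `ps_roi_mask` on the same grid (no resampling is done;
#'   a shape mismatch is an error).
#' @param labels Memory label per trial volume.
#' @param accurate Logical flag per trial (default all `TRUE`).
#' @param participant Identifier carried into the output.
#' @return A `ps_pattern_set`.
#' @export
extract_patterns <- function(tmaps, mask, labels, accurate = NULL,
                             participant = NA_integer_) {
  stopifnot(inherits(mask, "ps_roi_mask"))
  if (is.character(tmaps)) tmaps <- as.array(RNifti::readNifti(tmaps))
  d <- dim(tmaps)
  if (length(d) != 4L) {
    ps_abort("shape", "`tmaps` must be a 4-D (x, y, z, trial) array.")
  }
  if (!all(d[1:3] == dim(mask$grid))) {
    ps_abort("shape", sprintf(
      "Data grid %s does not match mask grid %s.",
      paste(d[1:3], collapse = "x"), paste(dim(mask$grid), collapse = "x")))
  }
  vox <- which(mask$grid)
  flat <- matrix(tmaps, prod(d[1:3]), d[4])
  pattern_set(t(flat[vox, , drop = FALSE]), labels, accurate,
              participant = participant, roi = mask$name)
}

#' Randomly subsample voxels (voxel-count control)
#'
#' Draws `k` of the available voxel columns without replacement,
#' keeping the selected columns in their original scan order, so
#' `k = ncol` reproduces the input exactly.  Used to check that
#' decoding differences between regions are not explained by their
#' voxel counts.
#'
#' @param ps A `ps_pattern_set`.
#' @param k Number of voxels to keep.
#' @param seed Integer seed (deterministic selection).
#' @return A `ps_pattern_set` with `k` columns.
#' @export
subsample_voxels <- function(ps, k, seed) {
  stopifnot(inherits(ps, "ps_pattern_set"))
  k <- check_count(k, "k")
  seed <- check_seed(seed)
  nv <- ncol(ps$patterns)
  if (k > nv) {
    ps_abort("invalid_parameter",
             sprintf("`k` (%d) exceeds the %d available voxels.", k, nv))
  }
  keep <- sort(with_seed(seed, sample.int(nv, k)))
  out <- ps
  out$patterns <- ps$patterns[, keep, drop = FALSE]
  attr(out, "voxel_index") <- keep
  out
}

#' Embed a pattern set back into volume space
#'
#' Inverse of [extract_patterns()]: masked voxels receive the pattern
#' values, all other voxels are zero.
#'
#' @param ps A `ps_pattern_set` whose columns match `mask`.
#' @param mask The `ps_roi_mask` used for extraction.
#' @return A 4-D array (x, y, z, trial).
#' @export
embed_patterns <- function(ps, mask) {
  stopifnot(inherits(ps, "ps_pattern_set"), inherits(mask, "ps_roi_mask"))
  vox <- which(mask$grid)
  if (length(vox) != ncol(ps$patterns)) {
    ps_abort("shape", "Pattern columns do not match the mask voxel count.")
  }
  d <- c(dim(mask$grid), nrow(ps$patterns))
  out <- array(0, dim = d)
  flat <- matrix(out, prod(d[1:3]), d[4])
  flat[vox, ] <- t(ps$patterns)
  array(flat, dim = d)
}
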