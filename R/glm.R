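# Single-trial beta-series GLM: canonical double-gamma HRF, per-trial
# boxcar regressors, least-squares fitting and beta-to-t conversion.

#' Canonical double-gamma HRF parameters
#'
#' The kernel is the difference of two gamma densities (response minus a
#' scaled undershoot), the canonical shape used by SPM-style analyses.
#' With the defaults the response peaks near 5 s and the undershoot near
#' 15 s.  Delays are in seconds; `dispersion` parameters are the gamma
#' scale (so shape = delay / dispersion).
#'
#' @param peak_delay Delay of the response gamma, seconds (default 6).
#' @param undershoot_delay Delay of the undershoot gamma (default 16).
#' @param peak_dispersion,undershoot_dispersion Gamma scales (default 1).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @param kernel_length Support of the sampled kernel, seconds
#'   (default 32; must exceed `undershoot_delay`).
#' @return A `ps_hrf_params` list.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, kernel_length = 32) {
  check_positive(peak_delay, "peak_delay")
  check_positive(undershoot_delay, "undershoot_delay")
  check_positive(peak_dispersion, "peak_dispersion")
  check_positive(undershoot_dispersion, "undershoot_dispersion")
  check_positive(undershoot_ratio, "undershoot_ratio", strict = FALSE)
  check_positive(kernel_length, "kernel_length")
  if (kernel_length <= undershoot_delay) {
    ps_abort("invalid_parameter",
             "`kernel_length` must exceed `undershoot_delay`.")
  }
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length),
            class = "ps_hrf_params")
}

#' Sample the canonical HRF kernel
#'
#' @param tr Sampling interval, seconds.
#' @param params An [hrf_params()] object.
#' @return Numeric vector sampled at `0, tr, 2 tr, ...` over
#'   `kernel_length`, scaled to a maximum of exactly 1.
#' @export
#' @examples
#' h <- canonical_hrf(2)
#' plot(seq_along(h) * 2 - 2, h, type = "l")
canonical_hrf <- function(tr, params = hrf_params()) {
  check_positive(tr, "tr")
  stopifnot(inherits(params, "ps_hrf_params"))
  t <- seq(0, params$kernel_length, by = tr)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    params$undershoot_ratio *
      stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
                    scale = params$undershoot_dispersion)
  h / max(h)
}

#' Build the single-trial design matrix
#'
#' One regressor per trial — a boxcar over `[onset, onset + duration)`
#' sampled at the volume grid and convolved with the HRF kernel — plus
#' polynomial drift columns and a constant.  All trials sit in a single
#' model, so each trial's estimate is adjusted for the overlap of its
#' neighbours.
#'
#' @param design A single participant's rows of a `ps_design` (or any
#'   tibble with `onset`/`duration`), timing attributes included.
#' @param hrf [hrf_params()] kernel settings, or a numeric vector used
#'   directly as the sampled kernel.
#' @param drift_order Order of the polynomial drift terms (default 1;
#'   0 = constant only).
#' @param tr Sampling interval; defaults to the design's `tr` attribute.
#' @return A `ps_design_matrix`: list with `values` (timepoints x
#'   regressors), `names`, `trial_cols`, `tr`.
#' @export
build_design_matrix <- function(design, hrf = hrf_params(), drift_order = 1,
                                tr = NULL) {
  if (length(unique(design$participant %||% 1L)) > 1L) {
    ps_abort("invalid_parameter",
             "`design` must contain a single participant's trials.")
  }
  tr <- tr %||% design_tr(design)
  check_positive(tr, "tr")
  drift_order <- check_count(drift_order, "drift_order", min = 0L)
  if (is.null(design$onset) || is.null(design$duration) ||
      is.unsorted(design$onset, strictly = TRUE)) {
    ps_abort("invalid_parameter",
             "`design` needs strictly increasing onsets and durations.")
  }
  kern <- if (inherits(hrf, "ps_hrf_params")) canonical_hrf(tr, hrf) else as.numeric(hrf)
  klen <- length(kern)
  n_trials <- nrow(design)
  t_end <- max(design$onset + design$duration) + (klen - 1) * tr
  n_tp <- ceiling(t_end / tr) + 1L
  times <- (seq_len(n_tp) - 1) * tr

  trial_mat <- vapply(seq_len(n_trials), function(i) {
    box <- as.numeric(times >= design$onset[i] &
                      times < design$onset[i] + design$duration[i])
    conv <- convolve_truncate(box, kern)
    conv
  }, numeric(n_tp))
  colnames(trial_mat) <- sprintf("trial_%03d", seq_len(n_trials))

  extras <- matrix(1, n_tp, 1L, dimnames = list(NULL, "constant"))
  if (drift_order >= 1L) {
    drift <- stats::poly(times, degree = drift_order)
    colnames(drift) <- sprintf("drift_%d", seq_len(drift_order))
    extras <- cbind(drift, extras)
  }
  values <- cbind(trial_mat, extras)
  structure(list(values = values, names = colnames(values),
                 trial_cols = seq_len(n_trials), tr = tr),
            class = "ps_design_matrix")
}

# causal discrete convolution truncated to the length of `x`
convolve_truncate <- function(x, kern) {
  out <- numeric(length(x))
  nz <- which(x != 0)
  for (i in nz) {
    j <- i:min(length(x), i + length(kern) - 1L)
    out[j] <- out[j] + x[i] * kern[seq_along(j)]
  }
  out
}

#' Fit the single-trial GLM
#'
#' Ordinary least squares per voxel: `beta = (X'X)^-1 X' y`, residual
#' variance `sigma2 = RSS / dof` with `dof = timepoints - rank`, and the
#' per-trial t statistic `t_i = beta_i / sqrt(sigma2 * [(X'X)^-1]_ii)` —
#' the beta-to-t conversion that scales each trial estimate by its
#' standard error under the full model.
#'
#' @param series A `ps_timeseries` or a voxels x timepoints matrix.
#' @param X A `ps_design_matrix` from [build_design_matrix()].
#' @return A `ps_glm_fit`: list with `beta` and `t` (trials x voxels,
#'   trial regressors only), `sigma2`, `dof`, `xtx_inv_diag`, `names`.
#' @export
fit_glm <- function(series, X) {
  stopifnot(inherits(X, "ps_design_matrix"))
  if (inherits(series, "ps_timeseries")) series <- series$series
  series <- as.matrix(series)
  xm <- X$values
  if (ncol(series) != nrow(xm)) {
    ps_abort("shape", sprintf(
      "series has %d timepoints but the design matrix has %d rows.",
      ncol(series), nrow(xm)))
  }
  qx <- qr(xm)
  p <- ncol(xm)
  if (qx$rank < p) {
    bad <- X$names[qx$pivot[(qx$rank + 1L):p]]
    ps_abort("singular_design", sprintf(
      "Design matrix is rank deficient; collinear column(s): %s.",
      paste(bad, collapse = ", ")))
  }
  n_tp <- nrow(xm)
  dof <- n_tp - p
  if (dof < 1) ps_abort("invalid_parameter", "Residual dof must be >= 1.")
  y <- t(series)                              # timepoints x voxels
  beta_all <- qr.coef(qx, y)                  # regressors x voxels
  resid <- y - xm %*% beta_all
  sigma2 <- colSums(resid^2) / dof
  # relative threshold: residual variance at rounding-error level means
  # the model interpolates the data and t-values are undefined
  degenerate <- sigma2 <= colMeans(y^2) * 1e-12
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  lev <- diag(xtx_inv)
  tc <- X$trial_cols
  beta <- t(beta_all[tc, , drop = FALSE])     # voxels x trials -> transpose
  se <- sqrt(outer(lev[tc], sigma2))          # trials x voxels
  tval <- t(beta) / se
  tval[, degenerate] <- NA_real_
  structure(list(beta = t(beta), t = tval, sigma2 = sigma2,
                 degenerate = degenerate, dof = dof,
                 xtx_inv_diag = lev, names = X$names),
            class = "ps_glm_fit")
}

#' Per-trial t-maps for accurately recalled trials
#'
#' Keeps only trials flagged as accurately recalled and returns their
#' t-statistic patterns as a [pattern_set()] ready for decoding.
#'
#' @param fit A `ps_glm_fit` from [fit_glm()].
#' @param labels Memory label per trial.
#' @param accurate Logical flag per trial.
#' @param participant,roi Identifiers attached to the output.
#' @return A `ps_pattern_set` of t-value patterns.
#' @export
trial_tmaps <- function(fit, labels, accurate = NULL,
                        participant = NA_integer_, roi = NA_character_) {
  stopifnot(inherits(fit, "ps_glm_fit"))
  n_trials <- nrow(fit$t)
  labels <- as_memory_factor(labels)
  if (is.null(accurate)) accurate <- rep(TRUE, n_trials)
  if (length(labels) != n_trials || length(accurate) != n_trials) {
    ps_abort("shape", "labels/accurate must have one entry per trial.")
  }
  if (any(fit$degenerate)) {
    ps_abort("degenerate_input", paste(
      "Residual variance is zero at some voxels, so t-values are undefined;",
      "add noise or drop constant voxels."))
  }
  keep <- which(accurate)
  tab <- table(labels[keep])
  if (any(tab < 2)) {
    ps_abort("insufficient_trials", sprintf(
      "Fewer than 2 accurate trials in condition(s): %s.",
      paste(names(tab)[tab < 2], collapse = ", ")))
  }
  pattern_set(fit$t[keep, , drop = FALSE], labels[keep],
              rep(TRUE, length(keep)), participant = participant, roi = roi)
}
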