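# Synthetic voxel patterns and BOLD time series with controllable
# bound-memory, shared-context and shared-event signal components.

#' Specify the synthetic signal composition
#'
#' Each participant receives independent unit-norm voxel templates: one
#' per memory (the "bound" trace unique to each episode), one per
#' spatial context (shared by the two memories set in that context) and
#' one per action event (shared by the two memories containing that
#' event).  A trial's pattern is the amplitude-weighted sum of its three
#' templates plus isotropic Gaussian noise, so the detectability of
#' bound traces, shared context and shared event content can be dialled
#' independently.
#'
#' Templates are drawn as unit-norm Gaussian directions and multiplied
#' by `template_scale`, so an amplitude `a` produces a distributed
#' signal with per-voxel root-mean-square contrast
#' `a * template_scale / sqrt(n_voxels)` in units of `noise_sd`.  The
#' default `template_scale = 4` places the default amplitudes in the
#' regime typical of region-of-interest fMRI decoding: per-voxel
#' contrast-to-noise near 0.1, single-participant four-way accuracy
#' well above chance but far from ceiling, so misclassifications remain
#' plentiful enough to analyse.
#'
#' Defaults (300 voxels, `amp_bound = amp_context = 0.5`,
#' `amp_event = 0`, `noise_sd = 1`) emulate a hippocampus-like region in
#' which individual memories and their shared spatial contexts are
#' decodable but event content alone is not.
#'
#' @param n_voxels Number of voxels in the simulated region.
#' @param amp_bound Amplitude of the memory-unique (bound) component.
#' @param amp_context Amplitude of the shared spatial-context component.
#' @param amp_event Amplitude of the shared event-content component.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param template_scale Multiplier applied to the unit-norm templates
#'   (default 4); fixes the per-voxel contrast-to-noise scale of the
#'   amplitude parameters.
#' @param p_inaccurate Probability that a trial is flagged as not
#'   accurately recalled (such trials are excluded from decoding).
#' @param orthogonalize If `TRUE`, Gram-Schmidt the eight templates so
#'   the three components are exactly orthogonal; by default templates
#'   are independent random directions (near-orthogonal at realistic
#'   voxel counts).
#' @return A `ps_signal_spec` list.
#' @export
#' @examples
#' signal_spec(amp_bound = 1, amp_context = 0, noise_sd = 0.5)
signal_spec <- function(n_voxels = 300, amp_bound = 0.5, amp_context = 0.5,
                        amp_event = 0, noise_sd = 1, p_inaccurate = 0.05,
                        template_scale = 4, orthogonalize = FALSE) {
  n_voxels <- check_count(n_voxels, "n_voxels")
  check_positive(amp_bound, "amp_bound", strict = FALSE)
  check_positive(amp_context, "amp_context", strict = FALSE)
  check_positive(amp_event, "amp_event", strict = FALSE)
  check_positive(noise_sd, "noise_sd")
  check_positive(template_scale, "template_scale")
  if (!is.numeric(p_inaccurate) || length(p_inaccurate) != 1L ||
      p_inaccurate < 0 || p_inaccurate >= 1) {
    ps_abort("invalid_parameter", "`p_inaccurate` must lie in [0, 1).")
  }
  structure(list(n_voxels = n_voxels, amp_bound = amp_bound,
                 amp_context = amp_context, amp_event = amp_event,
                 noise_sd = noise_sd, p_inaccurate = p_inaccurate,
                 template_scale = template_scale,
                 orthogonalize = isTRUE(orthogonalize)),
            class = "ps_signal_spec")
}

#' Construct a trial-by-voxel pattern set
#'
#' The atomic container passed to the decoding functions: a trials x
#' voxels matrix of activation estimates with a memory label and a
#' recall-accuracy flag per trial.
#'
#' @param patterns Numeric trials x voxels matrix, finite values only.
#' @param labels Memory labels (`"A"`–`"D"`), one per trial.
#' @param accurate Logical accuracy flag per trial (default all `TRUE`).
#' @param participant,roi Identifiers carried along for bookkeeping.
#' @return A `ps_pattern_set` object.
#' @export
pattern_set <- function(patterns, labels, accurate = NULL,
                        participant = NA_integer_, roi = NA_character_) {
  patterns <- as.matrix(patterns)
  if (!is.numeric(patterns) || !all(is.finite(patterns))) {
    ps_abort("invalid_parameter", "`patterns` must be a finite numeric matrix.")
  }
  labels <- as_memory_factor(labels)
  if (is.null(accurate)) accurate <- rep(TRUE, nrow(patterns))
  accurate <- as.logical(accurate)
  if (nrow(patterns) != length(labels) || nrow(patterns) != length(accurate)) {
    ps_abort("shape", sprintf(
      "Row count (%d), label count (%d) and flag count (%d) must agree.",
      nrow(patterns), length(labels), length(accurate)))
  }
  structure(list(patterns = patterns, labels = labels, accurate = accurate,
                 participant = participant, roi = roi),
            class = "ps_pattern_set")
}

#' @export
print.ps_pattern_set <- function(x, ...) {
  cat(sprintf("<ps_pattern_set> participant %s, roi %s: %d trials x %d voxels (%d accurate)\n",
              format(x$participant), format(x$roi), nrow(x$patterns),
              ncol(x$patterns), sum(x$accurate)))
  invisible(x)
}

unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# participant-level templates: 4 bound + 2 context + 2 event directions
draw_templates <- function(spec) {
  tpl <- unit_rows(8L, spec$n_voxels)
  if (spec$orthogonalize) {
    q <- qr.Q(qr(t(tpl)))[, 1:8]
    # keep orientation aligned with the raw draws
    s <- sign(colSums(q * t(tpl)))
    tpl <- t(q) * s
  }
  tpl <- tpl * (spec$template_scale %||% 1)
  list(bound = tpl[1:4, , drop = FALSE],
       context = tpl[5:6, , drop = FALSE],
       event = tpl[7:8, , drop = FALSE])
}

# noiseless per-trial amplitude patterns for one participant
signal_matrix <- function(labels, spec, tpl) {
  m <- as.integer(as_memory_factor(labels))
  e <- unname(EVENT_OF[as.character(labels)])
  cx <- unname(CONTEXT_OF[as.character(labels)])
  spec$amp_bound * tpl$bound[m, , drop = FALSE] +
    spec$amp_context * tpl$context[cx, , drop = FALSE] +
    spec$amp_event * tpl$event[e, , drop = FALSE]
}

#' Simulate trial-wise voxel patterns
#'
#' Draws, for every participant in the design, the template set
#' described in [signal_spec()] and produces one activation pattern per
#' trial: `amp_bound * u_memory + amp_context * v_context +
#' amp_event * w_event + noise`, with accuracy flags drawn
#' `Bernoulli(1 - p_inaccurate)`.  Deterministic given `seed`;
#' participants use independent derived sub-seeds.
#'
#' @param design A `ps_design` from [make_design()].
#' @param spec A `ps_signal_spec`.
#' @param seed Integer seed.
#' @param roi Region label attached to the output (default `"HC"`).
#' @return A tibble with one row per participant: `participant`, `roi`,
#'   and a `pattern_set` list-column of [pattern_set()] objects.
#' @export
#' @examples
#' d <- make_design(2, 5, seed = 1)
#' sim <- simulate_patterns(d, signal_spec(n_voxels = 50), seed = 1)
#' sim$pattern_set[[1]]
simulate_patterns <- function(design, spec, seed, roi = "HC") {
  stopifnot(inherits(spec, "ps_signal_spec"))
  seed <- check_seed(seed)
  split_design <- split(design, design$participant)
  rows <- lapply(split_design, function(dp) {
    p <- dp$participant[1]
    ps <- with_seed(derive_seed(seed, "patterns", roi, p), {
      tpl <- draw_templates(spec)
      sig <- signal_matrix(dp$memory_id, spec, tpl)
      noise <- matrix(stats::rnorm(length(sig), sd = spec$noise_sd),
                      nrow(sig), ncol(sig))
      acc <- stats::runif(nrow(sig)) >= spec$p_inaccurate
      pattern_set(sig + noise, dp$memory_id, acc, participant = p, roi = roi)
    })
    tibble::tibble(participant = p, roi = roi, pattern_set = list(ps))
  })
  dplyr::bind_rows(rows)
}

#' Simulate BOLD time series for the single-trial GLM stage
#'
#' Builds, per participant, the per-trial HRF-convolved design matrix,
#' multiplies it by trial-wise voxel amplitudes drawn from the same
#' generative model as [simulate_patterns()], and adds white or AR(1)
#' noise: `series = B' X' + E`.  With `sd = 0` the series equals the
#' noiseless construction exactly, so GLM estimates recover the
#' generated amplitudes to numerical precision.
#'
#' @inheritParams simulate_patterns
#' @param hrf [hrf_params()] settings for the convolution kernel.
#' @param noise List with elements `model` (`"white"` or `"ar1"`), `sd`
#'   (innovation standard deviation, may be 0) and `rho` (AR(1)
#'   coefficient, in (-1, 1)).
#' @return A tibble with one row per participant: `participant`,
#'   `timeseries` (list of `ps_timeseries`: `series` voxels x timepoints,
#'   `tr`, `design`), `amplitudes` (list of the true trials x voxels
#'   amplitude matrices) and `accurate` (list of flags).
#' @export
simulate_timeseries <- function(design, spec, hrf = hrf_params(),
                                noise = list(model = "white", sd = 1, rho = 0),
                                seed) {
  stopifnot(inherits(spec, "ps_signal_spec"))
  seed <- check_seed(seed)
  model <- match.arg(noise$model %||% "white", c("white", "ar1"))
  sd <- noise$sd %||% 1
  rho <- noise$rho %||% 0
  check_positive(sd, "noise$sd", strict = FALSE)
  if (model == "ar1" && (rho <= -1 || rho >= 1)) {
    ps_abort("invalid_parameter", "`noise$rho` must lie in (-1, 1).")
  }
  split_design <- split(design, design$participant)
  rows <- lapply(split_design, function(dp) {
    p <- dp$participant[1]
    with_seed(derive_seed(seed, "timeseries", p), {
      tpl <- draw_templates(spec)
      B <- signal_matrix(dp$memory_id, spec, tpl)  # trials x voxels
      acc <- stats::runif(nrow(B)) >= spec$p_inaccurate
      X <- build_design_matrix(dp, hrf = hrf, drift_order = 0)
      Xt <- X$values[, X$trial_cols, drop = FALSE]
      clean <- t(Xt %*% B)                         # voxels x timepoints
      if (sd > 0) {
        E <- matrix(stats::rnorm(length(clean), sd = sd),
                    nrow(clean), ncol(clean))
        if (model == "ar1" && rho != 0) {
          E <- t(apply(E, 1, function(e) as.numeric(stats::filter(e, rho, "recursive"))))
        }
        clean <- clean + E
      }
      ts <- structure(list(series = clean, tr = design_tr(design),
                           design = dp),
                      class = "ps_timeseries")
      tibble::tibble(participant = p, timeseries = list(ts),
                     amplitudes = list(B), accurate = list(acc))
    })
  })
  dplyr::bind_rows(rows)
}
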