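# End-to-end orchestration: simulate (or ingest) patterns for several
# regions, run the four analyses, and assemble group-level tables.

#' Assemble a run configuration
#'
#' Collects every parameter of an end-to-end run.  `rois` is a named
#' list of [signal_spec()] objects, one simulated region per entry; the
#' default mirrors the study layout: a hippocampus-like region carrying
#' bound-memory and shared-context signal, and three null
#' medial-temporal regions (EC, PRC, PHC) carrying noise only.
#'
#' @param seed Master integer seed (mandatory; every random draw in the
#'   run derives from it).
#' @param n_participants,n_trials_per_condition Design size (defaults
#'   15 and 20).
#' @param rois Named list of `ps_signal_spec` objects.
#' @param cost,normalize Decoding options.
#' @param n_perm Permutations for the group permutation test (0 skips
#'   it; when positive, at least 100).
#' @param alpha Significance level recorded with the results.
#' @param use_timeseries If `TRUE`, simulate BOLD time series and
#'   estimate trial patterns through the single-trial GLM instead of
#'   generating patterns directly.
#' @param hrf,noise,drift_order GLM-path options (see
#'   [simulate_timeseries()] and [build_design_matrix()]).
#' @param recall_duration,iti,tr Trial timing, seconds.
#' @param out_dir Directory for result tables and the manifest; `NULL`
#'   writes nothing.
#' @return A `ps_run_config` list.
#' @export
run_config <- function(seed,
                       n_participants = 15, n_trials_per_condition = 20,
                       rois = list(
                         HC = signal_spec(),
                         EC = signal_spec(amp_bound = 0, amp_context = 0),
                         PRC = signal_spec(amp_bound = 0, amp_context = 0),
                         PHC = signal_spec(amp_bound = 0, amp_context = 0)),
                       cost = 1, normalize = "none", n_perm = 0,
                       alpha = 0.05, use_timeseries = FALSE,
                       hrf = hrf_params(),
                       noise = list(model = "white", sd = 1, rho = 0),
                       drift_order = 1,
                       recall_duration = 12, iti = 4, tr = 2,
                       out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    ps_abort("config", "Config field `seed` is required.")
  }
  seed <- check_seed(seed)
  if (!is.list(rois) || is.null(names(rois)) || any(names(rois) == "") ||
      !all(vapply(rois, inherits, TRUE, "ps_signal_spec"))) {
    ps_abort("config",
             "Config field `rois` must be a named list of signal_spec objects.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    ps_abort("config", "Config field `alpha` must lie in (0, 1).")
  }
  if (n_perm != 0) n_perm <- check_count(n_perm, "n_perm", min = 100L)
  structure(list(seed = seed, n_participants = n_participants,
                 n_trials_per_condition = n_trials_per_condition,
                 rois = rois, cost = cost, normalize = normalize,
                 n_perm = n_perm, alpha = alpha,
                 use_timeseries = isTRUE(use_timeseries),
                 hrf = hrf, noise = noise, drift_order = drift_order,
                 recall_duration = recall_duration, iti = iti, tr = tr,
                 out_dir = out_dir),
            class = "ps_run_config")
}

roi_patterns <- function(config, design, roi) {
  spec <- config$rois[[roi]]
  if (!config$use_timeseries) {
    return(simulate_patterns(design, spec,
                             seed = derive_seed(config$seed, "simulate", roi),
                             roi = roi))
  }
  ts_tbl <- simulate_timeseries(design, spec, hrf = config$hrf,
                                noise = config$noise,
                                seed = derive_seed(config$seed, "simulate", roi))
  rows <- purrr::pmap(ts_tbl, function(participant, timeseries, amplitudes,
                                       accurate) {
    dp <- timeseries$design
    X <- build_design_matrix(dp, hrf = config$hrf,
                             drift_order = config$drift_order)
    fit <- fit_glm(timeseries, X)
    ps <- trial_tmaps(fit, dp$memory_id, accurate,
                      participant = participant, roi = roi)
    tibble::tibble(participant = participant, roi = roi,
                   pattern_set = list(ps))
  })
  dplyr::bind_rows(rows)
}

group_row <- function(gr, roi, analysis, n_perm) {
  tibble::tibble(
    roi = roi, analysis = analysis,
    mean_accuracy = gr$mean, chance = gr$chance,
    pct_above_chance = 100 * (gr$mean - gr$chance),
    sem = gr$sem, t = gr$t, df = gr$df, p = gr$p,
    perm_p = gr$perm_p, n_perm = n_perm)
}

#' Run the full analysis pipeline
#'
#' Simulates (or GLM-estimates) trial patterns for every configured
#' region, then runs per participant the four-way leave-one-trial-out
#' decoding, the context- and content-transfer analyses and the
#' misclassification decomposition, and assembles group-level
#' one-tailed t-tests against chance (plus permutation tests when
#' `n_perm > 0`).  Reruns with an identical configuration are
#' identical.
#'
#' @param config A [run_config()] object.
#' @return A `ps_run` list: `patterns` (tibble of pattern sets),
#'   `decoding` (per participant x region accuracies), `group`
#'   (region x analysis inference table), `misclass` (per-participant
#'   error profiles and their group contrasts), `config`, `manifest`.
#'   With `out_dir` set, result tables, confusion matrices and the
#'   manifest are also written there.
#' @export
#' @examples
#' cfg <- run_config(seed = 1, n_participants = 3,
#'                   n_trials_per_condition = 4,
#'                   rois = list(HC = signal_spec(n_voxels = 40)))
#' res <- run_all(cfg)
#' res$group
run_all <- function(config) {
  if (!inherits(config, "ps_run_config")) {
    ps_abort("config", "`config` must come from run_config().")
  }
  design <- make_design(config$n_participants, config$n_trials_per_condition,
                        recall_duration = config$recall_duration,
                        iti = config$iti, tr = config$tr,
                        seed = derive_seed(config$seed, "design"))
  analyses <- c("fourway", "context_transfer", "content_transfer")
  patterns <- decoding <- group <- misclass_tbl <- list()
  contrasts <- confusions <- list()

  for (roi in names(config$rois)) {
    tbl <- roi_patterns(config, design, roi)
    patterns[[roi]] <- tbl

    four <- decode_loto(tbl, cost = config$cost, normalize = config$normalize)
    ctx <- decode_transfer(tbl, "context", cost = config$cost,
                           normalize = config$normalize)
    cnt <- decode_transfer(tbl, "event", cost = config$cost,
                           normalize = config$normalize)
    decoding[[roi]] <- dplyr::bind_rows(
      tibble::tibble(roi = roi, analysis = "fourway",
                     participant = four$participant,
                     accuracy = four$accuracy, chance = four$chance),
      tibble::tibble(roi = roi, analysis = "context_transfer",
                     participant = ctx$participant,
                     accuracy = ctx$accuracy, chance = ctx$chance),
      tibble::tibble(roi = roi, analysis = "content_transfer",
                     participant = cnt$participant,
                     accuracy = cnt$accuracy, chance = cnt$chance))

    accs <- list(fourway = four$accuracy, context_transfer = ctx$accuracy,
                 content_transfer = cnt$accuracy)
    chances <- c(fourway = 0.25, context_transfer = 0.5,
                 content_transfer = 0.5)
    for (an in analyses) {
      gr <- if (config$n_perm > 0) {
        permutation_test(tbl, an, n_perm = config$n_perm,
                         seed = derive_seed(config$seed, "permtest", roi),
                         cost = config$cost, normalize = config$normalize)
      } else {
        tryCatch(t_vs_chance(accs[[an]], chances[[an]]),
                 patternsep_error_zero_variance = function(e) {
                   a <- accs[[an]]
                   structure(list(per_participant = a,
                                  chance = chances[[an]], mean = mean(a),
                                  sem = 0, t = NA_real_,
                                  df = length(a) - 1L, p = NA_real_,
                                  perm_p = NA_real_, n_permutations = 0L,
                                  null_means = numeric(0)),
                             class = "ps_group_result")
                 })
      }
      group[[paste(roi, an)]] <- group_row(gr, roi, an, config$n_perm)
    }

    confusions[[roi]] <- stats::setNames(purrr::map(four$decoding, "confusion"),
                                         four$participant)
    profiles <- purrr::map(four$decoding, misclass_profile)
    misclass_tbl[[roi]] <- tibble::tibble(
      roi = roi, participant = four$participant,
      n_errors = purrr::map_int(profiles, "n_errors"),
      prop_spatial = purrr::map_dbl(profiles, ~ .x$proportions[["spatial"]]),
      prop_content = purrr::map_dbl(profiles, ~ .x$proportions[["content"]]),
      prop_orthogonal = purrr::map_dbl(profiles, ~ .x$proportions[["orthogonal"]]),
      misclass = profiles)
    contrasts[[roi]] <- purrr::map(
      c(spatial_vs_content = "spatial_vs_content",
        spatial_vs_orthogonal = "spatial_vs_orthogonal"),
      function(ctr) tryCatch(compare_misclass(profiles, ctr),
                             patternsep_error_insufficient_data = function(e) NULL,
                             patternsep_error_zero_variance = function(e) NULL))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("patternsep")),
    seed = config$seed,
    stage_seeds = c(
      design = derive_seed(config$seed, "design"),
      stats::setNames(vapply(names(config$rois), function(r)
        derive_seed(config$seed, "simulate", r), integer(1)),
        paste0("simulate_", names(config$rois)))),
    n_participants = config$n_participants,
    n_trials_per_condition = config$n_trials_per_condition,
    rois = lapply(config$rois, unclass),
    cost = config$cost, normalize = config$normalize,
    n_perm = config$n_perm, alpha = config$alpha,
    use_timeseries = config$use_timeseries,
    permutation_scheme = "within-participant label shuffle, add-one p-value",
    voxel_scan_order = "ascending array index")

  res <- structure(list(
    patterns = dplyr::bind_rows(patterns),
    decoding = dplyr::bind_rows(decoding),
    group = dplyr::bind_rows(group),
    misclass = dplyr::bind_rows(misclass_tbl),
    misclass_contrasts = contrasts,
    confusions = confusions,
    config = config, manifest = manifest, design = design),
    class = "ps_run")

  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$group, file.path(out_dir, "group_results.csv"))
  readr::write_csv(res$decoding, file.path(out_dir, "decoding_results.csv"))
  readr::write_csv(
    dplyr::select(res$misclass, -"misclass"),
    file.path(out_dir, "misclassification.csv"))
  jsonlite::write_json(
    lapply(res$confusions, function(r) lapply(r, unname)),
    file.path(out_dir, "confusion.json"), pretty = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ps_run <- function(x, ...) {
  cat("<ps_run>\n")
  print(x$group)
  invisible(x)
}
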