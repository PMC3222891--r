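# Misclassification decomposition, group-level one-tailed t-tests
# against chance, and label-permutation inference.

#' Decompose four-way misclassifications by shared factor
#'
#' Every off-diagonal cell of the confusion matrix is a misclassification
#' of exactly one type: `spatial` (the predicted memory shares the true
#' trial's spatial context), `content` (shares its event content) or
#' `orthogonal` (shares neither).  A spatial bias in these errors would
#' indicate that four-way decoding rests on context rather than on
#' memory-unique representations.
#'
#' @param x A `ps_decoding`, or a 4x4 confusion matrix with memory
#'   labels as dimnames (rows = true, columns = predicted).
#' @return A `ps_misclass`: list with integer `counts`, `proportions`
#'   (all `NA` when there are no errors) and `n_errors`.
#' @export
#' @examples
#' cm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' cm["A", "C"] <- 3; cm["B", "D"] <- 2; cm["A", "B"] <- 1
#' misclass_profile(cm)
misclass_profile <- function(x) {
  cm <- if (inherits(x, "ps_decoding")) x$confusion else as.matrix(x)
  if (is.null(dimnames(cm)) || is.null(rownames(cm))) {
    dimnames(cm) <- list(MEMORY_LEVELS[seq_len(nrow(cm))],
                         MEMORY_LEVELS[seq_len(ncol(cm))])
  }
  counts <- c(spatial = 0L, content = 0L, orthogonal = 0L)
  for (i in rownames(cm)) {
    for (j in colnames(cm)) {
      if (i == j) next
      rel <- as.character(label_relation(i, j))
      counts[rel] <- counts[rel] + as.integer(cm[i, j])
    }
  }
  total <- sum(counts)
  props <- if (total > 0) counts / total else
    stats::setNames(rep(NA_real_, 3), names(counts))
  structure(list(counts = counts, proportions = props, n_errors = total),
            class = "ps_misclass")
}

#' @export
print.ps_misclass <- function(x, ...) {
  cat(sprintf("<ps_misclass> %d errors: spatial %s, content %s, orthogonal %s\n",
              x$n_errors,
              format(x$proportions[["spatial"]], digits = 3),
              format(x$proportions[["content"]], digits = 3),
              format(x$proportions[["orthogonal"]], digits = 3)))
  invisible(x)
}

one_tailed_t <- function(diffs, what = "values") {
  n <- length(diffs)
  if (n < 2L) {
    ps_abort("insufficient_data",
             sprintf("Need at least 2 %s, got %d.", what, n))
  }
  s <- stats::sd(diffs)
  if (s == 0) {
    if (all(diffs == 0)) {
      # exact null: no effect and no variability, report t = 0
      return(list(t = 0, df = n - 1L, p = 0.5, mean = 0, sem = 0, n = n))
    }
    ps_abort("zero_variance",
             sprintf("The %s have zero variance; t is undefined.", what))
  }
  t <- mean(diffs) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = t_tail_p(t, n - 1L),
       mean = mean(diffs), sem = s / sqrt(n), n = n)
}

#' Paired contrast of misclassification proportions
#'
#' One-tailed paired t-test of whether the spatial misclassification
#' proportion exceeds the content (or orthogonal) proportion across
#' participants.  Participants without any misclassification carry no
#' proportions and are excluded with a warning.
#'
#' @param profiles A list of `ps_misclass` objects (one per
#'   participant), or a tibble holding them in a `misclass` list-column.
#' @param contrast `"spatial_vs_content"` or `"spatial_vs_orthogonal"`.
#' @return A `ps_group_test`: list with `t`, `df`, `p` (upper tail:
#'   spatial greater), `mean_difference`, `n`.
#' @export
compare_misclass <- function(profiles,
                             contrast = c("spatial_vs_content",
                                          "spatial_vs_orthogonal")) {
  contrast <- match.arg(contrast)
  if (is.data.frame(profiles)) profiles <- profiles$misclass
  stopifnot(all(vapply(profiles, inherits, TRUE, "ps_misclass")))
  other <- sub("spatial_vs_", "", contrast)
  usable <- vapply(profiles, function(p) p$n_errors > 0L, TRUE)
  if (any(!usable)) {
    rlang::warn(sprintf(
      "%d participant(s) with zero misclassifications excluded from '%s'.",
      sum(!usable), contrast))
  }
  diffs <- vapply(profiles[usable],
                  function(p) p$proportions[["spatial"]] - p$proportions[[other]],
                  numeric(1))
  res <- one_tailed_t(diffs, "participants with misclassifications")
  structure(c(res, list(contrast = contrast, mean_difference = res$mean)),
            class = "ps_group_test")
}

#' One-sample t-test of group accuracy against chance
#'
#' One-tailed (upper) one-sample t-test of per-participant accuracies
#' against the chance level, with `df = n - 1`.  This is the group
#' inference applied to each region and analysis.
#'
#' @param per_participant Numeric vector of per-participant accuracies
#'   (or proportions).
#' @param chance Chance level (1/4 for four-way decoding, 1/2 for
#'   transfer analyses).
#' @return A `ps_group_result`: per-participant values, `mean`, `sem`,
#'   `t`, `df`, one-tailed `p`, and empty permutation fields.
#' @export
#' @examples
#' t_vs_chance(c(0.35, 0.30, 0.25, 0.40, 0.30), 0.25)
t_vs_chance <- function(per_participant, chance) {
  if (!is.numeric(per_participant) || !all(is.finite(per_participant))) {
    ps_abort("invalid_parameter", "Accuracies must be finite numbers.")
  }
  check_positive(chance, "chance", strict = FALSE)
  res <- one_tailed_t(per_participant - chance, "participants")
  structure(list(per_participant = per_participant, chance = chance,
                 mean = mean(per_participant), sem = res$sem,
                 t = res$t, df = res$df, p = res$p,
                 perm_p = NA_real_, n_permutations = 0L,
                 null_means = numeric(0)),
            class = "ps_group_result")
}

#' @export
print.ps_group_result <- function(x, ...) {
  cat(sprintf("<ps_group_result> mean %.3f (chance %.2f), t(%d) = %.3f, one-tailed p = %.4f",
              x$mean, x$chance, x$df, x$t, x$p))
  if (!is.na(x$perm_p)) {
    cat(sprintf(", permutation p = %.4f (%d permutations)",
                x$perm_p, x$n_permutations))
  }
  cat("\n")
  invisible(x)
}

#' Upper-tail probability of Student's t
#'
#' The one-tailed significance convention used throughout the group
#' analyses: `P(T > t)` for `T ~ t(df)`.
#'
#' @param t Statistic (vectorized).
#' @param df Degrees of freedom, at least 1.
#' @return Upper-tail probabilities.
#' @export
#' @examples
#' t_tail_p(1.90, 14)
t_tail_p <- function(t, df) {
  if (!is.numeric(df) || any(df < 1)) {
    ps_abort("invalid_parameter", "`df` must be >= 1.")
  }
  stats::pt(t, df, lower.tail = FALSE)
}

analysis_fun <- function(analysis, cost, normalize) {
  switch(analysis,
    fourway = function(ps) decode_loto(ps, cost = cost,
                                       normalize = normalize)$accuracy,
    context_transfer = function(ps) decode_transfer(ps, "context", cost = cost,
                                                    normalize = normalize)$accuracy,
    content_transfer = function(ps) decode_transfer(ps, "event", cost = cost,
                                                    normalize = normalize)$accuracy,
    ps_abort("invalid_parameter",
             sprintf("Unknown analysis '%s'.", analysis)))
}

permute_labels <- function(ps, idx) {
  out <- ps
  out$labels <- ps$labels[idx]
  out
}

#' Group-level label-permutation test
#'
#' For each permutation iteration the condition-label vector is
#' randomly permuted over trials, independently within each
#' participant, the full analysis (leave-one-trial-out four-way
#' decoding or a transfer analysis) is rerun, and the group mean
#' accuracy is recorded.  The permutation p-value uses the add-one
#' rule, `(1 + #(null >= observed)) / (1 + n_perm)`, so it is never
#' exactly zero.  Since labels are permuted rather than resampled, the
#' per-condition trial counts are preserved in every null draw.
#'
#' @param pattern_tbl A tibble with a `pattern_set` list-column (one
#'   row per participant), as returned by [simulate_patterns()].
#' @param analysis `"fourway"`, `"context_transfer"` or
#'   `"content_transfer"`.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed; permutations are deterministic given it.
#' @param cost,normalize Decoding options, see [decode_loto()].
#' @return A `ps_group_result` with `perm_p`, `n_permutations` and the
#'   null distribution of group means in `null_means`, alongside the
#'   parametric one-tailed t-test fields.
#' @export
permutation_test <- function(pattern_tbl,
                             analysis = c("fourway", "context_transfer",
                                          "content_transfer"),
                             n_perm = 1000, seed, cost = 1,
                             normalize = c("none", "zscore")) {
  if (is.character(analysis) && length(analysis) == 1L &&
      !analysis %in% c("fourway", "context_transfer", "content_transfer")) {
    ps_abort("invalid_parameter",
             sprintf("Unknown analysis '%s'.", analysis))
  }
  analysis <- match.arg(analysis)
  normalize <- match.arg(normalize)
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  seed <- check_seed(seed)
  sets <- if (is.data.frame(pattern_tbl)) pattern_tbl$pattern_set else pattern_tbl
  stopifnot(all(vapply(sets, inherits, TRUE, "ps_pattern_set")))
  f <- analysis_fun(analysis, cost, normalize)
  observed <- vapply(sets, f, numeric(1))
  chance <- if (analysis == "fourway") 0.25 else 0.5

  null_acc <- matrix(NA_real_, n_perm, length(sets))
  for (s in seq_along(sets)) {
    ps <- sets[[s]]
    n <- length(ps$labels)
    perm_idx <- with_seed(derive_seed(seed, "perm", analysis, s),
                          replicate(n_perm, sample.int(n)))
    if (analysis == "fourway") {
      # batched compiled path: all permuted label vectors against the
      # same accurate-trial pattern matrix
      acc <- accurate_subset(ps)
      classes <- levels(acc$labels)
      keep <- which(ps$accurate)
      labmat <- apply(perm_idx, 2, function(ix) {
        permuted <- ps$labels[ix]
        as.integer(factor(permuted[keep], levels = classes))
      })
      null_acc[, s] <- cpp_loto_many(t(acc$x), labmat, length(classes),
                                     cost, normalize == "zscore",
                                     1e-4, 2000L)
    } else {
      for (q in seq_len(n_perm)) {
        null_acc[q, s] <- f(permute_labels(ps, perm_idx[, q]))
      }
    }
  }
  null_means <- rowMeans(null_acc)
  obs_mean <- mean(observed)
  perm_p <- (1 + sum(null_means >= obs_mean)) / (1 + n_perm)
  # the parametric companion test can be degenerate (e.g. every
  # participant at ceiling); the permutation p-value still stands
  tt <- tryCatch(one_tailed_t(observed - chance, "participants"),
                 patternsep_error_zero_variance = function(e)
                   list(t = NA_real_, df = length(observed) - 1L,
                        p = NA_real_, sem = 0))
  structure(list(per_participant = observed, chance = chance,
                 mean = obs_mean, sem = tt$sem,
                 t = tt$t, df = tt$df, p = tt$p,
                 perm_p = perm_p, n_permutations = n_perm,
                 null_means = null_means, analysis = analysis),
            class = "ps_group_result")
}
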