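# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decoding result into per-trial rows
#'
#' @param x A `ps_decoding`.
#' @param ... Unused.
#' @return A tibble with one row per held-out trial: `fold`, `true`,
#'   `predicted`, `correct`, `relation`.
#' @method tidy ps_decoding
#' @export
tidy.ps_decoding <- function(x, ...) {
  tibble::tibble(
    participant = x$participant, roi = x$roi,
    fold = x$fold_index,
    true = x$true, predicted = x$predicted,
    correct = x$predicted == x$true,
    relation = label_relation(x$true, x$predicted))
}

#' @rdname tidy.ps_decoding
#' @method glance ps_decoding
#' @export
glance.ps_decoding <- function(x, ...) {
  tibble::tibble(participant = x$participant, roi = x$roi,
                 n_trials = length(x$true), accuracy = x$accuracy,
                 chance = x$chance,
                 pct_above_chance = 100 * (x$accuracy - x$chance))
}

#' Tidy a transfer (cross-classification) result
#'
#' @param x A `ps_transfer`.
#' @param ... Unused.
#' @method tidy ps_transfer
#' @export
tidy.ps_transfer <- function(x, ...) {
  tibble::tibble(participant = x$participant, roi = x$roi,
                 shared_factor = x$shared_factor,
                 true = x$true, predicted = x$predicted,
                 correct = x$predicted == x$true)
}

#' @rdname tidy.ps_transfer
#' @method glance ps_transfer
#' @export
glance.ps_transfer <- function(x, ...) {
  tibble::tibble(participant = x$participant, roi = x$roi,
                 shared_factor = x$shared_factor,
                 n_test_trials = length(x$true), accuracy = x$accuracy,
                 chance = x$chance)
}

#' Tidy a misclassification profile
#'
#' @param x A `ps_misclass`.
#' @param ... Unused.
#' @return One row per error type with its count and proportion.
#' @method tidy ps_misclass
#' @export
tidy.ps_misclass <- function(x, ...) {
  tibble::tibble(type = names(x$counts),
                 count = as.integer(x$counts),
                 proportion = as.numeric(x$proportions))
}

#' Tidy group-level inference results
#'
#' @param x A `ps_group_result` (from [t_vs_chance()] or
#'   [permutation_test()]).
#' @param ... Unused.
#' @return `tidy` gives one row per participant; `glance` one row of
#'   group statistics.
#' @method tidy ps_group_result
#' @export
tidy.ps_group_result <- function(x, ...) {
  tibble::tibble(participant = seq_along(x$per_participant),
                 accuracy = x$per_participant,
                 chance = x$chance)
}

#' @rdname tidy.ps_group_result
#' @method glance ps_group_result
#' @export
glance.ps_group_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean, chance = x$chance,
                 pct_above_chance = 100 * (x$mean - x$chance),
                 sem = x$sem, t = x$t, df = x$df, p = x$p,
                 perm_p = x$perm_p, n_perm = x$n_permutations)
}

#' @method glance ps_group_test
#' @export
glance.ps_group_test <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, mean_difference = x$mean_difference,
                 t = x$t, df = x$df, p = x$p, n = x$n)
}
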