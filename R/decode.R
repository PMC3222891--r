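# Four-way leave-one-trial-out decoding and the cross-classification
# (transfer) analyses.

accurate_subset <- function(ps) {
  keep <- which(ps$accurate)
  list(x = ps$patterns[keep, , drop = FALSE],
       labels = droplevels(ps$labels[keep]))
}

#' Four-way decoding with leave-one-trial-out cross-validation
#'
#' For each accurately recalled trial in turn, a one-vs-one linear SVM
#' is trained on all remaining accurate trials and predicts the
#' held-out trial; no information from the held-out trial enters
#' training or normalization.  Accuracy and the 4x4 confusion matrix
#' are assembled over the folds; chance is 1/4.
#'
#' @param x A `ps_pattern_set`, or a tibble with a `pattern_set`
#'   list-column as returned by [simulate_patterns()].
#' @param cost SVM cost parameter (default 1).
#' @param normalize `"none"` (default) or `"zscore"` (per-voxel
#'   z-scoring from each binary training set, applied to the held-out
#'   trial).
#' @param tol,max_epochs Solver controls, see [linear_svm()].
#' @param ... Passed between methods.
#' @return For a pattern set, a `ps_decoding` object; for a tibble, the
#'   input with added columns `n_trials`, `accuracy`, `chance` and a
#'   `decoding` list-column.
#' @export
#' @examples
#' d <- make_design(1, 4, seed = 1)
#' sim <- simulate_patterns(d, signal_spec(n_voxels = 30, amp_bound = 3,
#'                                         noise_sd = 0.1, p_inaccurate = 0),
#'                          seed = 1)
#' decode_loto(sim$pattern_set[[1]])$accuracy
decode_loto <- function(x, ...) UseMethod("decode_loto")

#' @rdname decode_loto
#' @export
decode_loto.ps_pattern_set <- function(x, cost = 1,
                                       normalize = c("none", "zscore"),
                                       tol = 1e-4, max_epochs = 2000, ...) {
  normalize <- match.arg(normalize)
  check_positive(cost, "cost")
  acc <- accurate_subset(x)
  tab <- table(acc$labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    ps_abort("insufficient_trials", paste(
      "Leave-one-trial-out decoding needs at least 2 accurate trials in",
      "each of at least 2 conditions."))
  }
  classes <- names(tab)
  lab_int <- as.integer(factor(acc$labels, levels = classes))
  pred_int <- cpp_loto(t(acc$x), lab_int, length(classes), cost,
                       normalize == "zscore", tol, as.integer(max_epochs))
  predicted <- factor(classes[pred_int], levels = classes)
  true <- factor(as.character(acc$labels), levels = classes)
  confusion <- table(true = true, predicted = predicted)
  confusion <- matrix(confusion, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  res <- structure(list(participant = x$participant, roi = x$roi,
                        true = true, predicted = predicted,
                        fold_index = seq_along(true),
                        accuracy = mean(predicted == true),
                        confusion = confusion,
                        chance = 1 / length(classes),
                        cost = cost, normalize = normalize),
                   class = "ps_decoding")
  stopifnot(sum(confusion) == length(true),
            all(rowSums(confusion) == as.integer(tab)))
  res
}

#' @rdname decode_loto
#' @export
decode_loto.data.frame <- function(x, cost = 1,
                                   normalize = c("none", "zscore"),
                                   tol = 1e-4, max_epochs = 2000, ...) {
  normalize <- match.arg(normalize)
  res <- purrr::map(x$pattern_set, decode_loto, cost = cost,
                    normalize = normalize, tol = tol,
                    max_epochs = max_epochs)
  dplyr::mutate(x,
                n_trials = purrr::map_int(res, ~ length(.x$true)),
                accuracy = purrr::map_dbl(res, "accuracy"),
                chance = purrr::map_dbl(res, "chance"),
                decoding = res)
}

#' @export
print.ps_decoding <- function(x, ...) {
  cat(sprintf("<ps_decoding> participant %s, roi %s: accuracy %.3f (chance %.2f) over %d trials\n",
              format(x$participant), format(x$roi), x$accuracy, x$chance,
              length(x$true)))
  print(x$confusion)
  invisible(x)
}

transfer_spec <- function(shared_factor) {
  # within each pair the shared factor differs between the two classes
  # and the other factor is constant; train classes map to the test
  # classes with the same shared-factor value
  switch(shared_factor,
    context = list(train = c("A", "B"), test = c("C", "D"),
                   map = c(A = "C", B = "D")),
    event = list(train = c("A", "C"), test = c("B", "D"),
                 map = c(A = "B", C = "D")))
}

validate_transfer_pair <- function(pair, shared_factor, what) {
  ev <- EVENT_OF[pair]
  cx <- CONTEXT_OF[pair]
  ok <- if (shared_factor == "context") {
    cx[1] != cx[2] && ev[1] == ev[2]
  } else {
    ev[1] != ev[2] && cx[1] == cx[2]
  }
  if (!ok) {
    ps_abort("invalid_pair", sprintf(
      "%s pair (%s, %s) is invalid for shared factor '%s': the pair must differ in the shared factor only.",
      what, pair[1], pair[2], shared_factor))
  }
}

#' Cross-classification of a shared factor (transfer test)
#'
#' Trains a binary linear SVM on one pair of memories and tests it on
#' the disjoint pair, scoring a test trial as correct when the
#' predicted training class shares the test trial's value of the shared
#' factor.  For `shared_factor = "context"` the classifier is trained
#' on A vs B (same event, different context) and tested on C vs D with
#' the mapping A<->C, B<->D; for `"event"` it is trained on A vs C and
#' tested on B vs D with A<->B, C<->D.  Above-chance transfer is
#' evidence for a representation of the shared factor that generalizes
#' across memories; chance is 1/2.
#'
#' @inheritParams decode_loto
#' @param shared_factor `"context"` or `"event"`.
#' @param train_pair,test_pair Optional custom memory pairs; each must
#'   differ in the shared factor only, and the two pairs must be
#'   disjoint.
#' @return For a pattern set, a `ps_transfer` object; for a tibble, the
#'   input with `accuracy`, `chance` and a `transfer` list-column.
#' @export
decode_transfer <- function(x, ...) UseMethod("decode_transfer")

#' @rdname decode_transfer
#' @export
decode_transfer.ps_pattern_set <- function(x,
                                           shared_factor = c("context", "event"),
                                           cost = 1,
                                           normalize = c("none", "zscore"),
                                           train_pair = NULL, test_pair = NULL,
                                           tol = 1e-4, max_epochs = 2000, ...) {
  shared_factor <- match.arg(shared_factor)
  normalize <- match.arg(normalize)
  check_positive(cost, "cost")
  spec <- transfer_spec(shared_factor)
  if (!is.null(train_pair) || !is.null(test_pair)) {
    train_pair <- as.character(train_pair %||% spec$train)
    test_pair <- as.character(test_pair %||% spec$test)
    validate_transfer_pair(train_pair, shared_factor, "Train")
    validate_transfer_pair(test_pair, shared_factor, "Test")
    if (length(intersect(train_pair, test_pair)) > 0L) {
      ps_abort("invalid_pair", "Train and test pairs must be disjoint.")
    }
    key <- if (shared_factor == "context") CONTEXT_OF else EVENT_OF
    map <- stats::setNames(test_pair[match(key[train_pair], key[test_pair])],
                           train_pair)
    spec <- list(train = train_pair, test = test_pair, map = map)
  }
  acc <- accurate_subset(x)
  present <- table(factor(acc$labels, levels = MEMORY_LEVELS))
  need <- unique(c(spec$train, spec$test))
  if (any(present[need] < 1L)) {
    ps_abort("insufficient_trials", sprintf(
      "Transfer decoding needs at least 1 accurate trial of each of %s.",
      paste(need, collapse = ", ")))
  }
  tr_sel <- acc$labels %in% spec$train
  te_sel <- acc$labels %in% spec$test
  y01 <- ifelse(acc$labels[tr_sel] == spec$train[1], 1, -1)
  fit <- fit_binary_svm(acc$x[tr_sel, , drop = FALSE], y01, cost, normalize,
                        tol, max_epochs)
  dec <- binary_decision(fit, acc$x[te_sel, , drop = FALSE])
  pred_train <- ifelse(dec >= 0, spec$train[1], spec$train[2])
  pred_test <- unname(spec$map[pred_train])
  truth <- as.character(acc$labels[te_sel])
  structure(list(participant = x$participant, roi = x$roi,
                 shared_factor = shared_factor,
                 train_pair = spec$train, test_pair = spec$test,
                 predicted = pred_test, true = truth,
                 accuracy = mean(pred_test == truth), chance = 0.5,
                 cost = cost, normalize = normalize),
            class = "ps_transfer")
}

#' @rdname decode_transfer
#' @export
decode_transfer.data.frame <- function(x,
                                       shared_factor = c("context", "event"),
                                       ...) {
  shared_factor <- match.arg(shared_factor)
  res <- purrr::map(x$pattern_set, decode_transfer,
                    shared_factor = shared_factor, ...)
  dplyr::mutate(x,
                shared_factor = shared_factor,
                accuracy = purrr::map_dbl(res, "accuracy"),
                chance = 0.5,
                transfer = res)
}

#' @export
print.ps_transfer <- function(x, ...) {
  cat(sprintf("<ps_transfer> %s transfer (train %s vs %s, test %s vs %s): accuracy %.3f\n",
              x$shared_factor, x$train_pair[1], x$train_pair[2],
              x$test_pair[1], x$test_pair[2], x$accuracy))
  invisible(x)
}
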