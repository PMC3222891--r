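# Condition structure and experimental designs for the 2x2
# event-by-context memory paradigm.

MEMORY_LEVELS <- c("A", "B", "C", "D")
EVENT_OF <- c(A = 1L, B = 1L, C = 2L, D = 2L)
CONTEXT_OF <- c(A = 1L, B = 2L, C = 1L, D = 2L)

#' The four-condition event-by-context structure
#'
#' Four memories arise from crossing two action events with two spatial
#' contexts: A = (event 1, context 1), B = (event 1, context 2),
#' C = (event 2, context 1), D = (event 2, context 2).  Every memory
#' shares its spatial context with exactly one other memory (A-C, B-D),
#' its event content with exactly one (A-B, C-D), and neither with the
#' remaining one (A-D, B-C).
#'
#' @return A tibble with columns `memory_id`, `event_id`, `context_id`.
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  tibble::tibble(
    memory_id = factor(MEMORY_LEVELS, levels = MEMORY_LEVELS),
    event_id = unname(EVENT_OF),
    context_id = unname(CONTEXT_OF)
  )
}

as_memory_factor <- function(x) {
  x <- as.character(x)
  bad <- !x %in% MEMORY_LEVELS
  if (any(bad)) {
    ps_abort("invalid_parameter",
             sprintf("Unknown memory label(s): %s.",
                     paste(unique(x[bad]), collapse = ", ")))
  }
  factor(x, levels = MEMORY_LEVELS)
}

#' Relation between a true and a predicted memory label
#'
#' Classifies each (true, predicted) pair as `correct` (identical),
#' `spatial` (same spatial context, different event), `content` (same
#' event content, different context) or `orthogonal` (neither factor
#' shared).  This is the decomposition used to ask whether four-way
#' decoding errors are biased toward memories sharing a spatial context.
#'
#' @param true,predicted Vectors of memory labels (`"A"`–`"D"`),
#'   recycled to a common length.
#' @return A factor with levels `correct`, `spatial`, `content`,
#'   `orthogonal`.
#' @export
#' @examples
#' label_relation("A", c("A", "B", "C", "D"))
label_relation <- function(true, predicted) {
  true <- as_memory_factor(true)
  predicted <- as_memory_factor(predicted)
  n <- max(length(true), length(predicted))
  true <- rep_len(true, n)
  predicted <- rep_len(predicted, n)
  same_ev <- EVENT_OF[as.character(true)] == EVENT_OF[as.character(predicted)]
  same_cx <- CONTEXT_OF[as.character(true)] == CONTEXT_OF[as.character(predicted)]
  out <- ifelse(true == predicted, "correct",
         ifelse(same_cx & !same_ev, "spatial",
         ifelse(same_ev & !same_cx, "content", "orthogonal")))
  factor(out, levels = c("correct", "spatial", "content", "orthogonal"))
}

# One balanced order with no immediate repeats.  Symbols are drawn
# sequentially with probability proportional to their remaining counts,
# excluding the previous symbol; a dead end (only the previous symbol
# left) restarts the draw.  Whole-sequence rejection sampling is
# hopeless here (acceptance decays like exp(-n/4)), while this sampler
# restarts rarely and keeps the marginal probability of every condition
# at every serial position exactly 1/4 by symmetry.
sample_order <- function(n_per, max_attempts = 10000L) {
  n_total <- 4L * n_per
  for (attempt in seq_len(max_attempts)) {
    counts <- stats::setNames(rep(n_per, 4L), MEMORY_LEVELS)
    ord <- character(n_total)
    prev <- ""
    ok <- TRUE
    for (i in seq_len(n_total)) {
      avail <- counts
      if (prev != "") avail[prev] <- 0L
      if (sum(avail) == 0L) { ok <- FALSE; break }
      pick <- sample(MEMORY_LEVELS, 1L, prob = avail)
      ord[i] <- pick
      counts[pick] <- counts[pick] - 1L
      prev <- pick
    }
    if (ok) return(ord)
  }
  ps_abort("invalid_parameter",
           sprintf("No repeat-free order found in %d attempts.", max_attempts))
}

#' Generate a balanced pseudo-random experimental design
#'
#' Builds per-participant trial sequences in which each of the four
#' memories occurs exactly `n_trials_per_condition` times and the same
#' memory never occurs on consecutive trials.  Orders are drawn
#' sequentially with probability proportional to the remaining count of
#' each memory, excluding the one just presented (restarting on the
#' rare dead end), which keeps the marginal probability of every memory
#' at every serial position exactly 1/4; orders are independent across
#' participants.
#'
#' @param n_participants Number of participants (default 15).
#' @param n_trials_per_condition Trials per memory condition (default 20).
#' @param recall_duration Duration of the modeled recall period, seconds.
#' @param iti Gap between the end of one recall period and the next
#'   onset, seconds.
#' @param tr Repetition time of the (simulated) acquisition, seconds.
#' @param seed Integer seed; the design is a pure function of its
#'   arguments.
#' @return A `ps_design` tibble with one row per trial: `participant`,
#'   `trial`, `memory_id`, `event_id`, `context_id`, `onset`,
#'   `duration`.  Timing parameters are carried as attributes.
#' @export
#' @examples
#' d <- make_design(n_participants = 2, n_trials_per_condition = 5, seed = 1)
#' dplyr::count(d, participant, memory_id)
make_design <- function(n_participants = 15, n_trials_per_condition = 20,
                        recall_duration = 12, iti = 4, tr = 2, seed = NULL) {
  n_participants <- check_count(n_participants, "n_participants")
  n_trials_per_condition <- check_count(n_trials_per_condition,
                                        "n_trials_per_condition")
  check_positive(recall_duration, "recall_duration")
  check_positive(iti, "iti")
  check_positive(tr, "tr")
  seed <- check_seed(seed)

  n_trials <- 4L * n_trials_per_condition
  onsets <- iti + (seq_len(n_trials) - 1) * (recall_duration + iti)
  rows <- lapply(seq_len(n_participants), function(p) {
    ord <- with_seed(derive_seed(seed, "design", p), sample_order(n_trials_per_condition))
    tibble::tibble(
      participant = p,
      trial = seq_len(n_trials),
      memory_id = as_memory_factor(ord),
      onset = onsets,
      duration = recall_duration
    )
  })
  out <- dplyr::bind_rows(rows)
  out$event_id <- unname(EVENT_OF[as.character(out$memory_id)])
  out$context_id <- unname(CONTEXT_OF[as.character(out$memory_id)])
  out <- out[, c("participant", "trial", "memory_id", "event_id",
                 "context_id", "onset", "duration")]
  structure(out,
            class = c("ps_design", class(out)),
            tr = tr, iti = iti,
            recall_duration = recall_duration,
            n_participants = n_participants,
            n_trials_per_condition = n_trials_per_condition,
            seed = seed)
}

design_tr <- function(design) attr(design, "tr") %||% 2

#' Write or read a BIDS-style events table
#'
#' Events are exchanged as a tab-separated table with columns `onset`,
#' `duration`, `memory_id`, `event_id`, `context_id` and, when known,
#' `accurate` (plus `participant`/`trial` when several participants are
#' stored in one file).
#'
#' @param design A `ps_design` tibble (or any tibble with those columns).
#' @param path File path for the TSV.
#' @return `write_events` returns `path` invisibly; `read_events`
#'   returns a tibble.
#' @export
write_events <- function(design, path) {
  readr::write_tsv(as.data.frame(design), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    ps_abort("io", sprintf("Events file not found: %s", path))
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("memory_id" %in% names(out)) out$memory_id <- as_memory_factor(out$memory_id)
  out
}
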