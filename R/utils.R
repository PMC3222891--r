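# Internal helpers: error taxonomy, RNG scoping, seed derivation.

ps_abort <- function(class, msg, ...) {
  rlang::abort(message = msg, class = paste0("patternsep_error_", class), ...)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    ps_abort("invalid_parameter",
             sprintf("`%s` must be a single %s number, got %s.",
                     name, if (strict) "positive" else "non-negative",
                     paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == as.integer(x)
  if (!ok) {
    ps_abort("invalid_parameter",
             sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (is.null(seed)) {
    ps_abort("invalid_parameter", "`seed` must be supplied (a single integer).")
  }
  check_count(seed, "seed", min = 0L)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible sub-stream seed
#'
#' Stages of the pipeline draw from independent RNG streams whose seeds
#' are derived deterministically from the master seed and a set of
#' string/integer tags (stage name, region, participant).  Adding
#' participants or regions therefore never shifts the stream of an
#' existing one.
#'
#' @param seed Master integer seed.
#' @param ... Character or integer tags identifying the sub-stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate", "HC", 3)
derive_seed <- function(seed, ...) {
  seed <- check_seed(seed)
  tags <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    for (b in utf8ToInt(tag)) {
      h <- (h * 31 + b) %% 2147483647
    }
  }
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
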