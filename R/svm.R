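# Linear support vector machine with one-vs-one multiclass aggregation.
# The quadratic program is solved in compiled code by dual coordinate
# descent on the L1-loss (hinge) dual with an augmented-constant
# intercept.

zscore_stats <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

fit_binary_svm <- function(x, y01, cost, normalize, tol, max_epochs) {
  # y01: +1 / -1
  if (normalize == "zscore") {
    st <- zscore_stats(x)
    xs <- sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
  } else {
    st <- list(mu = NULL, sd = NULL)
    xs <- x
  }
  fit <- cpp_dcd_fit(t(xs), as.numeric(y01), cost, tol, max_epochs, numeric(0))
  c(fit, st)
}

binary_decision <- function(fit, newx) {
  if (!is.null(fit$mu)) {
    newx <- sweep(sweep(newx, 2, fit$mu), 2, fit$sd, "/")
  }
  drop(newx %*% fit$w) + fit$b
}

#' Train a linear SVM (one-vs-one for more than two classes)
#'
#' Fits one binary max-margin linear classifier per unordered class
#' pair.  Multiclass predictions are made by majority vote over the
#' pairs; ties are broken by the summed signed decision values and then
#' by the lexicographically smallest class label.
#'
#' @param x Numeric trials x features matrix.
#' @param y Class labels, one per row of `x` (at least two classes).
#' @param cost Soft-margin cost parameter C (default 1).
#' @param normalize `"none"` (default) or `"zscore"` — per-feature
#'   z-scoring computed from the training data of each binary problem
#'   and applied to new data at prediction time.
#' @param tol Convergence tolerance on the projected dual gradient.
#' @param max_epochs Cap on coordinate-descent epochs.
#' @return A `ps_svm` model.
#' @export
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' m <- linear_svm(x, c("A", "B"))
#' predict(m, matrix(0.5))  # boundary at the midpoint, so "B"
linear_svm <- function(x, y, cost = 1, normalize = c("none", "zscore"),
                       tol = 1e-6, max_epochs = 20000) {
  x <- as.matrix(x)
  normalize <- match.arg(normalize)
  check_positive(cost, "cost")
  y <- factor(y)
  classes <- levels(droplevels(y))
  if (length(classes) < 2L) {
    ps_abort("degenerate_labels",
             "Training data must contain at least two classes.")
  }
  if (length(y) != nrow(x)) {
    ps_abort("shape", "`y` must have one label per row of `x`.")
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    y01 <- ifelse(y[sel] == pr[1], 1, -1)
    fit_binary_svm(x[sel, , drop = FALSE], y01, cost, normalize, tol,
                   max_epochs)
  })
  structure(list(classes = classes, pairs = pairs, fits = fits,
                 cost = cost, normalize = normalize),
            class = "ps_svm")
}

#' Predict from a linear SVM
#'
#' @param object A `ps_svm` model.
#' @param newdata Matrix of observations (rows) to classify.
#' @param type `"class"` for labels, `"votes"` for the per-class vote
#'   matrix, `"decision"` for per-pair signed decision values.
#' @param ... Unused.
#' @export
predict.ps_svm <- function(object, newdata,
                           type = c("class", "votes", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  K <- length(object$classes)
  dec <- vapply(object$fits, binary_decision, numeric(nrow(newdata)),
                newx = newdata)
  dec <- matrix(dec, nrow = nrow(newdata))
  colnames(dec) <- vapply(object$pairs, paste, "", collapse = "/")
  if (type == "decision") return(dec)
  votes <- matrix(0L, nrow(newdata), K, dimnames = list(NULL, object$classes))
  score <- matrix(0, nrow(newdata), K, dimnames = list(NULL, object$classes))
  for (j in seq_along(object$pairs)) {
    pr <- object$pairs[[j]]
    win <- ifelse(dec[, j] >= 0, pr[1], pr[2])
    for (i in seq_len(nrow(newdata))) {
      votes[i, win[i]] <- votes[i, win[i]] + 1L
    }
    score[, pr[1]] <- score[, pr[1]] + dec[, j]
    score[, pr[2]] <- score[, pr[2]] - dec[, j]
  }
  if (type == "votes") return(votes)
  pick <- vapply(seq_len(nrow(newdata)), function(i) {
    v <- votes[i, ]
    cand <- which(v == max(v))
    if (length(cand) > 1L) {
      s <- score[i, cand]
      cand <- cand[s == max(s)]
    }
    cand[1L]  # lexicographic fallback: classes are stored sorted
  }, integer(1))
  factor(object$classes[pick], levels = object$classes)
}
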