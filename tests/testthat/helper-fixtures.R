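# Shared fixtures: tiny separable cluster sets and an independent
# brute-force one-vs-one vote aggregator used as the multiclass oracle.

# widely separated Gaussian clusters, one per condition
make_cluster_set <- function(n_per = 4, n_voxels = 12, sep = 50,
                             noise = 0.1, seed = 1, participant = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(4 * n_voxels), 4) * sep
    labels <- rep(c("A", "B", "C", "D"), each = n_per)
    x <- centers[rep(1:4, each = n_per), ] +
      matrix(rnorm(4 * n_per * n_voxels, sd = noise), 4 * n_per)
    pattern_set(x, labels, participant = participant, roi = "HC")
  })
}

# Brute-force one-vs-one aggregation: trains every pairwise classifier
# independently, enumerates the pairwise outcomes for a test point, and
# applies the vote / summed-decision / lexicographic rule directly.
brute_force_ovo <- function(x, y, newx, cost = 1, tol = 1e-6) {
  y <- factor(y)
  classes <- levels(droplevels(y))
  votes <- stats::setNames(rep(0L, length(classes)), classes)
  score <- stats::setNames(rep(0, length(classes)), classes)
  for (a in seq_along(classes)) {
    for (b in seq_along(classes)) {
      if (a >= b) next
      pr <- classes[c(a, b)]
      sel <- y %in% pr
      m <- linear_svm(x[sel, , drop = FALSE], as.character(y[sel]),
                      cost = cost, tol = tol)
      dec <- predict(m, newx, type = "decision")[1, 1]
      win <- if (dec >= 0) pr[1] else pr[2]
      votes[win] <- votes[win] + 1L
      score[pr[1]] <- score[pr[1]] + dec
      score[pr[2]] <- score[pr[2]] - dec
    }
  }
  cand <- names(votes)[votes == max(votes)]
  if (length(cand) > 1L) {
    cand <- cand[score[cand] == max(score[cand])]
  }
  sort(cand)[1]
}
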