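test_that("the canonical HRF is peak-normalized with a plausible peak time", {
  h <- canonical_hrf(0.1)
  expect_equal(max(h), 1)
  peak_s <- (which.max(h) - 1) * 0.1
  expect_gte(peak_s, 5)
  expect_lte(peak_s, 6)
  # halving tr doubles the sample count (within one sample)
  n2 <- length(canonical_hrf(2))
  n1 <- length(canonical_hrf(1))
  expect_lte(abs(n1 - 2 * n2), 2)
  expect_error(canonical_hrf(0), class = "patternsep_error_invalid_parameter")
  expect_error(hrf_params(kernel_length = 10),
               class = "patternsep_error_invalid_parameter")
})

test_that("design matrices have one trial column plus drift and constant", {
  d <- make_design(1, 20, seed = 21)
  X <- build_design_matrix(d, drift_order = 1)
  expect_equal(ncol(X$values), 80 + 1 + 1)
  expect_true("constant" %in% X$names)
  expect_equal(length(X$trial_cols), 80)
  # identity kernel reproduces the sampled boxcar
  Xi <- build_design_matrix(d, hrf = 1, drift_order = 0)
  times <- (seq_len(nrow(Xi$values)) - 1) * 2
  box1 <- as.numeric(times >= d$onset[1] & times < d$onset[1] + d$duration[1])
  expect_equal(unname(Xi$values[, 1]), box1)
})

test_that("convolution matches the brute-force shifted sum", {
  box <- c(0, 1, 1, 0, 0, 0, 0)
  kern <- c(0.5, 1, 0.25)
  # direct summation oracle
  expected <- numeric(length(box))
  for (i in seq_along(box)) {
    for (k in seq_along(kern)) {
      j <- i + k - 1
      if (j <= length(box)) expected[j] <- expected[j] + box[i] * kern[k]
    }
  }
  expect_equal(patternsep:::convolve_truncate(box, kern), expected)
})

test_that("fit_glm solves the normal equations", {
  # hand-sized system: 4 timepoints, 2 regressors
  xm <- cbind(trial_001 = c(1, 2, 0, 1), constant = 1)
  X <- structure(list(values = xm, names = colnames(xm), trial_cols = 1L,
                      tr = 1), class = "ps_design_matrix")
  y <- c(2.0, 3.5, 0.5, 1.5)
  fit <- fit_glm(matrix(y, 1), X)
  beta_oracle <- solve(crossprod(xm), crossprod(xm, y))
  expect_equal(unname(fit$beta[1, 1]), unname(beta_oracle[1, 1]), tolerance = 1e-12)
  # and matches a generic least-squares solver on random systems
  withr::with_seed(22, {
    for (i in 1:5) {
      xr <- matrix(rnorm(60), 20, 3)
      colnames(xr) <- c("trial_001", "trial_002", "constant")
      Xr <- structure(list(values = xr, names = colnames(xr),
                           trial_cols = 1:2, tr = 1),
                      class = "ps_design_matrix")
      yr <- matrix(rnorm(40), 2, 20)  # 2 voxels
      fr <- fit_glm(yr, Xr)
      br <- qr.solve(xr, t(yr))
      expect_equal(unname(fr$beta), unname(br[1:2, ]), tolerance = 1e-10)
    }
  })
})

test_that("noiseless data are interpolated exactly", {
  withr::with_seed(23, {
    xm <- matrix(rnorm(50), 25, 2)
    colnames(xm) <- c("trial_001", "constant")
    X <- structure(list(values = xm, names = colnames(xm), trial_cols = 1L,
                        tr = 1), class = "ps_design_matrix")
    b <- c(1.5, -0.5)
    y <- matrix(drop(xm %*% b), 1)
    fit <- fit_glm(y, X)
    expect_lt(abs(fit$beta[1, 1] - b[1]) / abs(b[1]), 1e-10)
    expect_lt(fit$sigma2[1], 1e-20)
    expect_true(fit$degenerate[1])
  })
})

test_that("rank-deficient designs raise a singular-design error naming columns", {
  xm <- cbind(trial_001 = c(1, 2, 3, 4), trial_002 = c(1, 2, 3, 4),
              constant = 1)
  X <- structure(list(values = xm, names = colnames(xm), trial_cols = 1:2,
                      tr = 1), class = "ps_design_matrix")
  err <- expect_error(fit_glm(matrix(rnorm(4), 1), X),
                      class = "patternsep_error_singular_design")
  expect_match(conditionMessage(err), "trial_00")
  expect_error(fit_glm(matrix(rnorm(10), 1), structure(
    list(values = matrix(rnorm(8), 4, 2), names = c("a", "b"),
         trial_cols = 1L, tr = 1), class = "ps_design_matrix")),
    class = "patternsep_error_shape")
})

test_that("t and beta patterns are rank-correlated under homoscedastic noise", {
  d <- make_design(1, 10, seed = 24)
  spec <- signal_spec(n_voxels = 8, p_inaccurate = 0)
  ts <- simulate_timeseries(d, spec, noise = list(model = "white", sd = 1),
                            seed = 25)
  X <- build_design_matrix(ts$timeseries[[1]]$design, drift_order = 1)
  fit <- fit_glm(ts$timeseries[[1]], X)
  rc <- sapply(seq_len(ncol(fit$beta)), function(v)
    stats::cor(fit$beta[, v], fit$t[, v], method = "spearman"))
  expect_true(all(rc > 0.9))
})

test_that("beta error against true amplitudes shrinks with the noise level", {
  d <- make_design(1, 20, seed = 26)
  spec <- signal_spec(n_voxels = 6, p_inaccurate = 0)
  mae <- sapply(c(1, 0.5, 0.1), function(sd) {
    mean(sapply(1:10, function(s) {
      ts <- simulate_timeseries(d, spec, noise = list(model = "white", sd = sd),
                                seed = s)
      X <- build_design_matrix(ts$timeseries[[1]]$design, drift_order = 1)
      fit <- fit_glm(ts$timeseries[[1]], X)
      mean(abs(fit$beta - ts$amplitudes[[1]]))
    }))
  })
  expect_true(all(diff(mae) < 0))
})

test_that("trial_tmaps filters to accurate trials and guards degeneracy", {
  d <- make_design(1, 20, seed = 27)
  spec <- signal_spec(n_voxels = 5, p_inaccurate = 0)
  ts <- simulate_timeseries(d, spec, noise = list(model = "white", sd = 0.5),
                            seed = 28)
  dp <- ts$timeseries[[1]]$design
  X <- build_design_matrix(dp, drift_order = 1)
  fit <- fit_glm(ts$timeseries[[1]], X)

  all_acc <- trial_tmaps(fit, dp$memory_id)
  expect_equal(nrow(all_acc$patterns), 80)

  flags <- rep(TRUE, 80)
  flags[c(3, 40, 77)] <- FALSE
  some <- trial_tmaps(fit, dp$memory_id, flags)
  expect_equal(nrow(some$patterns), 77)
  expect_equal(as.character(some$labels),
               as.character(dp$memory_id[flags]))

  few <- rep(FALSE, 80)
  few[which(dp$memory_id == "A")[1]] <- TRUE
  few[dp$memory_id != "A"] <- TRUE
  expect_error(trial_tmaps(fit, dp$memory_id, few),
               class = "patternsep_error_insufficient_trials")

  ts0 <- simulate_timeseries(d, spec, noise = list(model = "white", sd = 0),
                             seed = 28)
  fit0 <- fit_glm(ts0$timeseries[[1]], X)
  expect_error(trial_tmaps(fit0, dp$memory_id),
               class = "patternsep_error_degenerate_input")
})
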