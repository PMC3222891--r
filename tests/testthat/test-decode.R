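test_that("leave-one-trial-out predicts every accurate trial exactly once", {
  d <- make_design(1, 20, seed = 50)
  spec <- signal_spec(n_voxels = 50, p_inaccurate = 0)
  ps <- simulate_patterns(d, spec, seed = 51)$pattern_set[[1]]
  r <- decode_loto(ps)
  expect_equal(length(r$predicted), 80)
  expect_equal(r$fold_index, 1:80)
  expect_equal(sum(r$confusion), 80)
  expect_equal(unname(rowSums(r$confusion)), rep(20L, 4), ignore_attr = TRUE)
  expect_equal(r$accuracy, sum(diag(r$confusion)) / 80)
  expect_equal(r$chance, 0.25)
})

test_that("well-separated clusters decode perfectly; guards fire otherwise", {
  ps <- make_cluster_set(seed = 52)
  expect_equal(decode_loto(ps)$accuracy, 1)
  small <- pattern_set(matrix(rnorm(8), 4, 2), c("A", "A", "B", "C"))
  expect_error(decode_loto(small),
               class = "patternsep_error_insufficient_trials")
  one_a <- ps$labels != "A"
  one_a[which(ps$labels == "A")[1]] <- TRUE  # a single accurate A trial
  flagged <- pattern_set(ps$patterns, ps$labels, one_a)
  expect_error(decode_loto(flagged),
               class = "patternsep_error_insufficient_trials")
  # dropping a whole condition is allowed: decoding proceeds on the rest
  no_a <- decode_loto(pattern_set(ps$patterns, ps$labels, ps$labels != "A"))
  expect_equal(no_a$chance, 1 / 3)
})

test_that("null patterns decode at chance on average", {
  d <- make_design(1, 20, seed = 53)
  spec <- signal_spec(n_voxels = 100, amp_bound = 0, amp_context = 0,
                      amp_event = 0, noise_sd = 1, p_inaccurate = 0)
  accs <- sapply(1:50, function(s)
    decode_loto(simulate_patterns(d, spec, seed = s)$pattern_set[[1]])$accuracy)
  expect_lt(abs(mean(accs) - 0.25), 0.02)
})

test_that("consistent relabeling permutes the confusion matrix, not accuracy", {
  ps <- make_cluster_set(n_per = 3, n_voxels = 20, sep = 1.5, noise = 1,
                         seed = 54)
  r <- decode_loto(ps)
  # swap A<->C and B<->D (a relabeling consistent across trials)
  swap <- c(A = "C", B = "D", C = "A", D = "B")
  ps2 <- pattern_set(ps$patterns, unname(swap[as.character(ps$labels)]),
                     ps$accurate)
  r2 <- decode_loto(ps2)
  expect_equal(r2$accuracy, r$accuracy)
  expect_equal(r2$confusion[swap, swap], r$confusion, ignore_attr = TRUE)
})

test_that("each fold equals training a fresh classifier without that trial", {
  # no-leakage: the held-out prediction is a pure function of the other
  # trials and the held-out features
  ps <- make_cluster_set(n_per = 3, n_voxels = 8, sep = 0.8, noise = 1,
                         seed = 55)
  for (normalize in c("none", "zscore")) {
    r <- decode_loto(ps, normalize = normalize, tol = 1e-7,
                     max_epochs = 50000)
    refit <- vapply(seq_along(ps$labels), function(f) {
      m <- linear_svm(ps$patterns[-f, ], as.character(ps$labels[-f]),
                      normalize = normalize, tol = 1e-7,
                      max_epochs = 50000)
      as.character(predict(m, ps$patterns[f, , drop = FALSE]))
    }, character(1))
    expect_equal(as.character(r$predicted), refit)
  }
})

test_that("decode_loto maps over a pattern tibble", {
  d <- make_design(3, 3, seed = 56)
  tbl <- simulate_patterns(d, signal_spec(n_voxels = 20, p_inaccurate = 0),
                           seed = 57)
  out <- decode_loto(tbl)
  expect_equal(nrow(out), 3)
  expect_true(all(c("accuracy", "chance", "decoding") %in% names(out)))
  expect_equal(out$n_trials, rep(12L, 3))
})

test_that("context transfer succeeds on a pure shared-context signal", {
  d <- make_design(1, 5, seed = 58)
  spec <- signal_spec(n_voxels = 60, amp_bound = 0, amp_context = 2,
                      amp_event = 0, noise_sd = 0.1, p_inaccurate = 0)
  ps <- simulate_patterns(d, spec, seed = 59)$pattern_set[[1]]
  tr <- decode_transfer(ps, "context")
  expect_equal(tr$accuracy, 1)
  expect_equal(tr$train_pair, c("A", "B"))
  expect_equal(tr$test_pair, c("C", "D"))
  expect_equal(tr$chance, 0.5)
})

test_that("event transfer succeeds on a pure shared-event signal", {
  d <- make_design(1, 5, seed = 60)
  spec <- signal_spec(n_voxels = 60, amp_bound = 0, amp_context = 0,
                      amp_event = 2, noise_sd = 0.1, p_inaccurate = 0)
  ps <- simulate_patterns(d, spec, seed = 61)$pattern_set[[1]]
  tr <- decode_transfer(ps, "event")
  expect_equal(tr$accuracy, 1)
  expect_equal(tr$train_pair, c("A", "C"))
  expect_equal(tr$test_pair, c("B", "D"))
})

test_that("bound-only signal transfers at chance on average", {
  d <- make_design(1, 10, seed = 62)
  spec <- signal_spec(n_voxels = 80, amp_bound = 2, amp_context = 0,
                      amp_event = 0, noise_sd = 1, p_inaccurate = 0)
  accs <- sapply(1:50, function(s)
    decode_transfer(simulate_patterns(d, spec, seed = s)$pattern_set[[1]],
                    "context")$accuracy)
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("transfer guards invalid pairs and missing conditions", {
  ps <- make_cluster_set(seed = 63)
  expect_error(decode_transfer(ps, "context", train_pair = c("A", "D")),
               class = "patternsep_error_invalid_pair")
  expect_error(decode_transfer(ps, "context", train_pair = c("A", "B"),
                               test_pair = c("A", "C")),
               class = "patternsep_error_invalid_pair")
  # custom but valid: train C/D, test A/B
  tr <- decode_transfer(ps, "context", train_pair = c("C", "D"),
                        test_pair = c("A", "B"))
  expect_equal(unname(tr$train_pair), c("C", "D"))
  gone <- pattern_set(ps$patterns, ps$labels, ps$labels != "D")
  expect_error(decode_transfer(gone, "context"),
               class = "patternsep_error_insufficient_trials")
})

test_that("tidiers expose per-trial and summary views", {
  ps <- make_cluster_set(seed = 64)
  r <- decode_loto(ps)
  td <- tidy(r)
  expect_equal(nrow(td), 16)
  expect_true(all(td$correct))
  gl <- glance(r)
  expect_equal(gl$accuracy, 1)
  expect_equal(gl$pct_above_chance, 75)
  tr <- decode_transfer(ps, "context")
  expect_equal(nrow(tidy(tr)), 8)
  expect_s3_class(autoplot(r), "ggplot")
})
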