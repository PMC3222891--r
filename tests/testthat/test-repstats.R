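test_that("misclassification counts follow the shared-factor relation", {
  # frozen expectation derived cell-by-cell from the relation structure:
  # A->C, B->D, C->A are spatial (4), A->B, D->C are content (2)
  cm <- matrix(c(18, 1, 1, 0,
                 0, 19, 0, 1,
                 2, 0, 18, 0,
                 0, 0, 1, 19),
               4, 4, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  prof <- misclass_profile(cm)
  expect_equal(unname(prof$counts), c(4L, 2L, 0L), ignore_attr = TRUE)
  expect_equal(prof$n_errors, 6L)
  expect_equal(unname(prof$proportions["spatial"]), 4 / 6)
  # invariance to the diagonal
  cm2 <- cm; diag(cm2) <- 0
  expect_equal(misclass_profile(cm2)$counts, prof$counts)
})

test_that("uniform and purely spatial error patterns give known profiles", {
  uni <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(uni) <- 17
  expect_equal(unname(misclass_profile(uni)$proportions),
               rep(1 / 3, 3), ignore_attr = TRUE)
  sp <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  sp["A", "C"] <- 5; sp["C", "A"] <- 3; sp["B", "D"] <- 2; sp["D", "B"] <- 4
  expect_equal(unname(misclass_profile(sp)$proportions["spatial"]), 1)
  none <- diag(20, 4)
  dimnames(none) <- list(LETTERS[1:4], LETTERS[1:4])
  prof0 <- misclass_profile(none)
  expect_equal(prof0$n_errors, 0L)
  expect_true(all(is.na(prof0$proportions)))
})

test_that("compare_misclass applies the paired one-tailed convention", {
  mk <- function(sp, co, or) {
    structure(list(counts = c(spatial = sp, content = co, orthogonal = or),
                   proportions = c(spatial = sp, content = co,
                                   orthogonal = or) / (sp + co + or),
                   n_errors = sp + co + or),
              class = "ps_misclass")
  }
  # identical proportions in every participant -> exact null
  same <- replicate(4, mk(2, 2, 2), simplify = FALSE)
  r0 <- compare_misclass(same, "spatial_vs_content")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  # constant nonzero differences -> zero-variance error
  shifted <- replicate(4, mk(3, 2, 2), simplify = FALSE)
  expect_error(compare_misclass(shifted, "spatial_vs_content"),
               class = "patternsep_error_zero_variance")
  # hand-computed t for a known difference vector
  base <- c(0.2, -0.1, 0.05, 0.15, 0.0)
  profs <- lapply(base, function(dd) {
    sp <- (1 / 3 + dd / 2) * 600; co <- (1 / 3 - dd / 2) * 600
    mk(round(sp), round(co), 600 - round(sp) - round(co))
  })
  r <- compare_misclass(profs, "spatial_vs_content")
  d <- vapply(profs, function(p)
    p$proportions[["spatial"]] - p$proportions[["content"]], numeric(1))
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$df, 4L)
  expect_equal(r$p, pt(r$t, 4, lower.tail = FALSE))
  # zero-error participants are excluded with a warning
  with_zero <- c(profs, list(mk(0, 0, 0)))
  expect_warning(r2 <- compare_misclass(with_zero, "spatial_vs_content"),
                 "zero misclassifications")
  expect_equal(r2$t, r$t)
  expect_error(suppressWarnings(
    compare_misclass(list(mk(1, 1, 1), mk(0, 0, 0)), "spatial_vs_content")),
    class = "patternsep_error_insufficient_data")
})

test_that("t_vs_chance implements the one-sample upper-tail test", {
  expect_equal(t_vs_chance(rep(0.25, 5), 0.25)$t, 0)
  expect_equal(t_vs_chance(rep(0.25, 5), 0.25)$p, 0.5)
  r0 <- t_vs_chance(c(0.30, 0.20, 0.30, 0.20), 0.25)
  expect_equal(r0$t, 0)
  acc <- c(0.35, 0.30, 0.25, 0.40, 0.30)
  r <- t_vs_chance(acc, 0.25)
  expect_equal(r$t, mean(acc - 0.25) / (sd(acc) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$df, 4L)
  expect_equal(r$p, pt(r$t, 4, lower.tail = FALSE))
  expect_error(t_vs_chance(0.3, 0.25),
               class = "patternsep_error_insufficient_data")
  expect_error(t_vs_chance(c(0.3, 0.3, 0.3), 0.25),
               class = "patternsep_error_zero_variance")
  # translation covariance
  r2 <- t_vs_chance(acc + 0.1, 0.35)
  expect_equal(r2$t, r$t, tolerance = 1e-12)
})

test_that("t_tail_p is the upper tail of Student's t", {
  expect_equal(t_tail_p(0, 5), 0.5)
  expect_equal(t_tail_p(0, 50), 0.5)
  # strictly decreasing in t; symmetric tails sum to one
  ts <- seq(-3, 3, by = 0.5)
  ps <- t_tail_p(ts, 14)
  expect_true(all(diff(ps) < 0))
  expect_equal(t_tail_p(ts, 14) + t_tail_p(-ts, 14), rep(1, length(ts)))
  expect_error(t_tail_p(1, 0), class = "patternsep_error_invalid_parameter")
})

test_that("permutation p-values honor the add-one rule and its bounds", {
  d <- make_design(4, 4, seed = 70)
  # strong signal: observed exceeds every null mean
  tbl <- simulate_patterns(d, signal_spec(n_voxels = 30, amp_bound = 3,
                                          amp_context = 0, amp_event = 0,
                                          noise_sd = 0.2, p_inaccurate = 0),
                           seed = 71)
  g <- permutation_test(tbl, "fourway", n_perm = 100, seed = 72)
  expect_equal(g$perm_p, 1 / 101)
  expect_equal(g$n_permutations, 100L)
  expect_equal(length(g$null_means), 100L)
  # internal consistency of the add-one formula
  expect_equal(g$perm_p, (1 + sum(g$null_means >= g$mean)) / 101)
  expect_gte(g$perm_p, 1 / 101)
  # determinism
  g2 <- permutation_test(tbl, "fourway", n_perm = 100, seed = 72)
  expect_identical(g$null_means, g2$null_means)
  expect_error(permutation_test(tbl, "fourway", n_perm = 50, seed = 1),
               class = "patternsep_error_invalid_parameter")
  expect_error(permutation_test(tbl, "sideways", n_perm = 100, seed = 1),
               class = "patternsep_error_invalid_parameter")
})

test_that("null data give an unremarkable permutation p-value", {
  d <- make_design(4, 5, seed = 73)
  tbl <- simulate_patterns(d, signal_spec(n_voxels = 30, amp_bound = 0,
                                          amp_context = 0, amp_event = 0,
                                          noise_sd = 1, p_inaccurate = 0),
                           seed = 74)
  g <- permutation_test(tbl, "context_transfer", n_perm = 200, seed = 75)
  expect_gt(g$perm_p, 0.05)
  expect_lte(g$perm_p, 1)
})

test_that("group tidiers summarize inference results", {
  g <- t_vs_chance(c(0.3, 0.35, 0.28, 0.4), 0.25)
  expect_equal(nrow(tidy(g)), 4)
  gl <- glance(g)
  expect_equal(gl$df, 3L)
  expect_true(is.na(gl$perm_p))
})
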