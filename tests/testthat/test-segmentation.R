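test_that("a noiseless two-segment curve is recovered exactly", {
  x <- seq(0, 10, length.out = 300)
  y <- ifelse(x < 5, x, 5 + 3 * (x - 5))
  fit <- fit_segmented(list(x = x, y = y), target_adj_r2 = 0.999)
  expect_equal(fit$k, 1L)
  expect_equal(fit$psi, 5, tolerance = 0.05)
  expect_equal(fit$slopes, c(1, 3), tolerance = 1e-6)
  expect_gt(fit$adj_r2, 0.9999)
  expect_true(fit$objective_met)
})

test_that("a straight line needs no breakpoints", {
  set.seed(2)
  x <- seq(0, 10, length.out = 400)
  y <- 2 + 3 * x + rnorm(400, 0, 0.01)
  fit <- fit_segmented(list(x = x, y = y), target_adj_r2 = 0.995)
  expect_equal(fit$k, 0L)
  expect_length(fit$psi, 0)
})

test_that("residual error never increases with more breakpoints", {
  pw <- make_piecewise(n = 600, seed = 5)
  rss <- numeric(5)
  prev <- NULL
  for (k in 0:4) {
    warm <- if (k > 0 && !is.null(prev) && length(prev$psi) == k - 1) {
      lapply(quantile(pw$x, c(0.2, 0.5, 0.8)),
             function(p) sort(c(prev$psi, p)))
    } else NULL
    fit <- fit_segments_k(pw$x, pw$y, k, n_restarts = 4, warm = warm)
    rss[k + 1] <- fit$rss
    prev <- fit
  }
  expect_true(all(diff(rss) <= 1e-6 * rss[1]))
})

test_that("Davies' test detects a strong break and degenerates to p = 1", {
  set.seed(3)
  x <- seq(0, 1, length.out = 500)
  y <- ifelse(x < 0.5, x, 0.5 + 2 * (x - 0.5)) + rnorm(500, 0, 0.05)
  expect_lt(davies_test(list(x = x, y = y)), 1e-3)
  expect_equal(davies_test(list(x = x, y = rep(1, 500))), 1)
})

test_that("cross-validation prefers the line for linear data and is seeded", {
  set.seed(4)
  x <- sort(runif(400, 0, 10))
  y <- 1 + 2 * x + rnorm(400, 0, 0.5)
  cv1 <- kfold_cv_segmentation(list(x = x, y = y), candidate_ks = 0:2,
                               seed = 7)
  cv2 <- kfold_cv_segmentation(list(x = x, y = y), candidate_ks = 0:2,
                               seed = 7)
  expect_identical(cv1, cv2)
  expect_equal(cv_select_k(cv1), 0L)
  expect_error(kfold_cv_segmentation(list(x = x[1:20], y = y[1:20]),
                                     candidate_ks = 0:5), "too few")
})

test_that("outer phases are trimmed to the outermost breakpoints", {
  fake <- structure(list(k = 3L, psi = c(2.5, 4, 9), x = c(1, 12)),
                    class = "segmentation_fit")
  expect_equal(trim_outer_phases(fake), c(2.5, 9))
  one <- structure(list(k = 1L, psi = 4, x = c(1, 12)),
                   class = "segmentation_fit")
  expect_warning(rng <- trim_outer_phases(one), "full u range")
  expect_equal(rng, c(1, 12))
})

test_that("mutations outside the accepted range are excluded exactly", {
  pw <- make_piecewise(n = 1500, breaks = c(4, 16), slopes = c(8, 2, 8),
                       sd = 2, seed = 6)
  fit <- fit_segmented(list(x = pw$x, y = pw$y), target_adj_r2 = 0.999,
                       max_breakpoints = 4)
  expect_gte(fit$k, 2L)
  rng <- trim_outer_phases(fit)
  inside <- sum(pw$x >= rng[1] & pw$x <= rng[2])
  expect_equal(inside + sum(pw$x < rng[1]) + sum(pw$x > rng[2]), 1500)
  expect_lt(inside, 1500)
})
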