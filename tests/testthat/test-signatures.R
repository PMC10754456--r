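test_that("binning on u tiles the accepted range with left-closed bins", {
  rec <- toy_variants(c(0.5, 1 / 2.5, 0.25),
                      context = c("A[C>T]G", "A[C>T]G", "T[T>C]A"))
  bins <- bin_spectra(rec, halfwidth = 0.5)
  expect_equal(bins$centers, c(2, 3, 4))
  # u = 2 sits in the bin centred at 2; the edge u = 2.5 goes right
  expect_equal(unname(bins$totals), c(1, 1, 1))
  expect_equal(sum(bins$counts), 3)
  rec2 <- rbind(rec, toy_variants(0.5, context = NA))
  expect_warning(b2 <- bin_spectra(rec2, 0.5), "lack a valid context")
  expect_equal(sum(b2$counts), 3)
})

test_that("NNLS recovers exact mixtures and satisfies the KKT conditions", {
  cat2 <- synthetic_signature_catalog()[, c("SBS1", "SBS5")]
  counts <- 700 * cat2[, 1] + 300 * cat2[, 2]
  fit <- fit_exposures(counts, cat2)
  expect_equal(unname(fit$theta), c(700, 300), tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)

  pure <- fit_exposures(1000 * cat2[, 1], cat2)
  expect_equal(unname(pure$theta), c(1000, 0), tolerance = 1e-6)

  zero <- fit_exposures(rep(0, 96), cat2)
  expect_true(zero$flagged)
  expect_equal(unname(zero$theta), c(0, 0))

  # KKT at a noisy solution: active gradients ~ 0, inactive >= 0
  set.seed(12)
  noisy <- as.vector(rmultinom(1, 5000, 0.6 * cat2[, 1] + 0.4 * cat2[, 2]))
  nf <- fit_exposures(noisy, cat2)
  grad <- drop(crossprod(cat2, cat2 %*% nf$theta - noisy))
  active <- nf$theta > 1e-8
  expect_true(all(abs(grad[active]) < 1e-6 * sum(noisy)))
  expect_true(all(grad[!active] >= -1e-8))
})

test_that("permuting catalog columns permutes exposures identically", {
  cat3 <- synthetic_signature_catalog()
  set.seed(5)
  counts <- as.vector(rmultinom(1, 3000, cat3 %*% c(0.5, 0.3, 0.2)))
  f1 <- fit_exposures(counts, cat3)
  f2 <- fit_exposures(counts, cat3[, c(3, 1, 2)])
  expect_equal(f2$theta[colnames(cat3)], f1$theta[colnames(cat3)],
               tolerance = 1e-8)
})

test_that("noisy mixtures are recovered within sampling error", {
  cat2 <- synthetic_signature_catalog()[, c("SBS1", "SBS5")]
  set.seed(77)
  n <- 1e4
  counts <- as.vector(rmultinom(1, n, 0.6 * cat2[, 1] + 0.4 * cat2[, 2]))
  th <- fit_exposures(counts, cat2)$theta
  expect_equal(unname(th) / n, c(0.6, 0.4), tolerance = 0.05)
})

test_that("bootstrap exposure CIs are seeded and bracket the point fit", {
  cat2 <- synthetic_signature_catalog()[, c("SBS1", "SBS5")]
  set.seed(41)
  n <- 2000
  ch <- sample(sbs_channels(), n, replace = TRUE,
               prob = 0.6 * cat2[, 1] + 0.4 * cat2[, 2])
  rec <- toy_variants(rep(0.5, n), context = ch)
  b1 <- bootstrap_exposures(rec, cat2, B = 150, seed = 6)
  b2 <- bootstrap_exposures(rec, cat2, B = 150, seed = 6)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_lo <= b1$exposure + 1e-9 &
                    b1$exposure <= b1$ci_hi + 1e-9))
  expect_equal(sum(b1$exposure), n, tolerance = 0.02 * n)
})
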