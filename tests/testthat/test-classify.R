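test_that("standardization centres, scales and is affine-invariant", {
  p1 <- data.frame(t = seq(0, 1, length.out = 20),
                   wgn = 2 * seq(0, 1, length.out = 20))
  p2 <- data.frame(t = p1$t, wgn = 5 + 3 * p1$wgn) # affine transform
  m <- standardize_profiles(list(a = p1, b = p2))
  expect_equal(dim(m), c(2L, 1000L))
  expect_equal(unname(rowMeans(m)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(m, 1, sd)), c(1, 1), tolerance = 1e-9)
  expect_equal(m["a", ], m["b", ], tolerance = 1e-9)

  # idempotence: standardizing a standardized curve changes nothing
  again <- standardize_profiles(list(a = data.frame(t = 1:1000,
                                                    wgn = m["a", ])))
  expect_equal(unname(again[1, ]), unname(m["a", ]), tolerance = 1e-6)

  # 3-point profile: endpoints preserved by linear interpolation
  p3 <- data.frame(t = c(0, 1, 2), wgn = c(0, 1, 0))
  m3 <- standardize_profiles(list(x = p3))
  expect_equal(m3[1, 1], m3[1, 1000])
  expect_warning(standardize_profiles(list(
    ok = p1, flat = data.frame(t = 1:5, wgn = rep(2, 5)))), "constant")
})

test_that("Calinski-Harabasz matches brute force and caps perfect splits", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  got <- calinski_harabasz(x, c(1, 1, 2, 2))
  # direct formula: B = 100, W = 1, (B/1)/(W/2) = 200
  expect_equal(got, 200)
  # exhaustive check: the natural split maximizes CH over all 2-partitions
  parts <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1),
                c(1, 1, 1, 2), c(1, 2, 2, 2), c(2, 1, 2, 2), c(1, 1, 2, 1))
  chs <- vapply(parts, function(p) calinski_harabasz(x, p), numeric(1))
  expect_equal(which.max(chs), 1L)
  expect_equal(calinski_harabasz(matrix(c(0, 0, 10, 10), ncol = 1),
                                 c(1, 1, 2, 2)), 1e12)
  expect_error(calinski_harabasz(x, c(1, 1, 1, 1)), "2 clusters")
})

test_that("the test helper's adjusted Rand agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(44)
  for (r in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("random labels on structureless data give CH near 1", {
  set.seed(15)
  x <- matrix(rnorm(200), ncol = 2)
  chs <- replicate(60, calinski_harabasz(x, sample(1:2, 100, TRUE)))
  expect_gt(mean(chs), 0.4)
  expect_lt(mean(chs), 2)
})

test_that("k-means separates well-separated shapes and is deterministic", {
  arch <- make_archetypes(n_rep = 6, noise = 0.05, seed = 3)
  m <- standardize_profiles(arch$profiles)
  part <- kmeans_curves(m, k_candidates = c(2, 4), seed = 5)
  part2 <- kmeans_curves(m, k_candidates = c(2, 4), seed = 5)
  expect_identical(part$fits, part2$fits)
  lab4 <- part$fits[["4"]]$labels
  expect_equal(adjusted_rand(lab4, arch$truth), 1)
  # duplication invariance: duplicated curves cluster like the originals
  m2 <- rbind(m, m)
  part_dup <- kmeans_curves(m2, k_candidates = 4, seed = 5)
  labs <- part_dup$fits[["4"]]$labels
  expect_equal(adjusted_rand(labs[seq_len(nrow(m))],
                             labs[nrow(m) + seq_len(nrow(m))]), 1)
  expect_warning(kmeans_curves(m[1:3, ], k_candidates = 4), "skipped")
})

test_that("partition selection covers reference shapes within the CH margin", {
  arch <- make_archetypes(n_rep = 8, noise = 0.15, seed = 8)
  m <- standardize_profiles(arch$profiles)
  parts <- kmeans_curves(m, k_candidates = 2:5, seed = 2)
  pick <- select_partition(
    parts, reference_shapes = c("convex", "peak", "increase", "paused_start"),
    tolerance = 0.5
  )
  expect_setequal(tolower(pick$cluster_names),
                  c("convex", "peak", "increase", "paused_start"))
  expect_match(pick$rationale, "covering shapes")
  pure <- select_partition(parts)
  expect_equal(pure$k, parts$ch_table$k[which.max(parts$ch_table$ch)])
  expect_equal(pure$rationale, "argmax CH")
})
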