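test_that("mu = 0 yields no mutations and deterministic doubling", {
  cfg <- sim_config(mu = 0, omega = 1, gamma = 1, n0 = 4,
                    n_generations = 6, seed = 3)
  sim <- simulate_clonal_expansion(cfg)
  expect_equal(nrow(sim$variants), 0L)
  expect_equal(sim$truth$N, 4 * 2^(0:6))
})

test_that("the same seed reproduces an identical variant table", {
  cfg <- sim_config(mu = 0.5, n0 = 10, n_generations = 8, seed = 11)
  s1 <- simulate_clonal_expansion(cfg)
  s2 <- simulate_clonal_expansion(cfg)
  expect_identical(s1$variants, s2$variants)
})

test_that("gamma = 0 produces an explicit extinct result", {
  cfg <- sim_config(mu = 0.3, omega = 1, gamma = 0, n0 = 5,
                    n_generations = 3, seed = 1)
  sim <- simulate_clonal_expansion(cfg)
  expect_equal(sim$status, "extinct")
  expect_equal(nrow(sim$variants), 0L)
})

test_that("true frequencies satisfy f = carriers / (pi * N) in (0, 1]", {
  cfg <- sim_config(mu = 0.4, ploidy_pi = 3, n0 = 10, n_generations = 9,
                    seed = 5)
  sim <- simulate_clonal_expansion(cfg)
  n_final <- tail(sim$truth$N, 1)
  expect_true(all(sim$variants$carriers >= 1))
  expect_equal(sim$variants$true_f,
               sim$variants$carriers / (3 * n_final))
  expect_true(all(sim$variants$true_f > 0 & sim$variants$true_f <= 1))
  # truth ledger and variant table agree (event conservation)
  expect_equal(nrow(sim$truth$events), nrow(sim$variants))
})

test_that("population size is nondecreasing in the budding model", {
  cfg <- sim_config(mu = 0.1, omega = 0.5, gamma = 0.4, n0 = 50,
                    n_generations = 30, seed = 2,
                    offspring_model = "budding")
  sim <- simulate_clonal_expansion(cfg)
  expect_true(all(diff(sim$truth$N) >= 0))
})

test_that("simulated spectra recover the configured signature mixture", {
  cfg <- sim_config(mu = 2, n0 = 50, n_generations = 9, gamma = 0.95,
                    seed = 7,
                    signature_weights = c(SBS1 = 0.7, SBS5 = 0.3))
  sim <- simulate_clonal_expansion(cfg)
  expect_gt(nrow(sim$variants), 1e4)
  emp <- sim$truth$realized_spectrum / sum(sim$truth$realized_spectrum)
  target <- as.vector(cfg$catalog[, c("SBS1", "SBS5")] %*% c(0.7, 0.3))
  tv <- 0.5 * sum(abs(emp - target))
  expect_lt(tv, 0.05)
})

test_that("impossible survival ratios error; full-resection continuation matches", {
  cfg <- sim_config(mu = 0.3, gamma = 0.9, n0 = 10, n_generations = 6,
                    seed = 9)
  expect_error(simulate_primary_recurrent(cfg, gamma_ratio = 2,
                                          resection_fraction = 0.5),
               "exceed")
  # resection_fraction = 1 with no recurrent growth: inherited VAFs match
  pair <- simulate_primary_recurrent(cfg, gamma_ratio = 1,
                                     resection_fraction = 1,
                                     n_generations_recurrent = 0)
  expect_equal(pair$status, "ok")
  prim <- pair$primary$variants
  rec <- pair$recurrent$variants
  expect_true(all(!rec$de_novo))
  m <- match(rec$pos, prim$pos)
  expect_true(all(!is.na(m)))
  expect_equal(rec$true_f, prim$true_f[m])
})

test_that("sequencing noise follows Poisson/binomial sampling", {
  v <- toy_variants(rep(0.5, 1e4))
  v$true_f <- v$freq
  nz <- attach_sequencing_noise(v, 100, seed = 4)
  expect_equal(mean(nz$freq, na.rm = TRUE), 0.5, tolerance = 0.01)
  expect_equal(mean(nz$depth), 100, tolerance = 0.05 * 100)
  # deep sequencing converges to the true frequency
  v2 <- toy_variants(c(0.2, 0.5, 0.8))
  v2$true_f <- v2$freq
  deep <- attach_sequencing_noise(v2, 1e6, seed = 1)
  expect_equal(deep$freq, v2$true_f, tolerance = 1e-2)
  # a clonal mutation is seen in every read
  v3 <- toy_variants(1)
  v3$true_f <- 1
  all_alt <- attach_sequencing_noise(v3, 50, seed = 1)
  expect_equal(all_alt$alt_depth, all_alt$depth)
  expect_error(attach_sequencing_noise(v3, 0), "positive")
})
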