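# Shared fixtures and small independent oracles for the test suite.

toy_variants <- function(f, qual = 50, depth = 100, context = NA,
                         effect = NA) {
  n <- length(f)
  data.frame(
    chrom = "chr1", pos = seq_len(n) * 100L,
    ref = "C", alt = "T",
    qual = rep_len(qual, n), depth = rep_len(depth, n),
    alt_depth = round(rep_len(depth, n) * f),
    freq = f,
    context = rep_len(context, n), effect = rep_len(effect, n),
    stringsAsFactors = FALSE
  )
}

# adjusted Rand index, computed from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# noisy piecewise-linear curve with known interior breakpoints
make_piecewise <- function(n = 2000, breaks = c(5, 10, 15),
                           slopes = c(2, 6, 1, 4), sd = 5, seed = 1,
                           xmax = 20) {
  set.seed(seed)
  x <- sort(runif(n, 0, xmax))
  y <- slopes[1] * x
  for (j in seq_along(breaks)) {
    y <- y + (slopes[j + 1] - slopes[j]) * pmax(x - breaks[j], 0)
  }
  list(x = x, y = y + rnorm(n, 0, sd), breaks = breaks)
}

# archetype expansion profiles (4 shapes x n_rep noisy replicates)
make_archetypes <- function(n_rep = 10, noise = 0.2, seed = 1,
                            n_points = 60) {
  set.seed(seed)
  s <- seq(0, 1, length.out = n_points)
  shapes <- list(
    convex = 4 * (s - 0.5)^2,
    peak = sin(pi * s),
    increase = s,
    paused_start = pmax(0, s - 0.5)
  )
  profiles <- list()
  truth <- integer(0)
  for (k in seq_along(shapes)) {
    for (r in seq_len(n_rep)) {
      v <- shapes[[k]] + rnorm(n_points, 0, noise)
      profiles[[paste0(names(shapes)[k], "_", r)]] <-
        data.frame(t = s, wgn = v)
      truth <- c(truth, k)
    }
  }
  list(profiles = profiles, truth = truth)
}
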