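# Synthetic clonal-expansion simulator with full ground truth.
#
# Model: discrete non-overlapping generations. In each generation every
# cell divides with probability p = min(1, omega); every surviving
# daughter acquires Poisson(mu) new single-base substitutions on one of
# the pi genome copies (infinite-sites: each event hits a fresh
# coordinate). Two division modes (see gw_step): fission (parent replaced
# by two daughters, each surviving w.p. gamma; gamma = 0 with full
# division drives extinction) and budding (parent persists, one daughter
# per division; survival-limited growth at small gamma). Both are
# discrete counterparts of dN = omega * gamma * N dt.

#' Simulation configuration for the clonal-expansion generator
#'
#' @param mu Mutations per genome per division (>= 0).
#' @param genome_size Genome length in nt (coordinates are drawn from it).
#' @param ploidy_pi Copies per cell (integer >= 1); a mutation sits on one
#'   copy, so a fully clonal mutation has allele frequency 1/ploidy_pi.
#' @param omega Divisions per unit time; scalar or function of the
#'   generation index. Per generation the division probability is
#'   `min(1, omega)`.
#' @param gamma Per-daughter survival probability in \[0, 1\]; scalar or
#'   function of the generation index (step functions model e.g. a
#'   treatment-induced survival drop).
#' @param n0 Founding cells.
#' @param n_generations Number of generations to simulate.
#' @param signature_weights Named nonnegative weights over catalog columns,
#'   summing to 1; the trinucleotide channel of each mutation is drawn from
#'   the corresponding signature mixture.
#' @param selection_s Retention probability of nonsynonymous mutations at
#'   origination (1 = neutral, < 1 purifying).
#' @param coding_fraction Fraction of mutations falling in coding sequence.
#' @param nonsyn_opportunity Genome-wide nonsynonymous/synonymous
#'   opportunity ratio used to label coding mutations before selection.
#' @param depth Mean sequencing depth used by [attach_sequencing_noise()].
#' @param seed Integer RNG seed; all randomness derives from it.
#' @param catalog 96 x S signature catalog; defaults to
#'   [synthetic_signature_catalog()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(mu = 0.3, genome_size = 3e9, ploidy_pi = 2,
                       omega = 1, gamma = 0.9, n0 = 10, n_generations = 12,
                       signature_weights = c(SBS1 = 0.5, SBS5 = 0.5),
                       selection_s = 1, coding_fraction = 0.02,
                       nonsyn_opportunity = 3, depth = 100, seed = 1,
                       catalog = synthetic_signature_catalog(),
                       offspring_model = c("fission", "budding")) {
  offspring_model <- match.arg(offspring_model)
  stopifnot(
    mu >= 0, genome_size >= 1, ploidy_pi >= 1, n0 >= 1, n_generations >= 0,
    selection_s >= 0, selection_s <= 1,
    coding_fraction >= 0, coding_fraction <= 1, depth > 0
  )
  w <- signature_weights
  if (is.null(names(w)) || !all(names(w) %in% colnames(catalog))) {
    stop("signature_weights must be named by catalog columns")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("signature_weights must be nonnegative and sum to 1")
  }
  gfun <- if (is.function(gamma)) gamma else function(t) gamma
  ofun <- if (is.function(omega)) omega else function(t) omega
  for (t in seq_len(max(1, n_generations))) {
    gt <- gfun(t); ot <- ofun(t)
    if (gt < 0 || gt > 1) stop("gamma must lie in [0, 1] at all times")
    if (ot < 0) stop("omega must be >= 0 at all times")
  }
  structure(
    list(
      mu = mu, genome_size = genome_size, ploidy_pi = as.integer(ploidy_pi),
      omega = omega, gamma = gamma, n0 = as.integer(n0),
      n_generations = as.integer(n_generations),
      signature_weights = w, selection_s = selection_s,
      coding_fraction = coding_fraction,
      nonsyn_opportunity = nonsyn_opportunity,
      depth = depth, seed = as.integer(seed), catalog = catalog,
      offspring_model = offspring_model
    ),
    class = "sim_config"
  )
}

as_rate_fun <- function(x) if (is.function(x)) x else function(t) x

# One generation step. pop size n; returns parent pointers of the next
# generation and which of its cells are fresh (mutation-acquiring) daughters.
# fission: a division replaces the parent by two daughters, each surviving
#   with probability gamma (expected growth 1 - p + 2*p*gamma; gamma = 0
#   with full division drives extinction).
# budding: the parent persists and each division adds one daughter
#   surviving with probability gamma (expected growth 1 + p*gamma; models
#   survival-limited expansions where gamma is small yet N still grows,
#   e.g. a treated tumor).
gw_step <- function(n, p_div, gamma, model = "fission") {
  divides <- runif(n) < p_div
  div_idx <- which(divides)
  n_daughters <- if (model == "fission") 2L else 1L
  keep_idx <- if (model == "fission") which(!divides) else seq_len(n)
  n_surv <- if (length(div_idx)) {
    rbinom(length(div_idx), n_daughters, gamma)
  } else integer(0)
  parents <- c(keep_idx, rep(div_idx, n_surv))
  fresh <- c(rep(FALSE, length(keep_idx)), rep(TRUE, sum(n_surv)))
  list(parents = as.integer(parents), fresh = fresh)
}

# Run generations gen_offset+1 .. gen_offset+n_gen from a starting
# population of size n_start. Returns parent-pointer lists, per-generation
# sizes, and raw mutation events (generation, cell index).
gw_generations <- function(n_start, n_gen, gen_offset, mu, omega_fun,
                           gamma_fun, model = "fission") {
  parents <- vector("list", n_gen)
  sizes <- integer(n_gen)
  ev_gen <- integer(0); ev_cell <- integer(0)
  n <- n_start
  for (g in seq_len(n_gen)) {
    t <- gen_offset + g
    if (n == 0L) { sizes[g] <- 0L; parents[[g]] <- integer(0); next }
    st <- gw_step(n, min(1, omega_fun(t)), gamma_fun(t), model)
    parents[[g]] <- st$parents
    n <- length(st$parents)
    sizes[g] <- n
    fresh_idx <- which(st$fresh)
    if (mu > 0 && length(fresh_idx)) {
      k <- rpois(length(fresh_idx), mu)
      ev_gen <- c(ev_gen, rep.int(t, sum(k)))
      ev_cell <- c(ev_cell, rep.int(fresh_idx, k))
    }
  }
  list(parents = parents, sizes = sizes, ev_gen = ev_gen, ev_cell = ev_cell)
}

# Number of final-generation descendants of every cell in every generation.
# parents[[g]] maps generation g cells to generation g-1 indices; returns a
# list desc[[g]] aligned with the generation-g population (g = 0 entry is
# the founder population, stored at index 1).
count_descendants <- function(n0, parents) {
  n_gen <- length(parents)
  desc <- vector("list", n_gen + 1L)
  last <- length(parents[[n_gen]])
  cur <- rep(1, last)
  desc[[n_gen + 1L]] <- cur
  for (g in rev(seq_len(n_gen))) {
    n_prev <- if (g == 1L) n0 else length(parents[[g - 1L]])
    prev <- numeric(n_prev)
    if (length(parents[[g]])) {
      agg <- rowsum(cur, parents[[g]])
      prev[as.integer(rownames(agg))] <- agg[, 1]
    }
    desc[[g]] <- prev
    cur <- prev
  }
  desc
}

# Draw channels, coding-effect labels and selection thinning for raw events.
annotate_events <- function(n_events, config) {
  if (n_events == 0L) {
    return(list(keep = logical(0), channel = character(0),
                effect = character(0)))
  }
  mix <- as.vector(config$catalog[, names(config$signature_weights), drop = FALSE] %*%
                     config$signature_weights)
  channel <- sample(sbs_channels(), n_events, replace = TRUE, prob = mix)
  coding <- runif(n_events) < config$coding_fraction
  p_nonsyn <- config$nonsyn_opportunity / (1 + config$nonsyn_opportunity)
  nonsyn <- coding & (runif(n_events) < p_nonsyn)
  effect <- ifelse(!coding, "noncoding", ifelse(nonsyn, "nonsyn", "syn"))
  keep <- rep(TRUE, n_events)
  if (config$selection_s < 1) {
    drop <- nonsyn & (runif(n_events) >= config$selection_s)
    keep <- !drop
  }
  list(keep = keep, channel = channel, effect = effect)
}

# Assemble a variant table for mutation events given per-generation
# descendant counts at the sequencing horizon.
build_variant_table <- function(ev_gen, ev_cell, channel, effect, desc,
                                n_final, config, positions, de_novo = NULL) {
  if (length(ev_gen) == 0L) {
    out <- empty_variant_table()
    if (!is.null(de_novo)) out$de_novo <- logical(0)
    return(out)
  }
  carriers <- vapply(seq_along(ev_gen), function(i) {
    desc[[ev_gen[i] + 1L]][ev_cell[i]]
  }, numeric(1))
  alive <- carriers > 0
  f <- carriers / (config$ploidy_pi * n_final)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ctx <- channel
  mid_ref <- substr(ctx, 3, 3)
  mid_alt <- substr(ctx, 5, 5)
  # random strand orientation of the reported ref/alt
  flip <- runif(length(ctx)) < 0.5
  ref <- ifelse(flip, comp[mid_ref], mid_ref)
  alt <- ifelse(flip, comp[mid_alt], mid_alt)
  df <- data.frame(
    chrom = "sim1",
    pos = positions,
    ref = ref, alt = alt,
    qual = NA_real_, depth = NA_integer_, alt_depth = NA_integer_,
    freq = f,
    context = ctx, effect = effect,
    true_f = f,
    origin_gen = ev_gen,
    carriers = carriers,
    stringsAsFactors = FALSE
  )
  if (!is.null(de_novo)) df$de_novo <- de_novo
  df <- df[alive, , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$pos), , drop = FALSE]
}

#' Simulate a clonal expansion with ground truth
#'
#' Runs the Galton-Watson style generative model described in the package
#' overview and returns every mutation present in at least one surviving
#' final-generation cell, with its true allele frequency
#' f = carriers / (ploidy * N_final).
#'
#' @param config A [sim_config()].
#' @return List with `status` (`"ok"` or `"extinct"`), `variants` (variant
#'   table data frame with true frequencies; sequencing fields are `NA`
#'   until [attach_sequencing_noise()]), and `truth` (per-generation
#'   population sizes `N`, the surviving event ledger, realized signature
#'   mixture, and the config).
#' @export
simulate_clonal_expansion <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gfun <- as_rate_fun(config$gamma)
  ofun <- as_rate_fun(config$omega)
  run <- gw_generations(config$n0, config$n_generations, 0L, config$mu,
                        ofun, gfun, config$offspring_model)
  N <- c(config$n0, run$sizes)
  n_final <- N[length(N)]
  if (n_final == 0L) {
    return(list(status = "extinct",
                variants = empty_variant_table(),
                truth = list(N = N, events = NULL, config = config)))
  }
  ann <- annotate_events(length(run$ev_gen), config)
  ev_gen <- run$ev_gen[ann$keep]
  ev_cell <- run$ev_cell[ann$keep]
  channel <- ann$channel[ann$keep]
  effect <- ann$effect[ann$keep]
  desc <- count_descendants(config$n0, run$parents)
  positions <- if (length(ev_gen)) sample.int(config$genome_size, length(ev_gen)) else integer(0)
  variants <- build_variant_table(ev_gen, ev_cell, channel, effect, desc,
                                  n_final, config, positions)
  realized <- table(factor(variants$context, levels = sbs_channels()))
  list(
    status = "ok",
    variants = variants,
    truth = list(
      N = N,
      events = variants[, c("pos", "origin_gen", "carriers", "true_f",
                            "context", "effect")],
      realized_spectrum = as.numeric(realized),
      config = config
    )
  )
}

empty_variant_table <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), qual = numeric(0), depth = integer(0),
    alt_depth = integer(0), freq = numeric(0), context = character(0),
    effect = character(0), true_f = numeric(0), origin_gen = integer(0),
    carriers = numeric(0), stringsAsFactors = FALSE
  )
}

#' Simulate a primary tumor and its post-resection recurrence
#'
#' The primary is grown under the config's survival schedule; at resection a
#' binomial subsample of cells (probability `resection_fraction`) seeds the
#' recurrence, which grows for `n_generations_recurrent` generations under
#' `gamma_R = gamma_ratio * gamma_P(end)`. Both tumors are "sequenced" at
#' their own final population: the primary table reflects the population at
#' resection, the recurrent table contains inherited plus de novo mutations
#' (flagged in its `de_novo` column).
#'
#' @param config A [sim_config()]; `n_generations` is the primary duration.
#' @param gamma_ratio Survival ratio gamma_R / gamma_P applied at resection
#'   (> 0); errors if the implied gamma_R exceeds 1.
#' @param resection_fraction Fraction of primary cells seeding the
#'   recurrence, in (0, 1].
#' @param n_generations_recurrent Recurrence duration in generations.
#' @return List with `status`, `primary`, `recurrent` (each as in
#'   [simulate_clonal_expansion()]), and `truth` holding the realized
#'   gamma ratio and the resection generation.
#' @export
simulate_primary_recurrent <- function(config, gamma_ratio,
                                       resection_fraction,
                                       n_generations_recurrent =
                                         config$n_generations) {
  stopifnot(inherits(config, "sim_config"), gamma_ratio > 0,
            resection_fraction > 0, resection_fraction <= 1)
  gfun <- as_rate_fun(config$gamma)
  ofun <- as_rate_fun(config$omega)
  g_p_end <- gfun(config$n_generations)
  gamma_R <- gamma_ratio * g_p_end
  if (gamma_R > 1) {
    stop("gamma_ratio * gamma_P = ", signif(gamma_R, 4),
         " exceeds 1: survival probability cannot exceed 1")
  }
  set.seed(config$seed)
  G_P <- config$n_generations
  run_p <- gw_generations(config$n0, G_P, 0L, config$mu, ofun, gfun,
                          config$offspring_model)
  N_p <- c(config$n0, run_p$sizes)
  n_p_final <- N_p[length(N_p)]
  if (n_p_final == 0L) {
    return(list(status = "extinct", primary = NULL, recurrent = NULL,
                truth = list(N_primary = N_p, config = config)))
  }

  # resection: pure subsampling generation (no division, no mutations)
  keep <- which(runif(n_p_final) < resection_fraction)
  if (length(keep) == 0L) keep <- sample.int(n_p_final, 1L)

  run_r <- gw_generations(length(keep), n_generations_recurrent, G_P + 1L,
                          config$mu, ofun, function(t) gamma_R,
                          config$offspring_model)
  N_r <- c(length(keep), run_r$sizes)
  n_r_final <- N_r[length(N_r)]

  # annotate all events in one stream (keeps one seed for everything)
  ev_gen <- c(run_p$ev_gen, run_r$ev_gen)
  ev_cell <- c(run_p$ev_cell, run_r$ev_cell)
  ann <- annotate_events(length(ev_gen), config)
  positions <- sample.int(config$genome_size, length(ev_gen))

  # primary horizon: descendants within the primary lineage only
  desc_p <- count_descendants(config$n0, run_p$parents)
  in_p <- seq_along(run_p$ev_gen)
  keep_p <- ann$keep[in_p]
  prim <- build_variant_table(
    run_p$ev_gen[keep_p], run_p$ev_cell[keep_p],
    ann$channel[in_p][keep_p], ann$effect[in_p][keep_p],
    desc_p, n_p_final, config, positions[in_p][keep_p]
  )

  # recurrence horizon: chain primary generations + resection + recurrence
  resection_parents <- as.integer(keep)
  chain <- c(run_p$parents, list(resection_parents), run_r$parents)
  desc_r <- count_descendants(config$n0, chain)
  # run_r event generations are offset by G_P + 1, which already accounts
  # for the resection pseudo-generation slot in the chain
  ev_gen_r <- c(run_p$ev_gen, run_r$ev_gen)
  all_keep <- ann$keep
  rec <- if (n_r_final > 0L) {
    build_variant_table(
      ev_gen_r[all_keep], ev_cell[all_keep],
      ann$channel[all_keep], ann$effect[all_keep],
      desc_r, n_r_final, config, positions[all_keep],
      de_novo = (ev_gen[all_keep] > G_P)
    )
  } else NULL
  # restore true origin generation on the recurrence table (undo pseudo-gen)
  if (!is.null(rec)) {
    rec$origin_gen <- ifelse(rec$origin_gen > G_P, rec$origin_gen - 1L,
                             rec$origin_gen)
  }

  list(
    status = if (n_r_final > 0L) "ok" else "extinct",
    primary = list(status = "ok", variants = prim,
                   truth = list(N = N_p, config = config)),
    recurrent = if (n_r_final > 0L) {
      list(status = "ok", variants = rec,
           truth = list(N = N_r, gamma = gamma_R))
    } else NULL,
    truth = list(
      gamma_P_end = g_p_end, gamma_R = gamma_R,
      gamma_ratio = gamma_R / g_p_end,
      resection_generation = G_P,
      n_kept_at_resection = length(keep),
      N_primary = N_p, N_recurrent = N_r
    )
  )
}

#' Overlay binomial sequencing noise on true allele frequencies
#'
#' Total depth is Poisson(depth), alternate depth Binomial(total, true f);
#' the observed frequency is alt/total (NA at total depth 0). A synthetic
#' phred-like QUAL increasing with alternate depth is populated so that
#' quality filters are exercised downstream.
#'
#' @param variants Variant table with a `true_f` column.
#' @param depth Mean sequencing depth (> 0).
#' @param ploidy_pi Unused scale hook, kept for interface symmetry.
#' @param seed Integer seed.
#' @return Variant table with `depth`, `alt_depth`, `freq`, `qual` filled.
#' @export
attach_sequencing_noise <- function(variants, depth, ploidy_pi = 2L,
                                    seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  n <- nrow(variants)
  total <- rpois(n, depth)
  alt <- rbinom(n, total, variants$true_f)
  variants$depth <- total
  variants$alt_depth <- alt
  variants$freq <- ifelse(total > 0, alt / total, NA_real_)
  variants$qual <- round(pmin(60, 25 + 3 * sqrt(pmax(alt, 0))), 1)
  variants
}
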