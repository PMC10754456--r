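# Frequency-resolved dN/dS against a codon-opportunity baseline.
#
# The raw nonsynonymous/synonymous count ratio in a window is normalized
# by the genome-wide opportunity ratio (possible nonsynonymous changes /
# possible synonymous changes over the coding sequence set), so that a
# neutral mutation process yields dN/dS = 1.

#' Enumerate synonymous/nonsynonymous opportunities of a CDS set
#'
#' Coding sequences are dropped unless they start with ATG, end with a
#' stop codon, contain no internal stop, and have length divisible by 3.
#' Every codon type is exploded into its 9 single-base changes under the
#' standard genetic code; changes into a stop count as nonsynonymous, and
#' stop codons themselves contribute no opportunities (mutations out of a
#' stop are not part of the somatic SNV universe considered here).
#'
#' @param cds Character vector of CDS sequences, a `Biostrings`
#'   DNAStringSet, or a FASTA path.
#' @return List of class `opportunity_table`: `codon_counts`, `per_codon`
#'   (data frame codon/syn/nonsyn, syn + nonsyn = 9), `syn_total`,
#'   `nonsyn_total`, `baseline` (= nonsyn_total / syn_total), and
#'   `n_dropped`.
#' @export
codon_opportunities <- function(cds) {
  if (is.character(cds) && length(cds) == 1 && file.exists(cds)) {
    cds <- as.character(Biostrings::readDNAStringSet(cds))
  }
  cds <- toupper(as.character(cds))
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  valid <- vapply(cds, function(s) {
    n <- nchar(s)
    if (n %% 3 != 0 || n < 6) return(FALSE)
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    if (codons[1] != "ATG") return(FALSE)
    if (!(codons[length(codons)] %in% stops)) return(FALSE)
    if (any(codons[-length(codons)] %in% stops)) return(FALSE)
    if (any(!codons %in% names(code))) return(FALSE)
    TRUE
  }, logical(1))
  n_dropped <- sum(!valid)
  cds <- cds[valid]
  if (length(cds) == 0) stop("no valid coding sequences after filtering")

  codons_all <- unlist(lapply(cds, function(s) {
    n <- nchar(s)
    cod <- substring(s, seq(1, n, 3), seq(3, n, 3))
    cod[!(cod %in% stops)] # stop codons contribute no opportunities
  }))
  codon_counts <- table(codons_all)

  per <- codon_change_table()
  idx <- match(names(codon_counts), per$codon)
  syn_total <- sum(codon_counts * per$syn[idx])
  nonsyn_total <- sum(codon_counts * per$nonsyn[idx])
  if (syn_total == 0) stop("no synonymous opportunities: baseline undefined")
  structure(list(
    codon_counts = codon_counts, per_codon = per,
    syn_total = unname(syn_total), nonsyn_total = unname(nonsyn_total),
    baseline = unname(nonsyn_total / syn_total), n_dropped = n_dropped
  ), class = "opportunity_table")
}

#' Per-codon-type synonymous/nonsynonymous change counts
#'
#' Enumerates the 9 single-base changes of every codon under the standard
#' genetic code (stopgain counts as nonsynonymous).
#'
#' @return Data frame: codon, syn, nonsyn (syn + nonsyn = 9).
#' @export
codon_change_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  syn <- nonsyn <- integer(length(codons))
  for (i in seq_along(codons)) {
    cod <- codons[i]
    aa <- code[[cod]]
    for (p in 1:3) {
      for (b in setdiff(SBS_BASES, substr(cod, p, p))) {
        new <- cod
        substr(new, p, p) <- b
        if (code[[new]] == aa) syn[i] <- syn[i] + 1L else
          nonsyn[i] <- nonsyn[i] + 1L
      }
    }
  }
  data.frame(codon = codons, syn = syn, nonsyn = nonsyn,
             stringsAsFactors = FALSE)
}

#' Longitudinal dN/dS along the inverse-allele-frequency axis
#'
#' Sliding windows on u = 1/f; per window the raw nonsyn/syn count ratio
#' is divided by the opportunity baseline. Windows without synonymous
#' mutations, or with fewer than `min_mutations` coding mutations, are
#' masked (NA), not infinite. Uncertainty comes from bootstrap resampling
#' of the mutations inside each window; the series is smoothed by a
#' running median (window 5) followed by a moving average (window 3).
#'
#' @param records Variant table with `freq` and `effect` columns
#'   (stopgain counts as nonsynonymous; noncoding/unknown are ignored).
#' @param baseline Opportunity baseline, or an `opportunity_table`.
#' @param window_halfwidth Half-width of the sliding window on u.
#' @param B Bootstrap replicates.
#' @param min_mutations Minimum coding mutations for an estimate.
#' @param step Spacing of window centres on u.
#' @param seed Integer seed.
#' @return Data frame of class `dnds_series`: u_center, n_nonsyn, n_syn,
#'   dnds (normalized), ci_lo, ci_hi, dnds_smooth.
#' @export
dnds_longitudinal <- function(records, baseline, window_halfwidth = 1,
                              B = 500, min_mutations = 20, step = 0.5,
                              seed = 1) {
  if (inherits(baseline, "opportunity_table")) baseline <- baseline$baseline
  stopifnot(baseline > 0)
  eff <- records$effect
  coding <- eff %in% c("syn", "nonsyn", "stopgain")
  u <- 1 / records$freq[coding]
  is_n <- eff[coding] %in% c("nonsyn", "stopgain")
  if (!any(!is_n)) stop("no synonymous mutations: baseline ratio undefined")
  if (!any(is_n)) stop("no nonsynonymous mutations in input")
  set.seed(seed)
  centers <- seq(floor(min(u) / step) * step, max(u), by = step)
  rows <- lapply(centers, function(cc) {
    inw <- which(abs(u - cc) <= window_halfwidth)
    nN <- sum(is_n[inw]); nS <- sum(!is_n[inw])
    if (length(inw) < min_mutations || nS == 0) {
      return(data.frame(u_center = cc, n_nonsyn = nN, n_syn = nS,
                        dnds = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    }
    est <- (nN / nS) / baseline
    boot <- vapply(seq_len(B), function(b) {
      lab <- is_n[inw][sample.int(length(inw), length(inw), replace = TRUE)]
      bS <- sum(!lab)
      if (bS == 0) NA_real_ else (sum(lab) / bS) / baseline
    }, numeric(1))
    ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE)
    data.frame(u_center = cc, n_nonsyn = nN, n_syn = nS, dnds = est,
               ci_lo = unname(ci[1]), ci_hi = unname(ci[2]))
  })
  out <- do.call(rbind, rows)
  out$dnds_smooth <- smooth_series(out$dnds)
  class(out) <- c("dnds_series", "data.frame")
  out
}

# running median (5) then centred moving average (3), NA-tolerant
smooth_series <- function(v) {
  ok <- !is.na(v)
  if (sum(ok) < 5) return(v)
  sm <- v
  sm[ok] <- runmed(v[ok], k = min(5, sum(ok) - (sum(ok) + 1) %% 2))
  ma <- sm
  for (i in seq_along(sm)) {
    w <- sm[max(1, i - 1):min(length(sm), i + 1)]
    ma[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  ma
}
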