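test_that("per-codon opportunities match direct enumeration", {
  tab <- codon_change_table()
  expect_true(all(tab$syn + tab$nonsyn == 9))
  expect_equal(tab$syn[tab$codon == "TTT"], 1L) # only TTT->TTC is silent
  expect_equal(tab$nonsyn[tab$codon == "TTT"], 8L)
  expect_equal(tab$syn[tab$codon == "ATG"], 0L)
  expect_equal(tab$nonsyn[tab$codon == "ATG"], 9L)
})

test_that("CDS validation drops malformed sequences", {
  opp <- codon_opportunities(c("ATGTTTTAA", "CCCTTTTAA", "ATGTT"))
  expect_equal(opp$n_dropped, 2L)
  # codons counted: ATG, TTT (the stop contributes no opportunities)
  expect_equal(sort(names(opp$codon_counts)), c("ATG", "TTT"))
  expect_equal(opp$syn_total, 1)
  expect_equal(opp$nonsyn_total, 17)
  expect_equal(opp$baseline, 17)
  expect_error(codon_opportunities("CCCTTT"), "no valid coding")
})

test_that("the FASTA baseline agrees with a brute-force mutation scan", {
  path <- system.file("extdata", "toy_cds.fa", package = "clonechron")
  opp <- codon_opportunities(path)
  expect_equal(opp$n_dropped, 1L) # the no-ATG record
  # oracle: mutate every non-stop-codon position of every valid CDS
  code <- Biostrings::GENETIC_CODE
  seqs <- c("ATGTTTACCGGATAA", "ATGGCTAAACTGTGTTAG")
  syn <- nonsyn <- 0
  for (s in seqs) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    codons <- codons[code[codons] != "*"]
    for (cod in codons) {
      for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                       substr(cod, p, p))) {
        new <- cod
        substr(new, p, p) <- b
        if (code[[new]] == code[[cod]]) syn <- syn + 1 else
          nonsyn <- nonsyn + 1
      }
    }
  }
  expect_equal(opp$syn_total, syn)
  expect_equal(opp$nonsyn_total, nonsyn)
  expect_equal(opp$baseline, nonsyn / syn)
})

test_that("windowed dN/dS normalizes by the baseline and masks bare windows", {
  # one window: 4 nonsyn, 2 syn, baseline 2 -> raw 2, normalized 1
  rec <- toy_variants(rep(0.5, 30))
  rec$effect <- rep(c("nonsyn", "nonsyn", "syn"), 10)
  out <- dnds_longitudinal(rec, baseline = 2, window_halfwidth = 1, B = 200,
                           min_mutations = 5)
  w <- out[out$u_center == 2, ]
  expect_equal(w$dnds, 1)
  expect_equal(w$n_nonsyn, 20)
  expect_equal(w$n_syn, 10)
  # scale equivariance: tripling every mutation leaves the ratio unchanged
  rec3 <- rec[rep(seq_len(nrow(rec)), 3), ]
  out3 <- dnds_longitudinal(rec3, baseline = 2, window_halfwidth = 1,
                            B = 200, min_mutations = 5)
  expect_equal(out3$dnds[out3$u_center == 2], 1)

  rec$effect <- rep("nonsyn", 30)
  expect_error(dnds_longitudinal(rec, 2), "no synonymous")
})

test_that("neutral labels give dN/dS compatible with unity", {
  set.seed(31)
  n <- 8000
  est <- do.call(rbind, lapply(1:2, function(r) {
    rec <- toy_variants(1 / runif(n, 2, 22))
    rec$effect <- ifelse(runif(n) < 0.75, "nonsyn", "syn") # baseline 3
    out <- dnds_longitudinal(rec, baseline = 3, B = 300, seed = r)
    out[!is.na(out$dnds), ]
  }))
  cover <- mean(est$ci_lo <= 1 & est$ci_hi >= 1)
  expect_gte(cover, 0.9)
})

test_that("purifying selection pushes dN/dS below one", {
  set.seed(32)
  n <- 6000
  u <- runif(n, 2, 12)
  # nonsynonymous mutations thinned by s = 0.5: odds 1.5 : 1
  rec <- toy_variants(1 / u)
  rec$effect <- ifelse(runif(n) < 0.6, "nonsyn", "syn")
  out <- dnds_longitudinal(rec, baseline = 3, B = 300, seed = 3)
  est <- out[!is.na(out$dnds), ]
  expect_true(all(est$dnds < 1))
  expect_gte(mean(est$ci_hi < 1), 0.9)
})
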