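# Reading, filtering and annotating variant tables.
#
# Coordinates are 1-based fully closed throughout, as in VCF. The observed
# allele frequency f = alt_depth / depth is the quantity obtained after
# sequencing and SNP calling; it is computed from AD-style depths when
# available and taken from an AF field otherwise.

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "qual", "depth",
                     "alt_depth", "freq", "context", "effect")

#' Variant filter thresholds
#'
#' Defaults follow the standard accumulation-curve filter: QUAL >= 30,
#' depth >= 10, alternate-allele depth >= 3, no upper depth cutoff. A
#' stricter profile (qual >= 35, 50 <= depth <= 200) is appropriate for
#' mutation-rate lower bounds, where high-coverage repeat regions
#' (depth >= 200) show an altered SNP distribution and are excluded.
#'
#' @param min_qual,min_depth,max_depth,min_alt_depth Thresholds; use `-Inf`
#'   / `Inf` to disable.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(min_qual = 30, min_depth = 10, max_depth = Inf,
                        min_alt_depth = 3) {
  if (min_depth > max_depth) stop("min_depth exceeds max_depth")
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_depth = max_depth, min_alt_depth = min_alt_depth),
            class = "filter_spec")
}

#' Apply quality/depth filters to a variant table
#'
#' @param records Variant table (data frame with qual, depth, alt_depth).
#' @param spec A [filter_spec()].
#' @return Filtered table; attribute `"filter_counts"` reports how many
#'   records each criterion dropped (evaluated independently) and the
#'   kept total.
#' @export
apply_filters <- function(records, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  ok_qual <- !is.na(records$qual) & records$qual >= spec$min_qual
  ok_dmin <- !is.na(records$depth) & records$depth >= spec$min_depth
  ok_dmax <- !is.na(records$depth) & records$depth <= spec$max_depth
  ok_alt <- !is.na(records$alt_depth) & records$alt_depth >= spec$min_alt_depth
  if (is.infinite(spec$min_qual)) ok_qual <- rep(TRUE, nrow(records))
  if (is.infinite(spec$max_depth)) ok_dmax[is.na(records$depth)] <- TRUE
  keep <- ok_qual & ok_dmin & ok_dmax & ok_alt
  if (spec$min_depth <= 0 && is.infinite(spec$max_depth) &&
      spec$min_alt_depth <= 0 && is.infinite(spec$min_qual)) {
    keep <- rep(TRUE, nrow(records))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    n_in = nrow(records), n_kept = sum(keep),
    dropped_qual = sum(!ok_qual), dropped_min_depth = sum(!ok_dmin),
    dropped_max_depth = sum(!ok_dmax), dropped_alt_depth = sum(!ok_alt)
  )
  out
}

#' Read a variant table from VCF or TSV
#'
#' VCF input (via the vcfR package) keeps biallelic SNVs, splits
#' multiallelic sites into one record per alternate allele, and skips
#' non-SNV alleles (the skipped count is attached as attribute
#' `"n_skipped"`). Depths are taken from INFO fields `TCN`/`ACN` (as
#' written by [write_variants()]), else from the first sample's `AD`;
#' the frequency falls back to INFO `AF` when no depths are present.
#' TSV input requires columns chrom, pos, ref, alt, qual, depth,
#' alt_depth (context, effect optional).
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return Variant table data frame.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "qual", "depth", "alt_depth")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("TSV variant table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(df$pos) | df$pos < 1)
  if (length(bad)) {
    stop("malformed variant row at line ", bad[1] + 1L, " (bad pos)")
  }
  if (is.null(df$freq)) df$freq <- df$alt_depth / df$depth
  if (is.null(df$context)) df$context <- NA_character_
  if (is.null(df$effect)) df$effect <- NA_character_
  df
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_variant_table()[, VARIANT_COLUMNS])
  info_field <- function(key) {
    suppressWarnings(vcfR::extract.info(v, element = key))
  }
  has_gt <- !is.null(v@gt) && ncol(v@gt) >= 2
  ad <- if (has_gt && "AD" %in% unlist(strsplit(v@gt[1, "FORMAT"], ":"))) {
    vcfR::extract.gt(v, element = "AD")[, 1]
  } else NULL

  rows <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- fix$REF[i]
    ads <- if (!is.null(ad) && !is.na(ad[i])) {
      as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]])
    } else NULL
    for (j in seq_along(alts)) {
      a <- alts[j]
      if (nchar(ref) != 1 || nchar(a) != 1 ||
          !(ref %in% SBS_BASES) || !(a %in% SBS_BASES)) {
        n_skipped <- n_skipped + 1L
        next
      }
      tcn <- suppressWarnings(as.numeric(info_field("TCN")[i]))
      acn <- suppressWarnings(as.numeric(info_field("ACN")[i]))
      if (is.na(tcn) && !is.null(ads)) tcn <- sum(ads)
      if (is.na(acn) && !is.null(ads) && length(ads) >= j + 1) acn <- ads[j + 1]
      f <- if (!is.na(tcn) && !is.na(acn) && tcn > 0) acn / tcn else
        suppressWarnings(as.numeric(info_field("AF")[i]))
      ctx <- info_field("CTX")[i]
      eff <- info_field("EFF")[i]
      tf <- suppressWarnings(as.numeric(info_field("TRUEF")[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = ref,
        alt = a, qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        depth = as.integer(tcn), alt_depth = as.integer(acn),
        freq = f, context = if (is.null(ctx)) NA_character_ else ctx,
        effect = if (is.null(eff)) NA_character_ else eff,
        true_f = tf, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_variant_table()[, c(VARIANT_COLUMNS, "true_f")]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a variant table as TSV or VCF 4.3
#'
#' The VCF writer emits INFO fields `TCN` (total depth), `ACN` (alternate
#' depth), `CTX` (trinucleotide channel), `EFF` (coding effect) and
#' `TRUEF` (true simulated frequency, when present).
#'
#' @param variants Variant table.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    keep <- intersect(c(VARIANT_COLUMNS, "true_f", "de_novo"),
                      names(variants))
    write.table(variants[, keep, drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.3",
    "##source=clonechron",
    "##INFO=<ID=TCN,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=ACN,Number=1,Type=Integer,Description=\"Alternate allele read depth\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Trinucleotide substitution channel\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect: syn|nonsyn|stopgain|noncoding|unknown\">",
    "##INFO=<ID=TRUEF,Number=1,Type=Float,Description=\"True simulated allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt_info <- function(i) {
    parts <- c(
      if (!is.na(variants$depth[i])) paste0("TCN=", variants$depth[i]),
      if (!is.na(variants$alt_depth[i])) paste0("ACN=", variants$alt_depth[i]),
      if (!is.na(variants$context[i])) paste0("CTX=", variants$context[i]),
      if (!is.na(variants$effect[i])) paste0("EFF=", variants$effect[i]),
      if (!is.null(variants$true_f) && !is.na(variants$true_f[i])) {
        paste0("TRUEF=", format(variants$true_f[i], digits = 10))
      }
    )
    if (length(parts)) paste(parts, collapse = ";") else "."
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
          variants$alt[i],
          ifelse(is.na(variants$qual[i]), ".", variants$qual[i]),
          "PASS", fmt_info(i), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Toy coding model for effect annotation
#'
#' A coding model is a set of forward-strand CDS placed on a genome:
#' each entry has a chromosome, a 1-based start, and an in-frame sequence.
#'
#' @param chrom Character vector of chromosomes.
#' @param start Integer vector of CDS start positions (1-based).
#' @param seq Character vector of CDS sequences (A/C/G/T, length divisible
#'   by 3).
#' @return Object of class `coding_model`.
#' @export
coding_model <- function(chrom, start, seq) {
  stopifnot(length(chrom) == length(start), length(start) == length(seq))
  if (any(nchar(seq) %% 3 != 0)) {
    stop("CDS length not a multiple of 3: coding model invalid")
  }
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(start) + nchar(seq) - 1L, seq = seq),
            class = "coding_model")
}

#' Annotate coding effects of single-base substitutions
#'
#' Positions inside a CDS of the model are classified by mutating the
#' containing codon and translating under the standard genetic code:
#' `syn` if the amino acid is unchanged, `stopgain` if the new codon is a
#' stop, otherwise `nonsyn`; positions outside every CDS are `noncoding`.
#' Records carrying a non-missing `effect` keep it (precomputed labels,
#' e.g. splice annotations, override the toy annotator).
#'
#' @param records Variant table.
#' @param model A [coding_model()].
#' @return The table with its `effect` column filled.
#' @export
annotate_effect <- function(records, model) {
  stopifnot(inherits(model, "coding_model"))
  code <- Biostrings::GENETIC_CODE
  eff <- if (is.null(records$effect)) rep(NA_character_, nrow(records)) else
    records$effect
  todo <- which(is.na(eff) | eff == "unknown")
  for (i in todo) {
    hit <- which(model$chrom == records$chrom[i] &
                   model$start <= records$pos[i] &
                   model$end >= records$pos[i])
    if (length(hit) == 0) { eff[i] <- "noncoding"; next }
    h <- hit[1]
    off <- records$pos[i] - model$start[h] # 0-based offset in CDS
    codon_i <- off %/% 3
    within <- off %% 3
    codon <- substr(model$seq[h], codon_i * 3 + 1, codon_i * 3 + 3)
    new_codon <- codon
    substr(new_codon, within + 1, within + 1) <- records$alt[i]
    aa_old <- code[[codon]]
    aa_new <- code[[new_codon]]
    eff[i] <- if (aa_new == aa_old) "syn" else if (aa_new == "*") "stopgain"
      else "nonsyn"
  }
  records$effect <- eff
  records
}
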