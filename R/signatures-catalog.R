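# 96-channel single-base-substitution conventions (COSMIC ordering) and
# catalog handling.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
SBS_BASES <- c("A", "C", "G", "T")

#' Canonical 96 trinucleotide substitution channels
#'
#' Pyrimidine-centred channels in COSMIC order: substitutions
#' C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the sixteen
#' 5'/3' flanking-base combinations (A, C, G, T), labelled e.g.
#' `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  out <- character(0)
  for (sub in SBS_SUBSTITUTIONS) {
    for (five in SBS_BASES) {
      for (three in SBS_BASES) {
        out <- c(out, paste0(five, "[", sub, "]", three))
      }
    }
  }
  out
}

#' Collapse a substitution with context to its pyrimidine-centred channel
#'
#' Substitutions at purine reference bases are reverse-complemented so that
#' the central base is C or T (the COSMIC convention).
#'
#' @param ref,alt Single reference/alternate bases.
#' @param fiveprime,threeprime Flanking bases.
#' @return Channel label such as `"A[C>T]G"`.
#' @export
sbs_channel <- function(ref, alt, fiveprime, threeprime) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  stopifnot(length(ref) == length(alt))
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  f5 <- ifelse(flip, comp[threeprime], fiveprime)
  f3 <- ifelse(flip, comp[fiveprime], threeprime)
  ch <- paste0(f5, "[", r, ">", a, "]", f3)
  bad <- !(ch %in% sbs_channels())
  if (any(bad)) stop("invalid substitution/context: ", ch[bad][1])
  ch
}

#' Synthetic signature catalog for tests and simulations
#'
#' Builds a deterministic 96 x 3 catalog with columns `SBS1` (synthetic
#' clock-like profile concentrated on N\[C>T\]G channels, mimicking CpG
#' deamination), `SBS5` (synthetic broad, flat-ish clock-like profile with
#' a mild T>C tilt) and `FLAT` (uniform). The profiles are *synthetic*
#' stand-ins with the qualitative structure of their COSMIC namesakes, not
#' copies of COSMIC data; columns sum to 1.
#'
#' @return Numeric matrix, 96 rows (named by [sbs_channels()]) x 3 columns.
#' @export
synthetic_signature_catalog <- function() {
  ch <- sbs_channels()
  n <- length(ch)
  sub <- sub("^.\\[(.+)\\].$", "\\1", ch)
  three <- sub("^.\\[.+\\](.)$", "\\1", ch)

  sbs1 <- rep(0.0005, n)
  sbs1[sub == "C>T"] <- 0.004
  sbs1[sub == "C>T" & three == "G"] <- 0.22
  sbs1 <- sbs1 / sum(sbs1)

  # broad profile: smooth deterministic ripple, mild T>C excess
  ripple <- 1 + 0.4 * sin(seq_len(n) / 7)
  sbs5 <- ripple
  sbs5[sub == "T>C"] <- sbs5[sub == "T>C"] * 2.0
  sbs5[sub == "C>T"] <- sbs5[sub == "C>T"] * 1.4
  sbs5 <- sbs5 / sum(sbs5)

  flat <- rep(1 / n, n)

  out <- cbind(SBS1 = sbs1, SBS5 = sbs5, FLAT = flat)
  rownames(out) <- ch
  out
}

#' Read a COSMIC-style signature catalog
#'
#' Expects a TSV with a channel-label column (first column or one named
#' `Type`/`Channel`/`MutationType`) holding the 96 trinucleotide channels,
#' and one numeric column per signature. Rows are reordered to the
#' canonical channel order; columns whose sums deviate from 1 by at most
#' 1e-2 are renormalized.
#'
#' @param path TSV file path.
#' @return 96 x S numeric matrix with channel rownames.
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  label_col <- intersect(c("Type", "Channel", "MutationType"), names(df))
  label_col <- if (length(label_col)) label_col[1] else names(df)[1]
  labels <- as.character(df[[label_col]])
  mat <- as.matrix(df[, setdiff(names(df), label_col), drop = FALSE])
  storage.mode(mat) <- "double"
  if (nrow(mat) != 96) {
    stop("signature catalog must have 96 channel rows, found ", nrow(mat))
  }
  if (any(mat < 0)) stop("signature catalog contains negative entries")
  canon <- sbs_channels()
  if (!setequal(labels, canon)) {
    stop("catalog channel labels do not match the canonical 96 channels")
  }
  mat <- mat[match(canon, labels), , drop = FALSE]
  rownames(mat) <- canon
  sums <- colSums(mat)
  off <- abs(sums - 1) > 1e-2
  if (any(off)) {
    stop(
      "signature column(s) ", paste(colnames(mat)[off], collapse = ", "),
      " do not sum to 1 (tolerance 1e-2)"
    )
  }
  sweep(mat, 2, sums, "/")
}

#' Write a signature catalog as TSV
#'
#' @param catalog 96 x S matrix as from [read_signature_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(Type = rownames(catalog), catalog, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
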