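## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

## alignment rows as a character matrix (taxa x columns)
.charMatrix <- function(seqs) {
  m <- t(vapply(strsplit(as.character(seqs), "", fixed = TRUE),
                identity, character(Biostrings::width(seqs)[1L])))
  rownames(m) <- names(seqs)
  m
}

.isResolved <- function(ch) ch %in% .BASES

## round half away from zero, for 1-decimal percentage reporting
.round1 <- function(x) {
  ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) * 10 + 0.5) / 10)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

## expand an IUPAC character into its base set (gap -> character(0))
.iupacBases <- function(ch) {
  if (ch %in% .BASES) return(ch)
  if (ch %in% names(Biostrings::IUPAC_CODE_MAP))
    return(strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "", fixed = TRUE)[[1L]])
  character(0)
}

## IUPAC code for a base set (e.g. c("A","G") -> "R")
.iupacCode <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(Biostrings::IUPAC_CODE_MAP)[
    vapply(Biostrings::IUPAC_CODE_MAP,
           function(s) paste(sort(strsplit(s, "", fixed = TRUE)[[1L]]),
                             collapse = "") == key,
           logical(1L))]
  if (length(hit) != 1L)
    stop("no IUPAC code for base set {", paste(bases, collapse = ","), "}")
  hit
}

.stopCodons <- c("TAA", "TAG", "TGA")

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}
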