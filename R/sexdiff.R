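## Male-specific variant detection, gametolog splitting, ORF integrity.

#' Read a sexed genotype panel from FASTA
#'
#' Headers carry pipe-separated fields, e.g. `>ind01|sex=M` or
#' `>locus|sex=F|id=f2`; the `sex=` field is required, the `id=` field
#' defaults to the first header token.
#'
#' @param path FASTA path (aligned, IUPAC ambiguity codes allowed).
#' @param locusId locus identifier; defaults to file name without extension.
#' @return a [GenotypePanel-class].
#' @export
readGenotypePanel <- function(path, locusId = NULL) {
  if (is.null(locusId))
    locusId <- sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  heads <- names(seqs)
  parts <- strsplit(heads, "|", fixed = TRUE)
  getField <- function(p, key, default = NA_character_) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else default
  }
  sex <- vapply(parts, getField, character(1L), key = "sex")
  ids <- vapply(parts, function(p) getField(p, "id", p[[1L]]), character(1L))
  if (anyNA(sex))
    stop("every FASTA header must carry a 'sex=' field")
  names(seqs) <- ids
  GenotypePanel(locusId, seqs, sex)
}

.panelMatrices <- function(panel, minMales, minFemales) {
  m <- .charMatrix(alignedSeqs(panel))
  males <- m[panel@sex == "M", , drop = FALSE]
  females <- m[panel@sex == "F", , drop = FALSE]
  if (nrow(males) < minMales || nrow(females) < minFemales)
    stop("panel must contain at least ", minMales, " males and ",
         minFemales, " females for calling")
  list(males = males, females = females)
}

## variant allele supported by one male character given the female base;
## NA = no variant, "" = unclassifiable
.maleVariant <- function(ch, femaleBase) {
  if (ch == femaleBase) return(NA_character_)
  if (ch %in% .BASES) return(ch)            # hemizygous-style signature
  bs <- .iupacBases(ch)
  if (length(bs) == 2L && femaleBase %in% bs)
    return(setdiff(bs, femaleBase))         # heterozygous IUPAC signature
  ""
}

#' Detect male-specific substitutions
#'
#' A position is called male-specific when every male shows a signature
#' consistent with one shared variant allele -- a two-base IUPAC code
#' containing the female base, or the plain variant base (one gametolog can
#' amplify preferentially) -- and every female shows the same homozygous
#' base with no ambiguity code.  Such variants are diagnostic of a diverged
#' neo-Y allele: the female base is the neo-X allele, the male-shared
#' variant the neo-Y allele.  Positions where males support conflicting
#' variant alleles are reported in the `"unclassified"` attribute, not
#' called.
#'
#' @param panel a [GenotypePanel-class].
#' @param minMales,minFemales minimum panel sizes accepted for calling.
#' @param maleSupportFraction fraction of males that must support the
#'   variant (default 1: every male; lower only for error-tolerant scans).
#' @return a `data.frame` of calls (`locus`, `pos0` 0-based, `kind`,
#'   `neoX`, `neoY`, `nMales`, `nFemales`) with attribute `"unclassified"`
#'   (0-based positions of polymorphic-unclassified sites).
#' @export
detectMaleSpecific <- function(panel, minMales = 2L, minFemales = 1L,
                               maleSupportFraction = 1) {
  pm <- .panelMatrices(panel, minMales, minFemales)
  males <- pm$males; females <- pm$females
  nM <- nrow(males); nF <- nrow(females)
  calls <- list(); unclassified <- integer(0)
  for (j in seq_len(ncol(males))) {
    f <- females[, j]
    if (!all(f %in% .BASES)) next          # female gap/N/ambiguity: rejected
    if (length(unique(f)) != 1L) next      # female polymorphism: rejected
    x <- f[1L]
    mv <- vapply(males[, j], .maleVariant, character(1L), femaleBase = x)
    if (any(males[, j] == "-")) next       # length variants handled separately
    if (all(is.na(mv))) next               # no variant anywhere
    if (any(!is.na(mv) & mv == "")) { unclassified <- c(unclassified, j - 1L); next }
    support <- sum(!is.na(mv))
    if (support / nM < maleSupportFraction) next
    v <- unique(mv[!is.na(mv)])
    if (length(v) != 1L) { unclassified <- c(unclassified, j - 1L); next }
    calls[[length(calls) + 1L]] <- data.frame(
      locus = locusId(panel), pos0 = j - 1L, kind = "SNV",
      neoX = x, neoY = v, nMales = nM, nFemales = nF,
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(locus = character(0), pos0 = integer(0), kind = character(0),
               neoX = character(0), neoY = character(0),
               nMales = integer(0), nFemales = integer(0),
               stringsAsFactors = FALSE)
  attr(out, "unclassified") <- unclassified
  out
}

#' Detect male-specific indels from gap signatures
#'
#' Length variants carried by the neo-Y appear in the aligned panel as gap
#' runs with opposite gap state between the sexes: a neo-Y deletion shows
#' gaps in every male and bases in every female; a neo-Y insertion shows
#' bases in every male at columns gapped in every female.  Maximal runs of
#' consistent columns become one indel call each; mixed gap states within a
#' sex are unclassified.
#'
#' @inheritParams detectMaleSpecific
#' @return a `data.frame` of calls (`kind = "indel"`, plus `length`),
#'   attribute `"unclassified"` as in [detectMaleSpecific()].
#' @export
detectMaleSpecificIndels <- function(panel, minMales = 2L, minFemales = 1L) {
  pm <- .panelMatrices(panel, minMales, minFemales)
  males <- pm$males; females <- pm$females
  nM <- nrow(males); nF <- nrow(females)
  type <- character(ncol(males)); unclassified <- integer(0)
  for (j in seq_len(ncol(males))) {
    mg <- males[, j] == "-"; fg <- females[, j] == "-"
    if (!any(mg) && !any(fg)) { type[j] <- "none"; next }
    if (all(mg) && all(fg)) { type[j] <- "pad"; next }
    if (all(mg) && !any(fg)) {
      if (length(unique(females[, j])) == 1L) type[j] <- "del"
      else { type[j] <- "bad"; unclassified <- c(unclassified, j - 1L) }
    } else if (!any(mg) && all(fg)) {
      if (length(unique(males[, j])) == 1L) type[j] <- "ins"
      else { type[j] <- "bad"; unclassified <- c(unclassified, j - 1L) }
    } else {
      type[j] <- "bad"; unclassified <- c(unclassified, j - 1L)
    }
  }
  calls <- list()
  r <- rle(type)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!(r$values[i] %in% c("del", "ins"))) next
    span <- starts[i]:ends[i]
    if (r$values[i] == "del") {
      neoX <- paste(females[1L, span], collapse = "")
      neoY <- strrep("-", length(span))
    } else {
      neoX <- strrep("-", length(span))
      neoY <- paste(males[1L, span], collapse = "")
    }
    calls[[length(calls) + 1L]] <- data.frame(
      locus = locusId(panel), pos0 = starts[i] - 1L, kind = "indel",
      length = length(span), neoX = neoX, neoY = neoY,
      nMales = nM, nFemales = nF, stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(locus = character(0), pos0 = integer(0), kind = character(0),
               length = integer(0), neoX = character(0), neoY = character(0),
               nMales = integer(0), nFemales = integer(0),
               stringsAsFactors = FALSE)
  attr(out, "unclassified") <- unclassified
  out
}

#' Split gametolog haplotypes according to a call set
#'
#' Imposes the called neo-X/neo-Y alleles on a pair of candidate gametolog
#' sequences (e.g. BAC-derived), verifying consistency: at every call
#' position at least one input must carry a call allele, and outside call
#' positions the two inputs must agree.  The returned haplotypes differ
#' exactly at the call positions.
#'
#' @param neoX,neoY candidate sequences (character or `DNAString`), equal
#'   length, aligned to the panel coordinate frame.
#' @param calls `data.frame` of calls from [detectMaleSpecific()] /
#'   [detectMaleSpecificIndels()].
#' @return a named `DNAStringSet` with rows `neoX` and `neoY`.
#' @export
splitGametologs <- function(neoX, neoY, calls) {
  hx <- strsplit(as.character(neoX), "", fixed = TRUE)[[1L]]
  hy <- strsplit(as.character(neoY), "", fixed = TRUE)[[1L]]
  if (length(hx) != length(hy))
    stop("identity error: gametolog sequences differ in length")
  callCols <- integer(0)
  if (nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      len <- if ("length" %in% colnames(calls) && calls$kind[i] == "indel")
        calls$length[i] else 1L
      span <- (calls$pos0[i] + 1L):(calls$pos0[i] + len)
      if (max(span) > length(hx))
        stop("consistency error: call outside sequence bounds")
      ax <- strsplit(calls$neoX[i], "", fixed = TRUE)[[1L]]
      ay <- strsplit(calls$neoY[i], "", fixed = TRUE)[[1L]]
      seen <- c(hx[span], hy[span])
      if (!any(c(ax, ay) %in% seen))
        stop("consistency error: call alleles absent from both inputs at ",
             "position ", calls$pos0[i])
      hx[span] <- ax; hy[span] <- ay
      callCols <- c(callCols, span)
    }
  }
  other <- setdiff(seq_along(hx), callCols)
  if (any(hx[other] != hy[other]))
    stop("consistency error: inputs differ outside call positions")
  out <- Biostrings::DNAStringSet(c(paste(hx, collapse = ""),
                                    paste(hy, collapse = "")))
  names(out) <- c("neoX", "neoY")
  out
}

#' Merge two haplotypes into a diploid IUPAC consensus
#'
#' Encodes a heterozygote the way a direct Sanger read of a neo-X/neo-Y
#' male does in this package's model: mismatching bases become the two-base
#' IUPAC code, and length-variant columns take the neo-Y gap state (the
#' length-polymorphism signature used by [detectMaleSpecificIndels()]).
#'
#' @param hapX,hapY haplotype sequences (character or `DNAString`), equal
#'   length, `hapY` supplying the gap state at length variants.
#' @return a character string.
#' @export
mergeHaplotypes <- function(hapX, hapY) {
  a <- strsplit(as.character(hapX), "", fixed = TRUE)[[1L]]
  b <- strsplit(as.character(hapY), "", fixed = TRUE)[[1L]]
  stopifnot(length(a) == length(b))
  out <- character(length(a))
  for (i in seq_along(a)) {
    out[i] <- if (a[i] == b[i]) a[i]
    else if (b[i] == "-") "-"
    else if (a[i] == "-") b[i]
    else .iupacCode(c(a[i], b[i]))
  }
  paste(out, collapse = "")
}

#' Audit open-reading-frame integrity of a gametolog sequence
#'
#' Flags frameshifts -- indel runs relative to the intact partner whose
#' length is not a multiple of 3 -- and premature stop codons found by
#' translating the degapped sequence in the declared frame.  An ORF is
#' intact iff it has neither.
#'
#' @param seq coding sequence (character or `DNAString`), gaps allowed when
#'   `reference` is given.
#' @param frame 0, 1 or 2: bases to skip before the first complete codon.
#' @param reference the aligned intact gametolog (same length as `seq`),
#'   or `NULL` to skip frameshift detection.
#' @param geneId,haplotype labels carried through to the report.
#' @return list with `geneId`, `haplotype`, `frameshiftPositions` (0-based
#'   alignment columns of frame-breaking indel runs), `prematureStopCodon`
#'   (1-based codon index or `NA`), `orfIntact`.
#' @export
orfIntegrity <- function(seq, frame = 0L, reference = NULL,
                         geneId = NA_character_, haplotype = NA_character_) {
  if (!(frame %in% 0:2))
    stop("parameter error: frame must be 0, 1 or 2")
  s <- strsplit(as.character(seq), "", fixed = TRUE)[[1L]]
  fsPos <- integer(0)
  if (!is.null(reference)) {
    r <- strsplit(as.character(reference), "", fixed = TRUE)[[1L]]
    if (length(r) != length(s))
      stop("identity error: sequence and reference differ in length")
    indel <- xor(s == "-", r == "-")
    runs <- rle(indel)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$values)) {
      if (runs$values[i] && runs$lengths[i] %% 3L != 0L)
        fsPos <- c(fsPos, starts[i] - 1L)
    }
  }
  bases <- s[s != "-"]
  if (length(bases) < 3L)
    stop("sequence must contain at least one codon after gap removal")
  if (frame > 0L) bases <- bases[-seq_len(frame)]
  nCodon <- length(bases) %/% 3L
  stopAt <- NA_integer_
  if (nCodon >= 2L) {
    codons <- vapply(seq_len(nCodon), function(k)
      paste(bases[(3L * k - 2L):(3L * k)], collapse = ""), character(1L))
    hit <- which(codons[-nCodon] %in% .stopCodons)
    if (length(hit)) stopAt <- hit[1L]
  }
  list(geneId = geneId, haplotype = haplotype,
       frameshiftPositions = fsPos, prematureStopCodon = stopAt,
       orfIntact = length(fsPos) == 0L && is.na(stopAt))
}
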