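## Parsimony direction assignment and Table-style spectrum construction.

.DIR_CATEGORIES <- c("A/T->G/C", "G/C->A/T", "A/T->C/G",
                     "C/G->A/T", "A/T->T/A", "G/C->C/G")

#' Classify a substitution into its strand-pooled direction category
#'
#' The 12 directed base changes pool into 6 categories by strand complement:
#' e.g. A->G and T->C are both A/T->G/C.  The map is invariant under
#' complementing both bases.
#'
#' @param ancestral,derived vectors of single bases (A/C/G/T), equal length.
#' @return character vector of categories (one of `"A/T->G/C"`,
#'   `"G/C->A/T"`, `"A/T->C/G"`, `"C/G->A/T"`, `"A/T->T/A"`, `"G/C->C/G"`).
#' @examples
#' classifyDirection("A", "G")  # "A/T->G/C"
#' @export
classifyDirection <- function(ancestral, derived) {
  if (length(ancestral) != length(derived))
    stop("ancestral and derived must have equal length")
  if (any(ancestral == derived))
    stop("classification error: ancestral and derived bases are equal")
  if (!all(.isResolved(ancestral)) || !all(.isResolved(derived)))
    stop("classification error: bases must be A, C, G or T")
  key <- paste0(ancestral, derived)
  map <- c(AG = "A/T->G/C", TC = "A/T->G/C",
           GA = "G/C->A/T", CT = "G/C->A/T",
           AC = "A/T->C/G", TG = "A/T->C/G",
           CA = "C/G->A/T", GT = "C/G->A/T",
           AT = "A/T->T/A", TA = "A/T->T/A",
           GC = "G/C->C/G", CG = "G/C->C/G")
  unname(map[key])
}

#' Assign a substitution to a lineage by 3-taxon parsimony
#'
#' Given the three resolved bases of one alignment column, the lineage whose
#' base differs from the base shared by the other two is inferred to carry a
#' substitution from the shared (ancestral) base to its own (derived) base.
#' Columns where all three bases agree are invariant; columns where all three
#' differ cannot be polarized and are excluded.
#'
#' @param bases character vector of 3 resolved bases, optionally named with
#'   taxon labels.
#' @return list with elements `status` (`"called"`, `"invariant"` or
#'   `"ambiguous_excluded"`), `lineage`, `ancestral`, `derived` (the last
#'   three `NA` unless called).
#' @examples
#' callSite3Taxon(c(tmu = "G", mouse = "A", rat = "A"))
#' @export
callSite3Taxon <- function(bases) {
  if (length(bases) != 3L || !all(.isResolved(bases)))
    stop("precondition error: need 3 resolved bases (A/C/G/T)")
  labels <- if (is.null(names(bases))) as.character(1:3) else names(bases)
  u <- unique(bases)
  if (length(u) == 1L)
    return(list(status = "invariant", lineage = NA_character_,
                ancestral = NA_character_, derived = NA_character_))
  if (length(u) == 3L)
    return(list(status = "ambiguous_excluded", lineage = NA_character_,
                ancestral = NA_character_, derived = NA_character_))
  tab <- table(bases)
  odd <- names(tab)[tab == 1L]
  shared <- names(tab)[tab == 2L]
  i <- which(bases == odd)
  list(status = "called", lineage = labels[i],
       ancestral = shared, derived = odd)
}

#' Assign a substitution by 4-taxon Fitch parsimony with an outgroup
#'
#' Exhaustive Fitch parsimony on the fixed unrooted topology
#' `((t1, t2), t3, t4)` with `t4` the outgroup.  All 16 internal-state
#' assignments are scored; a substitution is called only when every
#' most-parsimonious reconstruction places exactly one change on the same
#' terminal branch with the same ancestral and derived states.  Changes whose
#' most-parsimonious placement is on the internal branch, or ambiguous, are
#' excluded.  A unique placement on the outgroup terminal is returned with
#' `lineage` equal to the outgroup label; spectrum construction ignores it.
#'
#' @param bases character vector of 4 resolved bases, ordered
#'   `(t1, t2, t3, outgroup)`, optionally named.
#' @return list as in [callSite3Taxon()].
#' @examples
#' callSite4Taxon(c(tmu = "G", mouse = "A", rat = "A", gpig = "A"))
#' @export
callSite4Taxon <- function(bases) {
  if (length(bases) != 4L || !all(.isResolved(bases)))
    stop("precondition error: need 4 resolved bases (A/C/G/T)")
  labels <- if (is.null(names(bases))) as.character(1:4) else names(bases)
  if (length(unique(bases)) == 1L)
    return(list(status = "invariant", lineage = NA_character_,
                ancestral = NA_character_, derived = NA_character_))
  ## internal nodes: a joins (t1, t2); b joins (a, t3, t4); root at b
  best <- Inf; sols <- list()
  for (a in .BASES) for (b in .BASES) {
    sc <- (a != bases[1L]) + (a != bases[2L]) + (a != b) +
          (b != bases[3L]) + (b != bases[4L])
    if (sc > best) next
    chg <- list()
    if (a != bases[1L]) chg[[length(chg) + 1L]] <- c("t1", a, bases[1L])
    if (a != bases[2L]) chg[[length(chg) + 1L]] <- c("t2", a, bases[2L])
    if (b != a)         chg[[length(chg) + 1L]] <- c("internal", b, a)
    if (b != bases[3L]) chg[[length(chg) + 1L]] <- c("t3", b, bases[3L])
    if (b != bases[4L]) chg[[length(chg) + 1L]] <- c("t4", b, bases[4L])
    if (sc < best) { best <- sc; sols <- list(chg) }
    else sols[[length(sols) + 1L]] <- chg
  }
  single <- vapply(sols, length, integer(1L)) == 1L
  if (!all(single))
    return(list(status = "ambiguous_excluded", lineage = NA_character_,
                ancestral = NA_character_, derived = NA_character_))
  placements <- unique(vapply(sols, function(s) paste(s[[1L]], collapse = ""),
                              character(1L)))
  if (length(placements) != 1L || sols[[1L]][[1L]][1L] == "internal")
    return(list(status = "ambiguous_excluded", lineage = NA_character_,
                ancestral = NA_character_, derived = NA_character_))
  hit <- sols[[1L]][[1L]]
  idx <- match(hit[1L], c("t1", "t2", "t3", "t4"))
  list(status = "called", lineage = labels[idx],
       ancestral = hit[2L], derived = hit[3L])
}

## ---- vectorized engines via exhaustive lookup -----------------------------

.lookupCache <- new.env(parent = emptyenv())

## lookup tables are generated by the scalar engines themselves, so the
## vectorized path is equivalent by construction
.spectrumLookup <- function(mode) {
  key <- mode
  if (!is.null(.lookupCache[[key]])) return(.lookupCache[[key]])
  k <- if (mode == "3taxon") 3L else 4L
  combos <- as.matrix(expand.grid(rep(list(1:4), k))[, k:1, drop = FALSE])
  n <- nrow(combos)
  status <- character(n); lineage <- integer(n)
  anc <- character(n); der <- character(n)
  for (i in seq_len(n)) {
    bs <- .BASES[combos[i, ]]
    res <- if (k == 3L) callSite3Taxon(bs) else callSite4Taxon(bs)
    status[i] <- res$status
    lineage[i] <- if (res$status == "called") as.integer(res$lineage) else NA_integer_
    anc[i] <- res$ancestral; der[i] <- res$derived
  }
  tab <- data.frame(status = status, lineage = lineage,
                    ancestral = anc, derived = der,
                    stringsAsFactors = FALSE)
  .lookupCache[[key]] <- tab
  tab
}

## call every resolved column of a base-code matrix (taxa x columns, codes
## 1..4); returns data.frame rows parallel to columns
.callColumns <- function(codes, mode) {
  k <- nrow(codes)
  lut <- .spectrumLookup(mode)
  idx <- rep(1L, ncol(codes))
  for (r in seq_len(k)) idx <- (idx - 1L) * 4L + codes[r, ]
  lut[idx, , drop = FALSE]
}

#' G+C fraction of one sequence at selected sites
#'
#' @param seq a character string, `DNAString`, or character vector of bases.
#' @param sites integer vector of 1-based site indices.
#' @return fraction of G or C bases among the selected sites.
#' @examples
#' gcContent("ATGC", 1:4)  # 0.5
#' @export
gcContent <- function(seq, sites) {
  if (length(sites) == 0L)
    stop("undefined-value error: empty site set")
  ch <- if (length(seq) == 1L && nchar(seq[1L]) > 1L)
    strsplit(as.character(seq), "", fixed = TRUE)[[1L]]
  else as.character(seq)
  sum(ch[sites] %in% c("G", "C")) / length(sites)
}

#' Build substitution-direction spectra
#'
#' Tallies parsimony-called substitutions per lineage into the six
#' strand-pooled direction categories, together with the number of analyzed
#' columns, contributing genes, and per-species G+C content.  One row is
#' produced per species per (region, site class) group -- and per gene when
#' `grouping = "per_gene"`.  Only columns that are unmasked and fully
#' resolved across the analyzed taxa are counted; invariant and
#' parsimony-ambiguous columns contribute to `nBases` but never to `nSubs`.
#'
#' @param x a [PartitionedAlignment-class] (typically a concatenation from
#'   [concatenateAlignments()], but any annotated alignment works).
#' @param mode `"3taxon"` (three ingroup species) or `"4taxon"` (with an
#'   outgroup as the fourth analyzed taxon).
#' @param grouping `"region_pooled"` or `"per_gene"`.
#' @param taxa analyzed taxa in topology order `(t1, t2, t3[, outgroup])`;
#'   defaults to the first 3 (or 4) alignment rows.
#' @return a `data.frame` with count (`n*`) and percentage (`pct*`) columns;
#'   percentages are of `nSubs` and are `NA` when `nSubs` is 0.
#' @export
buildSpectrum <- function(x, mode = c("3taxon", "4taxon"),
                          grouping = c("region_pooled", "per_gene"),
                          taxa = NULL) {
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  stopifnot(is(x, "PartitionedAlignment"))
  k <- if (mode == "3taxon") 3L else 4L
  if (is.null(taxa)) taxa <- taxaNames(x)[seq_len(k)]
  if (length(taxa) != k || !all(taxa %in% taxaNames(x)))
    stop("identity error: need ", k, " taxa present in the alignment")
  nSpecies <- 3L  # spectra are reported for the ingroup only

  m <- .charMatrix(alignedSeqs(x))[taxa, , drop = FALSE]
  ann <- x@columns
  usable <- !ann$masked
  resolved <- colSums(!matrix(.isResolved(m), nrow = k)) == 0L
  analyzed <- usable & resolved

  codes <- matrix(match(m, .BASES), nrow = k)
  calls <- data.frame(status = rep(NA_character_, ncol(m)),
                      lineage = NA_integer_, ancestral = NA_character_,
                      derived = NA_character_, stringsAsFactors = FALSE)
  if (any(analyzed))
    calls[analyzed, ] <- .callColumns(codes[, analyzed, drop = FALSE], mode)

  groupKey <- paste(ann$region, ann$siteClass, sep = "\r")
  if (grouping == "per_gene")
    groupKey <- paste(groupKey, ann$geneId, sep = "\r")

  rows <- list()
  for (g in unique(groupKey[analyzed])) {
    inG <- analyzed & groupKey == g
    idx <- which(inG)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    nBases <- length(idx)
    nGenes <- length(unique(ann$geneId[idx]))
    for (s in seq_len(nSpecies)) {
      called <- inG & !is.na(calls$status) & calls$status == "called" &
        !is.na(calls$lineage) & calls$lineage == s
      cat6 <- if (any(called))
        classifyDirection(calls$ancestral[called], calls$derived[called])
      else character(0)
      counts <- as.integer(table(factor(cat6, levels = .DIR_CATEGORIES)))
      nSubs <- sum(counts)
      pct <- if (nSubs > 0) 100 * counts / nSubs else rep(NA_real_, 6L)
      row <- data.frame(
        species = taxa[s], siteClass = parts[2L], region = parts[1L],
        gene = if (grouping == "per_gene") parts[3L] else NA_character_,
        nGenes = nGenes, nBases = nBases,
        gcContent = 100 * gcContent(m[s, ], idx), nSubs = nSubs,
        stringsAsFactors = FALSE)
      names(counts) <- paste0("n_", c("AT_GC", "GC_AT", "AT_CG",
                                      "CG_AT", "AT_TA", "GC_CG"))
      names(pct) <- sub("^n_", "pct_", names(counts))
      rows[[length(rows) + 1L]] <- cbind(row, as.list(counts), as.list(pct))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- c(masked = sum(!usable),
                             unresolved = sum(usable & !resolved),
                             ambiguous_parsimony =
                               sum(analyzed & calls$status == "ambiguous_excluded",
                                   na.rm = TRUE))
  out
}

#' CpG-context substitution report
#'
#' Restricts the parsimony-called noncoding substitutions of each species to
#' sites in deamination-prone context -- preceded by C or followed by G in
#' that species' own sequence -- and reports the percentage of those that are
#' the methylation signature CpG->TpG (C->T with next base G) or CpG->CpA
#' (G->A with previous base C).  Context is evaluated on physical neighbor
#' columns of each gene alignment, with the ancestral allele restored at the
#' called column itself (deamination acts on the pre-substitution state).
#' Calls whose informative neighbors are unresolved are excluded and tallied.
#'
#' @param palns list of annotated, masked [PartitionedAlignment-class] gene
#'   alignments (full genes, so physical neighbors are available).
#' @param region genome region label to analyze.
#' @param mode,taxa as in [buildSpectrum()].
#' @return a `data.frame`, one row per ingroup species.
#' @export
cpgSpectrum <- function(palns, region, mode = c("3taxon", "4taxon"),
                        taxa = NULL) {
  mode <- match.arg(mode)
  if (is(palns, "PartitionedAlignment")) palns <- list(palns)
  k <- if (mode == "3taxon") 3L else 4L
  if (is.null(taxa)) taxa <- taxaNames(palns[[1L]])[seq_len(k)]

  nCtx <- nInCtx <- nDeam <- nExcl <- stats::setNames(numeric(3L), taxa[1:3])
  for (p in palns) {
    idx <- tryCatch(selectSites(p, region, "UTR+intron"),
                    error = function(e) integer(0))
    if (!length(idx)) next
    m <- .charMatrix(alignedSeqs(p))[taxa, , drop = FALSE]
    resolved <- colSums(!matrix(.isResolved(m[, idx, drop = FALSE]),
                                nrow = k)) == 0L
    idx <- idx[resolved]
    if (!length(idx)) next
    codes <- matrix(match(m[, idx, drop = FALSE], .BASES), nrow = k)
    calls <- .callColumns(codes, mode)
    nc <- ncol(m)
    for (s in 1:3) {
      row <- m[s, ]
      for (j in seq_along(idx)) {
        col <- idx[j]
        prevB <- if (col > 1L) row[col - 1L] else NA_character_
        nextB <- if (col < nc) row[col + 1L] else NA_character_
        prevOk <- !is.na(prevB) && .isResolved(prevB)
        nextOk <- !is.na(nextB) && .isResolved(nextB)
        inCtx <- (prevOk && prevB == "C") || (nextOk && nextB == "G")
        isCall <- calls$status[j] == "called" &&
          !is.na(calls$lineage[j]) && calls$lineage[j] == s
        if (inCtx) nCtx[s] <- nCtx[s] + 1
        if (!isCall) next
        if (inCtx) {
          nInCtx[s] <- nInCtx[s] + 1
          anc <- calls$ancestral[j]; der <- calls$derived[j]
          if ((anc == "C" && der == "T" && nextOk && nextB == "G") ||
              (anc == "G" && der == "A" && prevOk && prevB == "C"))
            nDeam[s] <- nDeam[s] + 1
        } else if (!prevOk || !nextOk) {
          ## context not determinable: neighbor gap/N and no known qualifier
          nExcl[s] <- nExcl[s] + 1
        }
      }
    }
  }
  data.frame(
    species = taxa[1:3], region = region, siteClass = "UTR+intron",
    nContextSites = as.integer(nCtx), nSubsInContext = as.integer(nInCtx),
    nDeamination = as.integer(nDeam),
    fractionDeamination = ifelse(nInCtx > 0, 100 * nDeam / nInCtx, NA_real_),
    nExcluded = as.integer(nExcl), row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Write a spectrum table in the standard report layout
#'
#' Tab-separated, one header line, columns ordered Species, Site, Genome
#' category, No. of genes, No. of bases, GC content, No. of substitutions,
#' then the six direction categories.  Percentages and GC content are
#' printed to 1 decimal (rounding half away from zero); undefined
#' percentages (zero substitutions) print blank.
#'
#' @param spec a `data.frame` from [buildSpectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrumTable <- function(spec, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.1f", .round1(x)))
  out <- data.frame(
    Species = spec$species, Site = spec$siteClass,
    `Genome category` = spec$region,
    `No. of genes` = spec$nGenes, `No. of bases` = spec$nBases,
    `GC content` = fmt(spec$gcContent),
    `No. of substitutions` = spec$nSubs,
    `A/T->G/C (%)` = fmt(spec$pct_AT_GC), `G/C->A/T` = fmt(spec$pct_GC_AT),
    `A/T->C/G` = fmt(spec$pct_AT_CG), `C/G->A/T` = fmt(spec$pct_CG_AT),
    `A/T->T/A` = fmt(spec$pct_AT_TA), `G/C->C/G` = fmt(spec$pct_GC_CG),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(spec$gene) && any(!is.na(spec$gene)))
    out <- cbind(out[1L], Gene = spec$gene, out[-1L])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
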