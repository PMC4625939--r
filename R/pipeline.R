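## End-to-end orchestration: spectrum reports and sex-divergence reports.

.asPartitioned <- function(alignments, metadata, mask, focal, taxa) {
  if (!is.null(alignments$genes)) alignments <- alignments$genes
  if (is.character(alignments)) {          # directory of FASTA files
    files <- sort(list.files(alignments, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    alignments <- lapply(files, readGeneAlignment)
    names(alignments) <- vapply(alignments, geneId, character(1L))
  }
  if (is.character(metadata)) metadata <- readPartitionMetadata(metadata)
  lapply(alignments, function(a) {
    p <- if (is(a, "PartitionedAlignment")) a
    else annotatePartitions(a, metadata, focal)
    applyMask(p, mask, taxa = taxa)
  })
}

#' Run the substitution-spectrum pipeline
#'
#' Reads (or accepts) gene alignments, annotates partitions, applies masks,
#' concatenates each region x site-class selection, and writes the spectrum
#' table, the CpG-context report, and a per-region exclusion log whose
#' tallies reconcile exactly with the total column count.  Outputs are
#' deterministic given identical inputs.
#'
#' @param alignments a directory of FASTA alignments, a named list of
#'   [GeneAlignment-class]/[PartitionedAlignment-class] objects, or the
#'   result of [simulateStudy()].
#' @param metadata partition metadata (path or `data.frame`); ignored for
#'   already-partitioned input.
#' @param mask optional mask (see [applyMask()]).
#' @param focal focal taxon label.
#' @param mode `"3taxon"` or `"4taxon"`.
#' @param taxa analyzed taxa in topology order; defaults to the first rows.
#' @param grouping `"region_pooled"` or `"per_gene"`.
#' @param outDir output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return invisibly, list with `spectrum`, `cpg`, `exclusions`
#'   `data.frame`s.
#' @export
runSpectrum <- function(alignments, metadata = NULL, mask = NULL,
                        focal = "focal", mode = c("3taxon", "4taxon"),
                        taxa = NULL, grouping = c("region_pooled", "per_gene"),
                        outDir = NULL) {
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  k <- if (mode == "3taxon") 3L else 4L
  probe <- if (!is.null(alignments$genes)) alignments$genes[[1L]]
  else if (is.list(alignments)) alignments[[1L]] else NULL
  if (is.null(taxa) && !is.null(probe)) taxa <- taxaNames(probe)[seq_len(k)]
  genes <- .asPartitioned(alignments, metadata, mask, focal, taxa)
  if (is.null(taxa)) taxa <- taxaNames(genes[[1L]])[seq_len(k)]

  regions <- unique(unlist(lapply(genes, function(p)
    unique(p@columns$region))))
  specRows <- list(); cpgRows <- list(); exclRows <- list()
  for (reg in regions) {
    for (sc in .SITE_CLASSES) {
      sel <- vapply(genes, function(p)
        length(selectSites(p, reg, sc)), integer(1L))
      if (sum(sel) == 0L) {
        for (s in taxa[1:3])
          specRows[[length(specRows) + 1L]] <- data.frame(
            species = s, siteClass = sc, region = reg, gene = NA_character_,
            nGenes = 0L, nBases = 0L, gcContent = NA_real_, nSubs = 0L,
            n_AT_GC = 0L, n_GC_AT = 0L, n_AT_CG = 0L, n_CG_AT = 0L,
            n_AT_TA = 0L, n_GC_CG = 0L,
            pct_AT_GC = NA_real_, pct_GC_AT = NA_real_, pct_AT_CG = NA_real_,
            pct_CG_AT = NA_real_, pct_AT_TA = NA_real_, pct_GC_CG = NA_real_,
            stringsAsFactors = FALSE)
        next
      }
      concat <- concatenateAlignments(genes[sel > 0L], reg, sc)
      sp <- buildSpectrum(concat, mode, grouping, taxa = taxa)
      attrExcl <- attr(sp, "excluded")
      specRows[[length(specRows) + 1L]] <- sp
      exclRows[[length(exclRows) + 1L]] <- data.frame(
        region = reg, siteClass = sc,
        analyzed = sum(sel) - sum(attrExcl[c("masked", "unresolved")]),
        ambiguousParsimony = attrExcl[["ambiguous_parsimony"]],
        stringsAsFactors = FALSE)
    }
    cpgRows[[length(cpgRows) + 1L]] <-
      cpgSpectrum(genes, reg, mode, taxa = taxa)
  }
  spectrum <- do.call(rbind, specRows)
  rownames(spectrum) <- NULL
  cpg <- do.call(rbind, cpgRows)

  ## per-region accounting: masked + ORF pos 1/2 + analyzed = total columns
  excl <- do.call(rbind, lapply(regions, function(reg) {
    tot <- maskedN <- orf12 <- orf3 <- nc <- 0L
    for (p in genes) {
      ann <- p@columns
      inReg <- ann$region == reg
      tot <- tot + sum(inReg)
      maskedN <- maskedN + sum(inReg & ann$masked)
      free <- inReg & !ann$masked
      orf12 <- orf12 + sum(free & ann$siteClass == "ORF" &
                             !is.na(ann$codonPos) & ann$codonPos != 3L)
      orf3 <- orf3 + sum(free & ann$siteClass == "ORF" &
                           !is.na(ann$codonPos) & ann$codonPos == 3L)
      nc <- nc + sum(free & ann$siteClass == "UTR+intron")
    }
    data.frame(region = reg, totalColumns = tot, masked = maskedN,
               orfPos12 = orf12, analyzedORF3 = orf3,
               analyzedNoncoding = nc, stringsAsFactors = FALSE)
  }))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSpectrumTable(spectrum, file.path(outDir, "spectrum.tsv"))
    utils::write.table(cpg, file.path(outDir, "cpg_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(excl, file.path(outDir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(spectrum = spectrum, cpg = cpg, exclusions = excl))
}

#' Run the sex-divergence pipeline
#'
#' Calls male-specific substitutions and indels from the sexed panels,
#' audits gametolog ORF integrity, and tests lineage rate asymmetry (Tajima
#' relative rate test plus counting dN/dS) per gene and on the combined
#' sequences.  Genes whose gametologs carry a frameshift are excluded from
#' the combined coding rows (their noncoding sites still contribute), the
#' treatment applied to frameshifted gametologs in this kind of analysis.
#'
#' @param panels named list of [GenotypePanel-class] objects (or FASTA
#'   paths, read with [readGenotypePanel()]).
#' @param coding named (by gene) list of in-frame codon alignments:
#'   `DNAStringSet` with rows `neoX`, `neoY`, and an outgroup row.
#' @param noncoding like `coding` but for noncoding sites; optional.
#' @param outgroupRow name of the outgroup row (default `"outgroup"`, with
#'   `"mouse"` accepted as a fallback).
#' @param minMales,minFemales panel-size thresholds for calling.
#' @param outDir output directory, or `NULL` to skip writing.
#' @return invisibly, list with `calls`, `integrity`, `rrt`, `dnds`
#'   `data.frame`s.
#' @export
runSexDiff <- function(panels = list(), coding = list(), noncoding = list(),
                       outgroupRow = "outgroup", minMales = 2L,
                       minFemales = 1L, outDir = NULL) {
  panels <- lapply(panels, function(p)
    if (is.character(p)) readGenotypePanel(p) else p)

  callRows <- list()
  for (p in panels) {
    snv <- detectMaleSpecific(p, minMales, minFemales)
    ind <- detectMaleSpecificIndels(p, minMales, minFemales)
    if (nrow(snv)) {
      snv$length <- 1L
      callRows[[length(callRows) + 1L]] <- snv
    }
    if (nrow(ind))
      callRows[[length(callRows) + 1L]] <-
        ind[, c("locus", "pos0", "kind", "neoX", "neoY", "nMales",
                "nFemales", "length")]
  }
  calls <- if (length(callRows)) do.call(rbind, callRows) else
    data.frame(locus = character(0), pos0 = integer(0), kind = character(0),
               neoX = character(0), neoY = character(0),
               nMales = integer(0), nFemales = integer(0),
               length = integer(0))
  rownames(calls) <- NULL

  getRow <- function(aln, what) {
    nm <- names(aln)
    if (what == "out") {
      hit <- intersect(c(outgroupRow, "mouse"), nm)
      if (!length(hit)) stop("no outgroup row in gametolog alignment")
      return(as.character(aln[[hit[1L]]]))
    }
    if (!(what %in% nm)) stop("missing row '", what, "'")
    as.character(aln[[what]])
  }

  integrity <- list(); frameshifted <- character(0)
  for (g in names(coding)) {
    x <- getRow(coding[[g]], "neoX"); y <- getRow(coding[[g]], "neoY")
    for (h in c("neoX", "neoY")) {
      rep_ <- orfIntegrity(if (h == "neoX") x else y, 0L,
                          reference = if (h == "neoX") y else x,
                          geneId = g, haplotype = h)
      integrity[[length(integrity) + 1L]] <- data.frame(
        gene = g, haplotype = h,
        frameshiftPositions = paste(rep_$frameshiftPositions + 1L,
                                    collapse = ","),
        prematureStopCodon = rep_$prematureStopCodon,
        orfIntact = rep_$orfIntact, stringsAsFactors = FALSE)
      if (!rep_$orfIntact && g %in% names(coding))
        frameshifted <- unique(c(frameshifted, g))
    }
  }
  integrity <- if (length(integrity)) do.call(rbind, integrity) else
    data.frame(gene = character(0), haplotype = character(0),
               frameshiftPositions = character(0),
               prematureStopCodon = integer(0), orfIntact = logical(0))

  ## Tajima relative rate tests, per gene and combined
  rrtRows <- list()
  rrtOne <- function(g, cls, a, b, o) {
    cnt <- uniqueDifferenceCounts(a, b, o)
    res <- tajimaRRT(cnt[["nUniqueA"]], cnt[["nUniqueB"]])
    data.frame(gene = g, siteClass = cls, nUniqueNeoX = res$nUniqueA,
               nUniqueNeoY = res$nUniqueB, chiSquare = res$chiSquare,
               pValue = res$pValue, stringsAsFactors = FALSE)
  }
  addCombined <- function(rows, cls, keep) {
    sub <- rows[rows$gene %in% keep, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    a <- sum(sub$nUniqueNeoX); b <- sum(sub$nUniqueNeoY)
    res <- tajimaRRT(a, b)
    data.frame(gene = "combined", siteClass = cls, nUniqueNeoX = a,
               nUniqueNeoY = b, chiSquare = res$chiSquare,
               pValue = res$pValue, stringsAsFactors = FALSE)
  }
  for (g in names(coding))
    rrtRows[[length(rrtRows) + 1L]] <-
      rrtOne(g, "coding", getRow(coding[[g]], "neoX"),
             getRow(coding[[g]], "neoY"), getRow(coding[[g]], "out"))
  for (g in names(noncoding))
    rrtRows[[length(rrtRows) + 1L]] <-
      rrtOne(g, "noncoding", getRow(noncoding[[g]], "neoX"),
             getRow(noncoding[[g]], "neoY"), getRow(noncoding[[g]], "out"))
  rrt <- if (length(rrtRows)) do.call(rbind, rrtRows) else
    data.frame(gene = character(0), siteClass = character(0),
               nUniqueNeoX = integer(0), nUniqueNeoY = integer(0),
               chiSquare = numeric(0), pValue = numeric(0))
  comb <- list(
    addCombined(rrt[rrt$siteClass == "coding", , drop = FALSE], "coding",
                setdiff(names(coding), frameshifted)),
    addCombined(rrt[rrt$siteClass == "noncoding", , drop = FALSE],
                "noncoding", names(noncoding)))
  rrt <- rbind(rrt, do.call(rbind, comb[!vapply(comb, is.null, logical(1))]))

  ## counting dN/dS per gene and combined (frameshifted genes excluded)
  dndsRows <- list(); accX <- accY <- list(); accAnc <- character(0)
  for (g in names(coding)) {
    asg <- assignBranchChanges(getRow(coding[[g]], "neoX"),
                               getRow(coding[[g]], "neoY"),
                               getRow(coding[[g]], "out"))
    for (br in c("neoX", "neoY")) {
      d <- ng86BranchDnds(asg[[br]], asg$ancestral, branch = br)
      d <- cbind(gene = g, d)
      dndsRows[[length(dndsRows) + 1L]] <- d
    }
    if (!(g %in% frameshifted)) {
      off <- length(accAnc)
      if (nrow(asg$neoX)) {
        tmp <- asg$neoX; tmp$codon <- tmp$codon + off
        accX[[length(accX) + 1L]] <- tmp
      }
      if (nrow(asg$neoY)) {
        tmp <- asg$neoY; tmp$codon <- tmp$codon + off
        accY[[length(accY) + 1L]] <- tmp
      }
      accAnc <- c(accAnc, asg$ancestral)
    }
  }
  if (length(accAnc)) {
    empty <- data.frame(codon = integer(0), syn = numeric(0),
                        nonsyn = numeric(0))
    chX <- if (length(accX)) do.call(rbind, accX) else empty
    chY <- if (length(accY)) do.call(rbind, accY) else empty
    dndsRows[[length(dndsRows) + 1L]] <-
      cbind(gene = "combined", ng86BranchDnds(chX, accAnc, branch = "neoX"))
    dndsRows[[length(dndsRows) + 1L]] <-
      cbind(gene = "combined", ng86BranchDnds(chY, accAnc, branch = "neoY"))
  }
  dnds <- if (length(dndsRows)) do.call(rbind, dndsRows) else
    data.frame(gene = character(0), branch = character(0),
               NSites = numeric(0), SSites = numeric(0),
               nChanges = numeric(0), sChanges = numeric(0),
               pN = numeric(0), pS = numeric(0), omega = numeric(0),
               omegaDefined = logical(0))
  rownames(dnds) <- NULL

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    rpt <- calls
    if (nrow(rpt)) rpt$position <- rpt$pos0 + 1L  # 1-based in reports
    else rpt$position <- integer(0)
    rpt$pos0 <- NULL
    utils::write.table(rpt, file.path(outDir, "malespec_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(integrity, file.path(outDir, "integrity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rrt, file.path(outDir, "rrt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dnds, file.path(outDir, "dnds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(calls = calls, integrity = integrity, rrt = rrt,
                 dnds = dnds, frameshifted = frameshifted))
}
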