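#' Read a multi-species gene alignment
#'
#' Reads a gapped nucleotide alignment in FASTA or Clustal format and returns
#' a validated [GeneAlignment-class].  Input taxon order is preserved.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param geneId gene identifier; defaults to the file name without extension.
#' @return a [GeneAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">tmu", "ACGT", ">mouse", "ACGT", ">rat", "ACGA"), fa)
#' readGeneAlignment(fa)
#' @export
readGeneAlignment <- function(path, format = c("fasta", "clustal"),
                              geneId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  if (is.null(geneId))
    geneId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "fasta") {
    seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                     error = function(e)
                       stop("alphabet error reading '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  } else {
    bin <- ape::read.dna(path, format = "clustal")
    rows <- toupper(apply(as.character(bin), 1L, paste, collapse = ""))
    seqs <- Biostrings::DNAStringSet(rows)
  }
  GeneAlignment(geneId, seqs)
}

#' Write a gene alignment to FASTA
#'
#' @param x a [GeneAlignment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneAlignment <- function(x, path) {
  stopifnot(is(x, "GeneAlignment"))
  Biostrings::writeXStringSet(alignedSeqs(x), filepath = path)
  invisible(path)
}

#' Read a partition metadata table
#'
#' Tab-separated table with columns `gene_id`, `region`, `orf_start`,
#' `orf_end`, `frame`.  One row per ORF interval; `orf_start`/`orf_end` are
#' 0-based half-open coordinates on the focal species' ungapped sequence, and
#' `frame` is the number of bases before the first complete codon (GFF-style
#' phase).  A gene with no coding sequence uses `NA` interval bounds.
#'
#' @param path path to the TSV file.
#' @return a `data.frame`.
#' @export
readPartitionMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "region", "orf_start", "orf_end", "frame")
  if (!all(need %in% colnames(md)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  md
}

#' Annotate alignment columns with partition labels and codon positions
#'
#' Labels every alignment column with its genome region and site class, and
#' assigns codon positions by walking the focal species' non-gap sites through
#' each declared ORF interval.  Columns where the focal species has a gap
#' inside an ORF are labelled ORF but masked (no focal base, no codon
#' position).
#'
#' @param aln a [GeneAlignment-class].
#' @param metadata a `data.frame` as returned by [readPartitionMetadata()]
#'   (rows for other genes are ignored).
#' @param focal focal taxon label.
#' @return a [PartitionedAlignment-class].
#' @export
annotatePartitions <- function(aln, metadata, focal) {
  stopifnot(is(aln, "GeneAlignment"))
  if (!(focal %in% taxaNames(aln)))
    stop("focal taxon '", focal, "' is not a row of the alignment")
  if ("gene_id" %in% colnames(metadata)) {
    rows <- metadata[metadata$gene_id == geneId(aln), , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("no metadata rows for gene '", geneId(aln), "'")
  } else rows <- metadata
  region <- unique(as.character(rows$region))
  if (length(region) != 1L)
    stop("metadata error: gene '", geneId(aln),
         "' must carry exactly one region label")
  if (!(region %in% .REGION_LEVELS))
    stop("unknown region label: ", region)

  m <- .charMatrix(alignedSeqs(aln))
  ncols <- ncol(m)
  focalRow <- m[focal, ]
  nonGap <- focalRow != "-"
  ## 0-based ungapped position of each non-gap focal column
  pos0 <- cumsum(nonGap) - 1L
  focalLen <- sum(nonGap)

  siteClass <- rep("UTR+intron", ncols)
  codonPos <- rep(NA_integer_, ncols)
  masked <- rep(FALSE, ncols)

  ivals <- rows[!is.na(rows$orf_start) & !is.na(rows$orf_end), , drop = FALSE]
  if (nrow(ivals)) {
    ivals <- ivals[order(ivals$orf_start), , drop = FALSE]
    for (k in seq_len(nrow(ivals))) {
      s <- ivals$orf_start[k]; e <- ivals$orf_end[k]; fr <- ivals$frame[k]
      if (is.na(fr) || !(fr %in% 0:2))
        stop("metadata error: frame must be 0, 1 or 2")
      if (s < 0 || e > focalLen || s >= e)
        stop("metadata error: ORF interval [", s, ",", e,
             ") out of bounds for focal length ", focalLen)
      if (k > 1L) {
        sPrev <- ivals$orf_start[k - 1L]; ePrev <- ivals$orf_end[k - 1L]
        frPrev <- ivals$frame[k - 1L]
        if (s < ePrev)
          stop("metadata error: overlapping ORF intervals")
        expect <- (3L - ((ePrev - sPrev - frPrev) %% 3L)) %% 3L
        if (fr != expect)
          stop("metadata error: interval frame ", fr,
               " inconsistent with continuation frame ", expect)
      }
      inIval <- nonGap & pos0 >= s & pos0 < e
      cols <- which(inIval)
      ## codon position cycles over focal non-gap sites within the interval
      codonPos[cols] <- ((pos0[cols] - s - fr) %% 3L) + 1L
      siteClass[cols] <- "ORF"
      ## focal-gap columns physically inside the ORF: ORF class, masked
      if (length(cols) >= 2L) {
        inside <- setdiff(seq(min(cols), max(cols)), cols)
        inside <- inside[focalRow[inside] == "-"]
        if (length(inside)) {
          siteClass[inside] <- "ORF"
          masked[inside] <- TRUE
        }
      }
    }
  }

  cols <- S4Vectors::DataFrame(
    region = rep(region, ncols), siteClass = siteClass,
    codonPos = codonPos, masked = masked,
    geneId = rep(geneId(aln), ncols), origColumn = seq_len(ncols))
  new("PartitionedAlignment", geneId = geneId(aln), seqs = alignedSeqs(aln),
      focal = focal, columns = cols)
}

## normalize a mask argument into a set of 0-based focal ungapped positions
.maskPositions <- function(mask, geneId) {
  if (is.null(mask)) return(integer(0))
  if (is.character(mask)) {
    gr <- tryCatch(rtracklayer::import(mask, format = "BED"),
                   error = function(e)
                     stop("mask BED parse error: ", conditionMessage(e),
                          call. = FALSE))
  } else if (is(mask, "GRanges")) {
    gr <- mask
  } else if (is.data.frame(mask)) {
    ## plain 0-based half-open intervals, optional gene_id column
    gr <- GenomicRanges::GRanges(
      seqnames = if ("gene_id" %in% colnames(mask)) mask$gene_id else geneId,
      ranges = IRanges::IRanges(start = mask$start + 1L, end = mask$end))
  } else stop("unsupported mask type: ", class(mask)[1L])
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% c(geneId, "*")]
  if (!length(gr)) return(integer(0))
  ## GRanges is 1-based closed; convert to 0-based positions
  unique(unlist(lapply(seq_along(gr), function(i)
    seq(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L))))
}

#' Mask alignment columns
#'
#' Masks (i) columns whose focal base falls inside a user-supplied interval
#' mask (repeats, unalignable stretches), given in 0-based half-open focal
#' ungapped coordinates, and (ii) columns carrying a gap, `N`, or any IUPAC
#' ambiguity in one of the analyzed taxa, since parsimony direction
#' assignment requires every taxon resolved.  Masked columns are never
#' counted by any downstream tally.
#'
#' @param paln a [PartitionedAlignment-class].
#' @param mask `NULL`, a BED file path, a `GRanges`, or a `data.frame` with
#'   columns `start`, `end` (0-based half-open) and optionally `gene_id`.
#' @param taxa taxa whose resolution is required (default: all rows).
#' @return the updated [PartitionedAlignment-class].
#' @export
applyMask <- function(paln, mask = NULL, taxa = taxaNames(paln)) {
  stopifnot(is(paln, "PartitionedAlignment"))
  bad <- setdiff(taxa, taxaNames(paln))
  if (length(bad))
    stop("unknown taxa: ", paste(bad, collapse = ", "))
  m <- .charMatrix(alignedSeqs(paln))
  cols <- paln@columns
  ## gap / N / ambiguity rule over the analyzed taxa
  unresolved <- colSums(!matrix(.isResolved(m[taxa, , drop = FALSE]),
                                nrow = length(taxa))) > 0L
  masked <- cols$masked | unresolved
  ## interval mask on the focal ungapped coordinate
  pos <- .maskPositions(mask, geneId(paln))
  if (length(pos)) {
    focalRow <- m[focalTaxon(paln), ]
    nonGap <- focalRow != "-"
    pos0 <- cumsum(nonGap) - 1L
    masked <- masked | (nonGap & pos0 %in% pos)
  }
  cols$masked <- masked
  paln@columns <- cols
  paln
}

#' Select analyzed columns for one region and site class
#'
#' Returns the strictly increasing indices of unmasked columns matching the
#' requested region and site class.  For the `"ORF"` site class only third
#' codon positions are returned, the near-neutral coding site class used
#' throughout the spectrum analysis.
#'
#' @param paln a [PartitionedAlignment-class].
#' @param region one of `"peritelomeric"`, `"middle"`, `"pericentromeric"`,
#'   `"other"`.
#' @param siteClass `"ORF"` or `"UTR+intron"`.
#' @return sorted integer vector of column indices (1-based, in-memory).
#' @export
selectSites <- function(paln, region, siteClass) {
  stopifnot(is(paln, "PartitionedAlignment"))
  if (!(region %in% .REGION_LEVELS))
    stop("selection error: unknown region label '", region, "'")
  if (!(siteClass %in% .SITE_CLASSES))
    stop("selection error: unknown site class '", siteClass, "'")
  cols <- paln@columns
  keep <- !cols$masked & cols$region == region & cols$siteClass == siteClass
  if (siteClass == "ORF")
    keep <- keep & !is.na(cols$codonPos) & cols$codonPos == 3L
  which(keep)
}

#' Concatenate selected sites across genes
#'
#' Builds the region/site-class concatenation used for pooled spectra: the
#' union of each gene's selected columns, gene order preserved, with
#' per-column gene identity retained so per-gene spectra can be recovered
#' from the same object.
#'
#' @param palns list of [PartitionedAlignment-class] objects sharing one
#'   taxon set and focal taxon.
#' @param region,siteClass passed to [selectSites()].
#' @return a [PartitionedAlignment-class] whose columns are the selected
#'   sites of all genes.
#' @export
concatenateAlignments <- function(palns, region, siteClass) {
  stopifnot(length(palns) >= 1L)
  taxa <- taxaNames(palns[[1L]])
  focal <- focalTaxon(palns[[1L]])
  pieces <- list(); annot <- list()
  for (p in palns) {
    if (!setequal(taxaNames(p), taxa))
      stop("identity error: taxon sets differ across genes")
    if (focalTaxon(p) != focal)
      stop("identity error: focal taxon differs across genes")
    idx <- selectSites(p, region, siteClass)
    if (!length(idx)) next
    m <- .charMatrix(alignedSeqs(p))[taxa, , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- m[, idx, drop = FALSE]
    annot[[length(annot) + 1L]] <- p@columns[idx, , drop = FALSE]
  }
  if (!length(pieces))
    stop("no columns selected for region '", region, "', site class '",
         siteClass, "'")
  m <- do.call(cbind, pieces)
  seqs <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
  names(seqs) <- taxa
  cols <- do.call(rbind, annot)
  new("PartitionedAlignment",
      geneId = paste0("concat:", region, ":", siteClass),
      seqs = seqs, focal = focal, columns = cols)
}
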