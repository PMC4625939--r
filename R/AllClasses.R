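#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.NUC_ALPHABET <- c("A", "C", "G", "T", "N", "-",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

.REGION_LEVELS <- c("peritelomeric", "middle", "pericentromeric", "other")
.SITE_CLASSES  <- c("ORF", "UTR+intron")

#' GeneAlignment: a validated multi-species gene alignment
#'
#' Thin S4 wrapper around a [Biostrings::DNAStringSet] holding one gapped row
#' per taxon for a single gene.  All rows must have identical width, taxon
#' labels must be unique, and the alphabet is restricted to IUPAC nucleotide
#' codes plus the gap character.
#'
#' @slot geneId single character, the gene identifier.
#' @slot seqs a `DNAStringSet`, one named row per taxon, equal widths.
#'
#' @exportClass GeneAlignment
setClass("GeneAlignment",
         representation(geneId = "character", seqs = "DNAStringSet"))

setValidity("GeneAlignment", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || is.na(object@geneId))
    msg <- c(msg, "geneId must be a single non-NA string")
  w <- Biostrings::width(object@seqs)
  if (length(w) < 1L)
    msg <- c(msg, "alignment must contain at least one row")
  if (length(unique(w)) > 1L)
    msg <- c(msg, "alignment rows must all have the same length")
  if (length(w) >= 1L && w[1L] < 1L)
    msg <- c(msg, "alignment must have length >= 1")
  nm <- names(object@seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "every row must carry a taxon label")
  else if (anyDuplicated(nm))
    msg <- c(msg, "taxon labels must be unique")
  chars <- unique(unlist(strsplit(as.character(object@seqs), "", fixed = TRUE)))
  bad <- setdiff(chars, .NUC_ALPHABET)
  if (length(bad))
    msg <- c(msg, paste0("illegal alignment characters: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PartitionedAlignment: a gene alignment with per-column annotations
#'
#' Extends [GeneAlignment-class] with a column-parallel annotation table:
#' `region` (genome category), `siteClass` (`"ORF"` or `"UTR+intron"`),
#' `codonPos` (1, 2, 3, or `NA` outside ORFs), `masked` (excluded from every
#' downstream tally), and `geneId` (per column, so concatenations across genes
#' retain gene identity).  `origColumn` records the source column index within
#' the contributing gene, which lets context-sensitive analyses recover
#' physical adjacency after site selection.
#'
#' @slot focal taxon label whose ungapped coordinates anchor ORF intervals and
#'   masks.
#' @slot columns a `DataFrame` with one row per alignment column.
#'
#' @exportClass PartitionedAlignment
setClass("PartitionedAlignment",
         contains = "GeneAlignment",
         representation(focal = "character", columns = "DataFrame"))

setValidity("PartitionedAlignment", function(object) {
  msg <- character()
  need <- c("region", "siteClass", "codonPos", "masked", "geneId", "origColumn")
  if (!all(need %in% colnames(object@columns)))
    msg <- c(msg, paste0("columns must contain: ", paste(need, collapse = ", ")))
  else {
    if (nrow(object@columns) != Biostrings::width(object@seqs)[1L])
      msg <- c(msg, "one annotation row per alignment column required")
    cp <- object@columns$codonPos
    sc <- object@columns$siteClass
    if (any(!is.na(cp) & sc != "ORF"))
      msg <- c(msg, "codonPos must be NA outside ORF columns")
    if (any(is.na(cp) & sc == "ORF" & !object@columns$masked))
      msg <- c(msg, "unmasked ORF columns must carry a codon position")
    bad <- setdiff(unique(object@columns$region), .REGION_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown region label(s): ", paste(bad, collapse = ", ")))
    bad <- setdiff(unique(sc), .SITE_CLASSES)
    if (length(bad))
      msg <- c(msg, paste0("unknown site class(es): ", paste(bad, collapse = ", ")))
  }
  if (length(object@focal) != 1L || !(object@focal %in% names(object@seqs)))
    msg <- c(msg, "focal must name one alignment row")
  if (length(msg)) msg else TRUE
})

#' GenotypePanel: sexed per-individual sequences over one locus
#'
#' Holds aligned per-individual consensus sequences over a shared coordinate
#' frame.  Heterozygous positions are encoded with IUPAC ambiguity codes
#' (Sanger double peaks); alignment gaps encode length variants.
#'
#' @slot locusId single character locus identifier.
#' @slot seqs `DNAStringSet`, one named row per individual, equal widths.
#' @slot sex character vector, `"M"` or `"F"`, parallel to `seqs`.
#'
#' @exportClass GenotypePanel
setClass("GenotypePanel",
         representation(locusId = "character", seqs = "DNAStringSet",
                        sex = "character"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L)
    msg <- c(msg, "locusId must be a single string")
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) > 1L)
    msg <- c(msg, "all individual sequences must have the same length")
  if (length(object@sex) != length(object@seqs))
    msg <- c(msg, "one sex entry per individual required")
  if (!all(object@sex %in% c("M", "F")))
    msg <- c(msg, "sex must be 'M' or 'F'")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "individual ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneAlignment-class constructor.
#' @param geneId gene identifier.
#' @param seqs named `DNAStringSet` (or named character vector) of aligned rows.
#' @export
GeneAlignment <- function(geneId, seqs) {
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  new("GeneAlignment", geneId = as.character(geneId), seqs = seqs)
}

#' @describeIn GenotypePanel-class constructor.
#' @param locusId locus identifier.
#' @param seqs named `DNAStringSet` (or character vector) of individual rows.
#' @param sex character vector of `"M"`/`"F"`, parallel to `seqs`.
#' @export
GenotypePanel <- function(locusId, seqs, sex) {
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  new("GenotypePanel", locusId = as.character(locusId), seqs = seqs,
      sex = as.character(sex))
}

## ---- accessors ------------------------------------------------------------

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @describeIn GeneAlignment-class gene identifier.
#' @param x object.
#' @export
setMethod("geneId", "GeneAlignment", function(x) x@geneId)

#' @export
setGeneric("taxaNames", function(x) standardGeneric("taxaNames"))
#' @describeIn GeneAlignment-class taxon labels in input order.
#' @export
setMethod("taxaNames", "GeneAlignment", function(x) names(x@seqs))

#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))
#' @describeIn GeneAlignment-class the underlying `DNAStringSet`.
#' @export
setMethod("alignedSeqs", "GeneAlignment", function(x) x@seqs)
#' @describeIn GenotypePanel-class the underlying `DNAStringSet`.
#' @export
setMethod("alignedSeqs", "GenotypePanel", function(x) x@seqs)

#' @export
setGeneric("alignmentColumns", function(x) standardGeneric("alignmentColumns"))
#' @describeIn PartitionedAlignment-class per-column annotation `DataFrame`.
#' @param x object.
#' @export
setMethod("alignmentColumns", "PartitionedAlignment", function(x) x@columns)

#' @export
setGeneric("focalTaxon", function(x) standardGeneric("focalTaxon"))
#' @describeIn PartitionedAlignment-class focal taxon label.
#' @export
setMethod("focalTaxon", "PartitionedAlignment", function(x) x@focal)

#' @export
setGeneric("panelSex", function(x) standardGeneric("panelSex"))
#' @describeIn GenotypePanel-class sexes of the individuals.
#' @param x object.
#' @export
setMethod("panelSex", "GenotypePanel", function(x) {
  stats::setNames(x@sex, names(x@seqs))
})

#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @describeIn GenotypePanel-class locus identifier.
#' @export
setMethod("locusId", "GenotypePanel", function(x) x@locusId)

## ---- show -----------------------------------------------------------------

setMethod("show", "GeneAlignment", function(object) {
  cat("GeneAlignment '", object@geneId, "': ",
      length(object@seqs), " taxa x ", Biostrings::width(object@seqs)[1L],
      " columns\n  taxa: ", paste(names(object@seqs), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "PartitionedAlignment", function(object) {
  tab <- table(region = object@columns$region,
               siteClass = object@columns$siteClass)
  cat("PartitionedAlignment '", object@geneId, "': ",
      length(object@seqs), " taxa x ", nrow(object@columns),
      " columns (focal: ", object@focal, ")\n  masked columns: ",
      sum(object@columns$masked), "\n", sep = "")
  print(tab)
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel '", object@locusId, "': ",
      sum(object@sex == "M"), " males + ", sum(object@sex == "F"),
      " females, ", Biostrings::width(object@seqs)[1L], " columns\n",
      sep = "")
})
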