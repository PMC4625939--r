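## Shared fixtures and independent oracles used across the suite.

## build a PartitionedAlignment directly from character rows
makePaln <- function(rows, region = "middle", siteClass = "UTR+intron",
                     focal = names(rows)[1L], geneId = "g1",
                     codonPos = NULL, masked = NULL) {
  seqs <- Biostrings::DNAStringSet(rows)
  n <- Biostrings::width(seqs)[1L]
  if (is.null(codonPos))
    codonPos <- if (siteClass == "ORF") rep(1:3, length.out = n)
    else rep(NA_integer_, n)
  if (is.null(masked)) masked <- rep(FALSE, n)
  cols <- S4Vectors::DataFrame(
    region = rep(region, n),
    siteClass = rep(siteClass, length.out = n),
    codonPos = as.integer(codonPos), masked = masked,
    geneId = rep(geneId, n), origColumn = seq_len(n))
  new("PartitionedAlignment", geneId = geneId, seqs = seqs,
      focal = focal, columns = cols)
}

writeFasta <- function(rows, path) {
  writeLines(paste0(">", names(rows), "\n", rows), path)
  path
}

BASES <- c("A", "C", "G", "T")

## independent 3-taxon rule table: explicit pairwise comparisons
oracle3taxon <- function(b) {
  if (b[1L] == b[2L] && b[2L] == b[3L])
    return(list(status = "invariant", lineage = NA_integer_,
                ancestral = NA_character_, derived = NA_character_))
  if (b[1L] == b[2L])
    return(list(status = "called", lineage = 3L, ancestral = b[1L],
                derived = b[3L]))
  if (b[1L] == b[3L])
    return(list(status = "called", lineage = 2L, ancestral = b[1L],
                derived = b[2L]))
  if (b[2L] == b[3L])
    return(list(status = "called", lineage = 1L, ancestral = b[2L],
                derived = b[1L]))
  list(status = "ambiguous_excluded", lineage = NA_integer_,
       ancestral = NA_character_, derived = NA_character_)
}

## independent exhaustive Fitch oracle on ((t1,t2),t3,t4), root at the
## t3/t4 junction: enumerate internal states, keep minimum-score
## reconstructions, and demand a unique single-change terminal placement
oracleFitch4 <- function(b) {
  recon <- list()
  minScore <- Inf
  for (a in BASES) for (r in BASES) {
    edges <- list(
      list(edge = "t1", parent = a, child = b[1L]),
      list(edge = "t2", parent = a, child = b[2L]),
      list(edge = "int", parent = r, child = a),
      list(edge = "t3", parent = r, child = b[3L]),
      list(edge = "t4", parent = r, child = b[4L]))
    changed <- Filter(function(e) e$parent != e$child, edges)
    sc <- length(changed)
    if (sc < minScore) { minScore <- sc; recon <- list(changed) }
    else if (sc == minScore) recon[[length(recon) + 1L]] <- changed
  }
  if (minScore == 0L)
    return(list(status = "invariant", lineage = NA_integer_,
                ancestral = NA_character_, derived = NA_character_))
  descr <- vapply(recon, function(ch) {
    if (length(ch) != 1L) return("multi")
    paste(ch[[1L]]$edge, ch[[1L]]$parent, ch[[1L]]$child)
  }, character(1L))
  if (length(unique(descr)) != 1L || descr[1L] == "multi")
    return(list(status = "ambiguous_excluded", lineage = NA_integer_,
                ancestral = NA_character_, derived = NA_character_))
  e <- recon[[1L]][[1L]]
  if (e$edge == "int")
    return(list(status = "ambiguous_excluded", lineage = NA_integer_,
                ancestral = NA_character_, derived = NA_character_))
  list(status = "called", lineage = match(e$edge, c("t1", "t2", "t3", "t4")),
       ancestral = e$parent, derived = e$child)
}

revcompRows <- function(rows) {
  vapply(rows, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1L))
}

## reverse-complement a PartitionedAlignment (noncoding fixtures only)
revcompPaln <- function(p) {
  rows <- vapply(as.character(alignedSeqs(p)), function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1L))
  names(rows) <- taxaNames(p)
  cols <- alignmentColumns(p)[rev(seq_len(nrow(alignmentColumns(p)))), ]
  cols$origColumn <- seq_len(nrow(cols))
  new("PartitionedAlignment", geneId = geneId(p), seqs =
        Biostrings::DNAStringSet(rows), focal = focalTaxon(p),
      columns = cols)
}

## small symmetric simulator configuration (no direction bias, no CpG)
symmetricConfig <- function(seed, noncodingLen = 5000L, nGenes = 4L) {
  simConfig(seed = seed,
            regions = data.frame(name = "middle", nGenes = nGenes,
                                 orfLen = 0L, noncodingLen = noncodingLen,
                                 lambdaATGC = 1, lambdaGCAT = 1,
                                 rootGC = 0.5, stringsAsFactors = FALSE),
            cpgMultiplier = 1)
}
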