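test_that("FASTA alignments parse, validate, and round-trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(c(tmu = "ACGT", mouse = "ACGT", rat = "ACGA", gpig = "ACGT"), fa)
  aln <- readGeneAlignment(fa)
  expect_s4_class(aln, "GeneAlignment")
  expect_equal(taxaNames(aln), c("tmu", "mouse", "rat", "gpig"))
  expect_equal(Biostrings::width(alignedSeqs(aln)), rep(4L, 4L))

  out <- withr::local_tempfile(fileext = ".fasta")
  writeGeneAlignment(aln, out)
  rt <- readGeneAlignment(out, geneId = geneId(aln))
  expect_identical(as.character(alignedSeqs(rt)),
                   as.character(alignedSeqs(aln)))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(c(a = "ACGT", b = "ACGTA"), bad)
  expect_error(readGeneAlignment(bad), "same length")
  writeFasta(c(a = "ACGT", a = "ACGA"), bad)
  expect_error(readGeneAlignment(bad), "unique")
  writeLines(c(">a", "AC+T", ">b", "ACGT"), bad)
  expect_error(readGeneAlignment(bad))
})

test_that("Clustal alignments are read with taxa and rows intact", {
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.1) multiple sequence alignment", "",
               "tmu             ACGTACGT", "mouse           ACGTACGT",
               "rat             ACGAACGT",
               "                *** ****", ""), cl)
  aln <- readGeneAlignment(cl, format = "clustal")
  expect_equal(taxaNames(aln), c("tmu", "mouse", "rat"))
  expect_equal(as.character(alignedSeqs(aln)[["rat"]]), "ACGAACGT")
})

test_that("codon positions walk the focal frame through ORF intervals", {
  aln <- GeneAlignment("g1", c(tmu = "ATGAAA", mouse = "ATGAAA",
                               rat = "ATGAAA"))
  md <- data.frame(gene_id = "g1", region = "peritelomeric",
                   orf_start = 0L, orf_end = 6L, frame = 0L)
  p <- annotatePartitions(aln, md, focal = "tmu")
  expect_equal(alignmentColumns(p)$codonPos, c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_true(all(alignmentColumns(p)$siteClass == "ORF"))

  ## focal gap inside the ORF: no focal base, so no codon position; masked
  aln2 <- GeneAlignment("g1", c(tmu = "ATG-AAA", mouse = "ATGCAAA",
                                rat = "ATGCAAA"))
  md2 <- data.frame(gene_id = "g1", region = "peritelomeric",
                    orf_start = 0L, orf_end = 6L, frame = 0L)
  p2 <- annotatePartitions(aln2, md2, focal = "tmu")
  expect_true(is.na(alignmentColumns(p2)$codonPos[4L]))
  expect_true(alignmentColumns(p2)$masked[4L])
  expect_equal(alignmentColumns(p2)$siteClass[4L], "ORF")
  ## the walk resumes across the gap
  expect_equal(alignmentColumns(p2)$codonPos[c(1:3, 5:7)],
               c(1L, 2L, 3L, 1L, 2L, 3L))

  expect_error(
    annotatePartitions(aln, data.frame(gene_id = "g1", region = "middle",
                                       orf_start = 0L, orf_end = 100L,
                                       frame = 0L), "tmu"),
    "out of bounds")
})

test_that("split ORF intervals must continue the reading frame", {
  aln <- GeneAlignment("g1", c(tmu = strrep("A", 12L),
                               mouse = strrep("C", 12L)))
  good <- data.frame(gene_id = "g1", region = "middle",
                     orf_start = c(0L, 8L), orf_end = c(4L, 12L),
                     frame = c(0L, 2L))
  p <- annotatePartitions(aln, good, "tmu")
  ## first interval ends mid-codon after position 1, so the continuation
  ## resumes at codon position 2 (phase 2 = two bases already consumed)
  expect_equal(alignmentColumns(p)$codonPos[9:12], c(2L, 3L, 1L, 2L))
  bad <- transform(good, frame = c(0L, 0L))
  expect_error(annotatePartitions(aln, bad, "tmu"), "inconsistent")
})

test_that("masking covers BED intervals and unresolved columns", {
  p <- makePaln(c(tmu = "ACGTAC", mouse = "ACGTAC", rat = "ACGTAC"))
  masked <- applyMask(p, data.frame(start = 2L, end = 4L))
  expect_equal(which(alignmentColumns(masked)$masked), c(3L, 4L))

  expect_equal(sum(alignmentColumns(applyMask(p))$masked), 0L)

  g <- makePaln(c(tmu = "ACGTAC", mouse = "AC-TAC", rat = "ACGTAC"))
  expect_equal(which(alignmentColumns(applyMask(g))$masked), 3L)
  amb <- makePaln(c(tmu = "ACRTAC", mouse = "ACGTAC", rat = "ACGTAC"))
  expect_equal(which(alignmentColumns(applyMask(amb))$masked), 3L)

  ## BED path input: 0-based half-open on the focal ungapped coordinate
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("g1\t2\t4", bed)
  expect_equal(which(alignmentColumns(applyMask(p, bed))$masked), c(3L, 4L))
  writeLines("g1\tnotanumber\t4", bed)
  expect_error(applyMask(p, bed), "parse")
})

test_that("site selection honors region, site class, codon position, masks", {
  orf <- makePaln(c(tmu = "ATGAAAGGG", mouse = "ATGAAAGGG",
                    rat = "ATGAAAGGG"), region = "peritelomeric",
                  siteClass = "ORF")
  expect_equal(selectSites(orf, "peritelomeric", "ORF"), c(3L, 6L, 9L))
  expect_equal(selectSites(orf, "middle", "ORF"), integer(0))
  expect_error(selectSites(orf, "nowhere", "ORF"), "unknown region")

  m <- rep(FALSE, 9L); m[6L] <- TRUE
  orfM <- makePaln(c(tmu = "ATGAAAGGG", mouse = "ATGAAAGGG",
                     rat = "ATGAAAGGG"), region = "peritelomeric",
                   siteClass = "ORF", masked = m)
  expect_equal(selectSites(orfM, "peritelomeric", "ORF"), c(3L, 9L))

  ## ORF and noncoding selections never overlap
  expect_length(intersect(selectSites(orf, "peritelomeric", "ORF"),
                          selectSites(orf, "peritelomeric", "UTR+intron")),
                0L)
})

test_that("concatenation is additive and preserves gene identity", {
  g1 <- makePaln(c(tmu = "ACG", mouse = "ACG", rat = "ACG"),
                 geneId = "g1")
  g2 <- makePaln(c(tmu = "TT", mouse = "TT", rat = "TT"), geneId = "g2")
  cc <- concatenateAlignments(list(g1, g2), "middle", "UTR+intron")
  expect_equal(Biostrings::width(alignedSeqs(cc))[1L], 5L)
  expect_equal(alignmentColumns(cc)$geneId, c(rep("g1", 3), rep("g2", 2)))

  one <- concatenateAlignments(list(g1), "middle", "UTR+intron")
  expect_equal(as.character(alignedSeqs(one)),
               as.character(alignedSeqs(g1)))

  gX <- makePaln(c(tmu = "AC", other = "AC", rat = "AC"))
  expect_error(concatenateAlignments(list(g1, gX), "middle", "UTR+intron"),
               "identity error")

  ## analyzed-base count equals the brute-force per-gene recount
  set.seed(11)
  genes <- lapply(1:5, function(i) {
    n <- sample(5:30, 1L)
    rows <- c(tmu = paste(sample(BASES, n, TRUE), collapse = ""),
              mouse = paste(sample(BASES, n, TRUE), collapse = ""),
              rat = paste(sample(BASES, n, TRUE), collapse = ""))
    makePaln(rows, geneId = paste0("g", i),
             masked = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)))
  })
  cc <- concatenateAlignments(genes, "middle", "UTR+intron")
  expect_equal(Biostrings::width(alignedSeqs(cc))[1L],
               sum(vapply(genes, function(g)
                 length(selectSites(g, "middle", "UTR+intron")),
                 integer(1L))))
})

test_that("masking is monotone in the analyzed-site count", {
  set.seed(5)
  p <- makePaln(c(tmu = paste(sample(BASES, 60, TRUE), collapse = ""),
                  mouse = paste(sample(BASES, 60, TRUE), collapse = ""),
                  rat = paste(sample(BASES, 60, TRUE), collapse = "")))
  prev <- length(selectSites(applyMask(p), "middle", "UTR+intron"))
  ivals <- data.frame(start = c(5L, 20L, 40L), end = c(10L, 30L, 55L))
  for (k in 1:3) {
    cur <- length(selectSites(applyMask(p, ivals[seq_len(k), ]),
                              "middle", "UTR+intron"))
    expect_lte(cur, prev)
    prev <- cur
  }
})
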