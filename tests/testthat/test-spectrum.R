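test_that("3-taxon calls match the independent rule-table oracle on all 64 columns", {
  grid <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    b <- unname(unlist(grid[i, ]))
    got <- callSite3Taxon(unname(b))
    want <- oracle3taxon(b)
    expect_equal(got$status, want$status, info = paste(b, collapse = ""))
    if (want$status == "called") {
      expect_equal(as.integer(got$lineage), want$lineage)
      expect_equal(got$ancestral, want$ancestral)
      expect_equal(got$derived, want$derived)
    }
  }
  ## the published worked example: focal G, others share A => A -> G
  call <- callSite3Taxon(c(tmu = "G", mouse = "A", rat = "A"))
  expect_equal(call[c("status", "lineage", "ancestral", "derived")],
               list(status = "called", lineage = "tmu",
                    ancestral = "A", derived = "G"))
  expect_equal(callSite3Taxon(c("G", "G", "G"))$status, "invariant")
  expect_error(callSite3Taxon(c("G", "N", "A")), "precondition")
})

test_that("4-taxon calls match the exhaustive Fitch oracle on all 256 columns", {
  grid <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES, b4 = BASES,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    b <- unname(unlist(grid[i, ]))
    got <- callSite4Taxon(unname(b))
    want <- oracleFitch4(b)
    expect_equal(got$status, want$status, info = paste(b, collapse = ""))
    if (want$status == "called") {
      expect_equal(as.integer(got$lineage), want$lineage)
      expect_equal(got$ancestral, want$ancestral)
      expect_equal(got$derived, want$derived)
    }
  }
  expect_equal(callSite4Taxon(c("G", "A", "A", "A"))$lineage, "1")
  ## a shared focal+sister state against rat+outgroup sits on the internal
  ## branch: never a terminal call
  expect_equal(callSite4Taxon(c("G", "G", "A", "A"))$status,
               "ambiguous_excluded")
})

test_that("3- and 4-taxon engines agree when the outgroup matches the shared allele", {
  grid <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    b <- unname(unlist(grid[i, ]))
    c3 <- callSite3Taxon(unname(b))
    if (c3$status != "called" || c3$lineage != "1") next
    c4 <- callSite4Taxon(unname(c(b, c3$ancestral)))
    expect_equal(c4$status, "called")
    expect_equal(c4$lineage, "1")
    expect_equal(c4$ancestral, c3$ancestral)
    expect_equal(c4$derived, c3$derived)
  }
})

test_that("all 12 directed changes pool into 6 complement-invariant categories", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- expand.grid(a = BASES, d = BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$d, ]
  want <- c(AG = "A/T->G/C", TC = "A/T->G/C", GA = "G/C->A/T",
            CT = "G/C->A/T", AC = "A/T->C/G", TG = "A/T->C/G",
            CA = "C/G->A/T", GT = "C/G->A/T", AT = "A/T->T/A",
            TA = "A/T->T/A", GC = "G/C->C/G", CG = "G/C->C/G")
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; d <- pairs$d[i]
    expect_equal(classifyDirection(a, d), unname(want[paste0(a, d)]))
    expect_equal(classifyDirection(a, d),
                 classifyDirection(comp[a], comp[d]))
  }
  expect_error(classifyDirection("A", "A"), "classification error")
})

test_that("gc content counts G and C at the selected sites", {
  expect_equal(gcContent("GGCC", 1:4), 1.0)
  expect_equal(gcContent("ATGC", 1:4), 0.5)
  expect_error(gcContent("ATGC", integer(0)), "undefined")
  set.seed(3)
  s <- paste(sample(BASES, 1000, TRUE), collapse = "")
  sites <- sort(sample(1000, 400))
  ch <- strsplit(s, "")[[1L]]
  expect_equal(gcContent(s, sites),
               mean(vapply(sites, function(i) ch[i] %in% c("G", "C"),
                           logical(1L))))
})

test_that("spectra tally forced calls and leave zero-substitution rows blank", {
  rows <- c(tmu = "GGGG", mouse = "AAAA", rat = "AAAA")
  p <- makePaln(rows)
  sp <- buildSpectrum(p, "3taxon")
  tmu <- sp[sp$species == "tmu", ]
  expect_equal(tmu$nSubs, 4L)
  expect_equal(tmu$pct_AT_GC, 100)
  expect_equal(sp[sp$species == "mouse", "nSubs"], 0L)
  expect_true(is.na(sp[sp$species == "mouse", "pct_AT_GC"]))
  expect_equal(sp[sp$species == "rat", "nSubs"], 0L)
  ## all rows share one analyzed column set
  expect_equal(unique(sp$nBases), 4L)
})

test_that("category counts conserve totals and per-gene rows sum to the pooled row", {
  set.seed(21)
  genes <- lapply(1:4, function(i) {
    n <- 120L
    anc <- sample(BASES, n, TRUE)
    mut <- function(x) {
      hit <- runif(n) < 0.12
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1L),
                       character(1L))
      x
    }
    rows <- c(tmu = paste(mut(anc), collapse = ""),
              mouse = paste(mut(anc), collapse = ""),
              rat = paste(mut(anc), collapse = ""))
    makePaln(rows, geneId = paste0("g", i))
  })
  cc <- concatenateAlignments(genes, "middle", "UTR+intron")
  pooled <- buildSpectrum(cc, "3taxon")
  perGene <- buildSpectrum(cc, "3taxon", grouping = "per_gene")
  catCols <- paste0("n_", c("AT_GC", "GC_AT", "AT_CG", "CG_AT",
                            "AT_TA", "GC_CG"))
  for (s in c("tmu", "mouse", "rat")) {
    pr <- pooled[pooled$species == s, ]
    expect_equal(sum(unlist(pr[catCols])), pr$nSubs)
    gr <- perGene[perGene$species == s, ]
    expect_equal(sum(gr$nSubs), pr$nSubs)
    expect_equal(sum(gr$nBases), pr$nBases)
  }
  ## percentages of every non-empty row sum to 100 within rounding
  nz <- pooled[pooled$nSubs > 0, ]
  pctCols <- sub("^n_", "pct_", catCols)
  for (i in seq_len(nrow(nz)))
    expect_lt(abs(sum(unlist(nz[i, pctCols])) - 100), 0.3)
})

test_that("spectrum counts agree with the simulator truth log at clean columns", {
  cfg <- symmetricConfig(seed = 404, noncodingLen = 3000L, nGenes = 2L)
  sim <- simulateStudy(cfg)
  for (gid in names(sim$genes)) {
    p <- sim$genes[[gid]]
    m <- do.call(rbind, strsplit(as.character(alignedSeqs(p)), ""))
    rownames(m) <- taxaNames(p)
    tr <- sim$truth[sim$truth$gene == gid, ]
    evCount <- table(factor(tr$pos, levels = seq_len(ncol(m))))
    ## columns hit by exactly one event, on a terminal ingroup branch
    single <- which(evCount == 1L)
    for (col in single) {
      ev <- tr[tr$pos == col, ]
      call <- callSite3Taxon(m[c("focal", "mouse", "rat"), col])
      if (ev$branch %in% c("focal", "mouse", "rat")) {
        expect_equal(call$status, "called")
        expect_equal(call$lineage, ev$branch)
        expect_equal(call$ancestral, ev$from)
        expect_equal(call$derived, ev$to)
      }
    }
    ## untouched columns are never called
    for (col in which(evCount == 0L)[1:50])
      expect_equal(callSite3Taxon(m[c("focal", "mouse", "rat"), col])$status,
                   "invariant")
  }
})

test_that("reverse-complementing every row leaves spectra invariant", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 150L
    anc <- sample(BASES, n, TRUE)
    mut <- function(x) {
      hit <- runif(n) < 0.1
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1L),
                       character(1L))
      x
    }
    rows <- c(tmu = paste(mut(anc), collapse = ""),
              mouse = paste(mut(anc), collapse = ""),
              rat = paste(mut(anc), collapse = ""))
    p <- makePaln(rows)
    fwd <- buildSpectrum(p, "3taxon")
    rev <- buildSpectrum(revcompPaln(p), "3taxon")
    pctCols <- grep("^pct_", colnames(fwd), value = TRUE)
    expect_equal(rev[, pctCols], fwd[, pctCols])
    expect_equal(rev$gcContent, fwd$gcContent)
    expect_equal(rev$nSubs, fwd$nSubs)
  }
})

test_that("CpG report recognizes deamination context and classes", {
  ## focal C->T before G: the CpG->TpG signature
  p1 <- makePaln(c(tmu = "ATGT", mouse = "ACGT", rat = "ACGT"))
  r1 <- cpgSpectrum(list(p1), "middle")
  tmu <- r1[r1$species == "tmu", ]
  expect_equal(tmu$nSubsInContext, 1L)
  expect_equal(tmu$fractionDeamination, 100)

  ## C->A at a CpG site: context substitution but not the deamination class
  p2 <- makePaln(c(tmu = "AAGT", mouse = "ACGT", rat = "ACGT"))
  r2 <- cpgSpectrum(list(p2), "middle")
  tmu2 <- r2[r2$species == "tmu", ]
  expect_equal(tmu2$nSubsInContext, 1L)
  expect_equal(tmu2$fractionDeamination, 0)

  ## G->A after C on the complementary strand reading: CpG->CpA
  p3 <- makePaln(c(tmu = "ACAT", mouse = "ACGT", rat = "ACGT"))
  r3 <- cpgSpectrum(list(p3), "middle")
  tmu3 <- r3[r3$species == "tmu", ]
  expect_equal(tmu3$nDeamination, 1L)
})

test_that("a stronger CpG multiplier raises the deamination fraction", {
  frac <- vapply(c(1, 10), function(mult) {
    cfg <- simConfig(seed = 77,
                     regions = data.frame(name = "middle", nGenes = 4L,
                                          orfLen = 0L, noncodingLen = 12500L,
                                          lambdaATGC = 1, lambdaGCAT = 1,
                                          rootGC = 0.5),
                     cpgMultiplier = mult)
    sim <- simulateStudy(cfg)
    rep <- cpgSpectrum(sim$genes, "middle")
    rep$fractionDeamination[rep$species == "focal"]
  }, numeric(1L))
  expect_gt(frac[2L], frac[1L])
})

test_that("the spectrum table writes the standard layout with 1-decimal rounding", {
  rows <- c(tmu = "GGGG", mouse = "AAAA", rat = "AAAA")
  sp <- buildSpectrum(makePaln(rows), "3taxon")
  out <- withr::local_tempfile(fileext = ".tsv")
  writeSpectrumTable(sp, out)
  tab <- utils::read.delim(out, check.names = FALSE,
                           colClasses = "character")
  expect_equal(colnames(tab)[1:7],
               c("Species", "Site", "Genome category", "No. of genes",
                 "No. of bases", "GC content", "No. of substitutions"))
  expect_equal(tab[tab$Species == "tmu", "A/T->G/C (%)"], "100.0")
  expect_equal(tab[tab$Species == "mouse", "A/T->G/C (%)"], "")
})
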