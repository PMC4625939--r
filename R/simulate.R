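## Synthetic-data generator: alignments, gametolog panels, truth logs.

#' HKY-style rate matrix
#'
#' Off-diagonal substitution rates with transition/transversion ratio
#' `kappa`, scaled so every base's total leave rate is 1: branch lengths are
#' then expected substitutions per site (before context effects).
#'
#' @param kappa transition/transversion rate ratio.
#' @return 4x4 numeric matrix, rows/cols A, C, G, T, zero diagonal.
#' @export
hkyRates <- function(kappa = 2) {
  stopifnot(kappa >= 0)
  Q <- matrix(1, 4L, 4L, dimnames = list(.BASES, .BASES))
  diag(Q) <- 0
  Q["A", "G"] <- Q["G", "A"] <- Q["C", "T"] <- Q["T", "C"] <- kappa
  Q / (kappa + 2)
}

#' Apply direction-bias multipliers to a rate matrix
#'
#' Multiplies the A/T->G/C transition rates (A->G, T->C) by `lambdaATGC`
#' and the G/C->A/T transition rates (G->A, C->T) by `lambdaGCAT`; this is
#' how region-specific GC-biased gene conversion (or its loss) is emulated
#' on the focal branch.
#'
#' @param Q 4x4 rate matrix (rows/cols A, C, G, T).
#' @param lambdaATGC,lambdaGCAT non-negative multipliers.
#' @return the modified rate matrix.
#' @export
biasRates <- function(Q, lambdaATGC = 1, lambdaGCAT = 1) {
  stopifnot(lambdaATGC >= 0, lambdaGCAT >= 0)
  Q["A", "G"] <- Q["A", "G"] * lambdaATGC
  Q["T", "C"] <- Q["T", "C"] * lambdaATGC
  Q["G", "A"] <- Q["G", "A"] * lambdaGCAT
  Q["C", "T"] <- Q["C", "T"] * lambdaGCAT
  Q
}

#' Simulation configuration
#'
#' Defaults mirror the comparative study design this package analyzes:
#' three genome regions whose gene counts, coding/noncoding lengths and
#' G+C composition follow the published per-region totals; per-lineage
#' branch lengths calibrated to the observed noncoding substitution loads;
#' a CpG transition multiplier of 10 (methylated CpG deamination is more
#' than an order of magnitude faster than other transitions); and
#' direction-bias multipliers giving the focal branch an A/T->G/C excess in
#' the peritelomeric region and a G/C->A/T excess in the pericentromeric
#' region.
#'
#' @param seed mandatory integer seed; all randomness flows from it.
#' @param taxa four taxon labels, ordered `(focal, sister, third, outgroup)`
#'   on the fixed topology `((focal, sister), third, outgroup)`.
#' @param tree named branch lengths (expected substitutions/site):
#'   `focal`, `mouse`, `internal`, `rat`, `outgroup`.
#' @param regions `data.frame` with columns `name`, `nGenes`, `orfLen`
#'   (multiple of 3), `noncodingLen`, `lambdaATGC`, `lambdaGCAT`, `rootGC`.
#' @param cpgMultiplier fold-increase of C->T at CpG and G->A at CpG.
#' @param kappa transition/transversion ratio of the base rate matrix.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(seed,
                      taxa = c("focal", "mouse", "rat", "outgroup"),
                      tree = c(focal = 0.065, mouse = 0.055,
                               internal = 0.03, rat = 0.07,
                               outgroup = 0.25),
                      regions = data.frame(
                        name = c("peritelomeric", "middle", "pericentromeric"),
                        nGenes = c(51L, 29L, 40L),
                        orfLen = c(1338L, 1614L, 1362L),
                        noncodingLen = c(6713L, 11963L, 14404L),
                        lambdaATGC = c(2, 1, 1),
                        lambdaGCAT = c(1, 1, 1.5),
                        rootGC = c(0.524, 0.482, 0.455),
                        stringsAsFactors = FALSE),
                      cpgMultiplier = 10,
                      kappa = 2) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory in the simulation configuration")
  stopifnot(length(taxa) == 4L, !anyDuplicated(taxa))
  need <- c("focal", "mouse", "internal", "rat", "outgroup")
  if (!all(need %in% names(tree)) || any(tree < 0))
    stop("tree must name non-negative branch lengths: ",
         paste(need, collapse = ", "))
  stopifnot(all(c("name", "nGenes", "orfLen", "noncodingLen", "lambdaATGC",
                  "lambdaGCAT", "rootGC") %in% colnames(regions)))
  if (any(regions$orfLen %% 3L != 0L))
    stop("orfLen must be a multiple of 3")
  if (any(regions$lambdaATGC < 0) || any(regions$lambdaGCAT < 0))
    stop("bias multipliers must be non-negative")
  if (any(regions$rootGC < 0) || any(regions$rootGC > 1))
    stop("rootGC must be in [0, 1]")
  if (cpgMultiplier < 0 || kappa < 0)
    stop("rates and multipliers must be non-negative")
  structure(list(seed = as.integer(seed), taxa = taxa, tree = tree,
                 regions = regions, cpgMultiplier = cpgMultiplier,
                 kappa = kappa),
            class = "SimConfig")
}

#' Evolve a sequence along one branch
#'
#' Exact continuous-time simulation: exponential waiting times over the
#' total rate, with the per-site rate recomputed after every event because
#' CpG context makes neighboring sites interact.  Codon positions 1 and 2
#' are frozen when a `codonPos` annotation is supplied, and third-position
#' changes creating a stop codon are forbidden when `forbidStop = TRUE`.
#' Randomness comes from R's RNG stream (use `set.seed()` for
#' reproducibility).
#'
#' @param seq starting sequence (character string or vector of bases).
#' @param branchLength expected substitutions/site (at unit total rate).
#' @param rates 4x4 rate matrix, e.g. [hkyRates()] (+ [biasRates()]).
#' @param cpgMultiplier CpG-context transition multiplier.
#' @param codonPos integer vector (0 = unconstrained, 1/2/3 codon
#'   positions), or `NULL` for all-unconstrained.
#' @param forbidStop disallow third-position changes creating TAA/TAG/TGA.
#' @return list with `seq` (character string after evolution) and `events`
#'   (`data.frame`: `pos` 1-based, `from`, `to`, `cpg` context flag, in
#'   event order).
#' @export
evolveBranch <- function(seq, branchLength, rates = hkyRates(),
                         cpgMultiplier = 1, codonPos = NULL,
                         forbidStop = TRUE) {
  ch <- if (length(seq) == 1L && nchar(seq[1L]) > 1L)
    strsplit(seq, "", fixed = TRUE)[[1L]]
  else as.character(seq)
  codes <- match(ch, .BASES)
  if (anyNA(codes)) stop("sequence must contain only A, C, G, T")
  if (is.null(codonPos)) codonPos <- integer(length(codes))
  stopifnot(length(codonPos) == length(codes))
  res <- cpp_evolve_branch(codes - 1L, branchLength, rates, cpgMultiplier,
                           as.integer(codonPos), forbidStop)
  list(seq = paste(.BASES[res$seq + 1L], collapse = ""),
       events = data.frame(pos = res$pos, from = .BASES[res$from + 1L],
                           to = .BASES[res$to + 1L], cpg = res$cpg,
                           stringsAsFactors = FALSE))
}

## draw a root sequence: noncoding flanks around an ORF, stop-free codons
.drawRootGene <- function(orfLen, noncodingLen, gc) {
  nc1 <- noncodingLen %/% 2L
  nc2 <- noncodingLen - nc1
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(n) sample(.BASES, n, replace = TRUE, prob = p)
  orf <- draw(orfLen)
  if (orfLen > 0L) {
    repeat {
      cods <- vapply(seq_len(orfLen %/% 3L), function(k)
        paste(orf[(3L * k - 2L):(3L * k)], collapse = ""), character(1L))
      bad <- which(cods %in% .stopCodons)
      if (!length(bad)) break
      for (k in bad) orf[(3L * k - 2L):(3L * k)] <- draw(3L)
    }
  }
  list(seq = c(draw(nc1), orf, draw(nc2)),
       codonPos = c(integer(nc1), rep(1:3, length.out = orfLen),
                    integer(nc2)))
}

#' Simulate the full comparative study design
#'
#' Draws a root sequence per gene at the region's G+C composition, evolves
#' it along the fixed topology `((focal, mouse), rat, outgroup)` with
#' region-specific direction bias on the focal branch, and returns fully
#' annotated per-gene alignments plus a replayable truth log of every
#' substitution event.  Coding partitions freeze codon positions 1-2 and
#' forbid stop-creating third-position changes, so all observed coding
#' changes are third-position and frames stay intact.
#'
#' @param config a [simConfig()] object.
#' @return list with `genes` (named list of
#'   [PartitionedAlignment-class]), `truth` (`data.frame` of events:
#'   `region`, `gene`, `branch`, `pos`, `from`, `to`, `cpg`), and `roots`
#'   (named list of root sequences for replay).
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  taxa <- config$taxa
  tr <- config$tree
  Q0 <- hkyRates(config$kappa)
  genes <- list(); events <- list(); roots <- list()
  for (r in seq_len(nrow(config$regions))) {
    reg <- config$regions[r, ]
    Qfocal <- biasRates(Q0, reg$lambdaATGC, reg$lambdaGCAT)
    for (g in seq_len(reg$nGenes)) {
      gid <- sprintf("%s_g%02d", reg$name, g)
      root <- .drawRootGene(reg$orfLen, reg$noncodingLen, reg$rootGC)
      cp <- root$codonPos
      ev <- function(seqv, len, Q, branch) {
        res <- cpp_evolve_branch(match(seqv, .BASES) - 1L, len, Q,
                                 config$cpgMultiplier, cp, TRUE)
        list(seq = .BASES[res$seq + 1L],
             events = if (length(res$pos))
               data.frame(region = reg$name, gene = gid, branch = branch,
                          pos = res$pos, from = .BASES[res$from + 1L],
                          to = .BASES[res$to + 1L], cpg = res$cpg,
                          stringsAsFactors = FALSE)
             else NULL)
      }
      anc <- ev(root$seq, tr[["internal"]], Q0, "internal")
      foc <- ev(anc$seq, tr[["focal"]], Qfocal, "focal")
      mou <- ev(anc$seq, tr[["mouse"]], Q0, "mouse")
      rat <- ev(root$seq, tr[["rat"]], Q0, "rat")
      out <- ev(root$seq, tr[["outgroup"]], Q0, "outgroup")
      for (e in list(anc, foc, mou, rat, out))
        if (!is.null(e$events)) events[[length(events) + 1L]] <- e$events
      rows <- vapply(list(foc$seq, mou$seq, rat$seq, out$seq),
                     paste, character(1L), collapse = "")
      seqs <- Biostrings::DNAStringSet(rows)
      names(seqs) <- taxa
      ncols <- length(root$seq)
      cols <- S4Vectors::DataFrame(
        region = rep(reg$name, ncols),
        siteClass = ifelse(cp > 0L, "ORF", "UTR+intron"),
        codonPos = ifelse(cp > 0L, cp, NA_integer_),
        masked = rep(FALSE, ncols),
        geneId = rep(gid, ncols), origColumn = seq_len(ncols))
      genes[[gid]] <- new("PartitionedAlignment", geneId = gid, seqs = seqs,
                          focal = taxa[1L], columns = cols)
      roots[[gid]] <- paste(root$seq, collapse = "")
    }
  }
  truth <- if (length(events)) do.call(rbind, events) else
    data.frame(region = character(0), gene = character(0),
               branch = character(0), pos = integer(0), from = character(0),
               to = character(0), cpg = logical(0))
  list(genes = genes, truth = truth, roots = roots, config = config)
}

#' Replay truth-log events to reconstruct a leaf sequence
#'
#' Applies the logged substitution events along the root-to-leaf path in
#' event order; the result must equal the simulated leaf exactly, which is
#' the replayability contract of the truth log.
#'
#' @param sim result of [simulateStudy()].
#' @param gene gene identifier.
#' @param taxon one of the four configured taxa.
#' @return the reconstructed leaf sequence (character string).
#' @export
replayLeaf <- function(sim, gene, taxon) {
  taxa <- sim$config$taxa
  path <- switch(match(taxon, taxa),
                 c("internal", "focal"), c("internal", "mouse"),
                 "rat", "outgroup")
  if (is.null(path)) stop("unknown taxon: ", taxon)
  s <- strsplit(sim$roots[[gene]], "", fixed = TRUE)[[1L]]
  ev <- sim$truth[sim$truth$gene == gene & sim$truth$branch %in% path, ,
                  drop = FALSE]
  ## rows are stored in simulation order: internal-branch events first
  ev <- ev[order(match(ev$branch, path)), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    if (s[ev$pos[i]] != ev$from[i])
      stop("truth log inconsistent at ", gene, " position ", ev$pos[i])
    s[ev$pos[i]] <- ev$to[i]
  }
  paste(s, collapse = "")
}

#' Simulate a sexed gametolog resequencing panel
#'
#' Generates a neo-X haplotype shared by every individual and a diverged
#' neo-Y haplotype carrying planted SNVs and indels.  Females are neo-X
#' homozygotes; males are neo-X/neo-Y heterozygotes whose consensus encodes
#' mismatches as IUPAC ambiguity codes and length variants as the neo-Y
#' gap signature (see [mergeHaplotypes()]).  An optional per-base error
#' rate injects spurious ambiguity codes.
#'
#' @param nMales,nFemales panel sizes (study design: two-to-six males and
#'   four females).
#' @param locusLen ungapped neo-X locus length.
#' @param nSnvs number of planted neo-Y SNVs.
#' @param indels `data.frame` with columns `kind` (`"ins"`/`"del"`) and
#'   `length`, one planted indel per row; `NULL` for none.
#' @param errorRate per-base probability of a spurious ambiguity code.
#' @param seed mandatory integer seed.
#' @param gc neo-X G+C fraction.
#' @param locusId locus label.
#' @return list with `panel` (a [GenotypePanel-class]) and `truth`
#'   (planted `snvs` and `indels` in 0-based aligned coordinates, plus the
#'   two haplotypes).
#' @export
simulateGametologPanel <- function(nMales = 6L, nFemales = 4L,
                                   locusLen = 5000L, nSnvs = 20L,
                                   indels = NULL, errorRate = 0,
                                   seed, gc = 0.45,
                                   locusId = "locus") {
  if (missing(seed)) stop("seed is mandatory")
  if (nSnvs > locusLen) stop("nSnvs must not exceed locusLen")
  set.seed(seed)
  if (is.null(indels))
    indels <- data.frame(kind = character(0), length = integer(0))
  stopifnot(all(indels$kind %in% c("ins", "del")), all(indels$length >= 1L))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  neoX <- sample(.BASES, locusLen, replace = TRUE, prob = p)

  ## place SNVs and indel anchors without collision (interior positions so
  ## indel runs have flanking anchors); resample on collision
  nIndel <- nrow(indels)
  maxLen <- if (nIndel) max(indels$length) else 0L
  repeat {
    pos <- sample(2:(locusLen - maxLen - 1L), nSnvs + nIndel)
    snvPos <- sort(pos[seq_len(nSnvs)])
    indelPos <- pos[nSnvs + seq_len(nIndel)]
    ## footprint includes one flanking base so runs never touch or merge
    foot <- lapply(seq_len(nIndel), function(i)
      (indelPos[i] - 1L):(indelPos[i] + indels$length[i]))
    allFoot <- unlist(foot)
    ok <- !anyDuplicated(allFoot) && !any(snvPos %in% allFoot)
    if (ok) break
  }
  snvAlt <- vapply(neoX[snvPos],
                   function(b) sample(setdiff(.BASES, b), 1L), character(1L))

  ## build the aligned haplotypes left to right
  isDel <- logical(locusLen)
  insAfter <- vector("list", locusLen)
  if (nIndel) for (i in seq_len(nIndel)) {
    if (indels$kind[i] == "del")
      isDel[indelPos[i]:(indelPos[i] + indels$length[i] - 1L)] <- TRUE
    else
      insAfter[[indelPos[i]]] <- sample(.BASES, indels$length[i],
                                        replace = TRUE, prob = p)
  }
  hx <- hy <- character(0)
  snvAligned <- integer(nSnvs)
  indelAligned <- integer(nIndel); indelKind <- character(nIndel)
  indelTrack <- integer(0)
  for (i in seq_len(locusLen)) {
    hx <- c(hx, neoX[i])
    yBase <- if (isDel[i]) "-" else if (i %in% snvPos)
      snvAlt[match(i, snvPos)] else neoX[i]
    hy <- c(hy, yBase)
    if (i %in% snvPos) snvAligned[match(i, snvPos)] <- length(hx) - 1L
    if (isDel[i] && (i == 1L || !isDel[i - 1L])) {
      k <- which(vapply(seq_len(nIndel), function(j)
        indels$kind[j] == "del" && indelPos[j] == i, logical(1L)))
      indelAligned[k] <- length(hx) - 1L; indelKind[k] <- "del"
    }
    ins <- insAfter[[i]]
    if (!is.null(ins)) {
      k <- which(vapply(seq_len(nIndel), function(j)
        indels$kind[j] == "ins" && indelPos[j] == i, logical(1L)))
      indelAligned[k] <- length(hx); indelKind[k] <- "ins"
      hx <- c(hx, rep("-", length(ins)))
      hy <- c(hy, ins)
    }
  }
  hapX <- paste(hx, collapse = ""); hapY <- paste(hy, collapse = "")
  maleSeq <- mergeHaplotypes(hapX, hapY)

  addErrors <- function(s) {
    if (errorRate <= 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(ch %in% .BASES & stats::runif(length(ch)) < errorRate)
    for (i in hit)
      ch[i] <- .iupacCode(c(ch[i], sample(setdiff(.BASES, ch[i]), 1L)))
    paste(ch, collapse = "")
  }
  rows <- c(vapply(seq_len(nMales), function(i) addErrors(maleSeq),
                   character(1L)),
            vapply(seq_len(nFemales), function(i) addErrors(hapX),
                   character(1L)))
  ids <- c(sprintf("m%02d", seq_len(nMales)),
           sprintf("f%02d", seq_len(nFemales)))
  seqs <- Biostrings::DNAStringSet(rows); names(seqs) <- ids
  panel <- GenotypePanel(locusId, seqs,
                         c(rep("M", nMales), rep("F", nFemales)))
  truthSnvs <- data.frame(pos0 = snvAligned, neoX = neoX[snvPos],
                          neoY = snvAlt, stringsAsFactors = FALSE)
  truthIndels <- if (nIndel)
    data.frame(pos0 = indelAligned, kind = indels$kind,
               length = indels$length, stringsAsFactors = FALSE)
  else data.frame(pos0 = integer(0), kind = character(0),
                  length = integer(0))
  list(panel = panel,
       truth = list(snvs = truthSnvs[order(truthSnvs$pos0), ],
                    indels = truthIndels,
                    hapX = hapX, hapY = hapY))
}
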