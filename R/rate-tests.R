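## Tajima relative rate test and counting-based per-branch dN/dS.

#' Lineage-unique difference counts against an outgroup
#'
#' Per-site pattern tally over three sequences: a site where A differs while
#' B equals the outgroup is unique to A, and symmetrically for B.  Sites
#' where all three agree, where A and B share a state different from the
#' outgroup, or where all three differ contribute to neither count.  Sites
#' with a gap or unresolved base in any sequence are dropped (complete
#' deletion).
#'
#' @param seqA,seqB,outgroup sequences (character strings, `DNAString`, or
#'   character vectors), equal length.
#' @param sites optional 1-based site indices to restrict to.
#' @return named integer vector `c(nUniqueA = , nUniqueB = )`.
#' @export
uniqueDifferenceCounts <- function(seqA, seqB, outgroup, sites = NULL) {
  tochar <- function(x) {
    if (length(x) == 1L && nchar(x[1L]) > 1L)
      strsplit(as.character(x), "", fixed = TRUE)[[1L]]
    else as.character(x)
  }
  a <- tochar(seqA); b <- tochar(seqB); o <- tochar(outgroup)
  if (length(a) != length(b) || length(a) != length(o))
    stop("identity error: sequences differ in length")
  if (!is.null(sites)) { a <- a[sites]; b <- b[sites]; o <- o[sites] }
  ok <- .isResolved(a) & .isResolved(b) & .isResolved(o)
  a <- a[ok]; b <- b[ok]; o <- o[ok]
  c(nUniqueA = sum(a != b & b == o),
    nUniqueB = sum(b != a & a == o))
}

#' Tajima's relative rate test
#'
#' Chi-squared test (1 df) of the equality of lineage-unique substitution
#' counts in two sequences against a shared outgroup:
#' `chi2 = (nA - nB)^2 / (nA + nB)`.  Equal counts give statistic 0 and
#' p = 1; two zero counts make the test undefined (degenerate result with
#' `NA` statistic).
#'
#' @param nUniqueA,nUniqueB non-negative lineage-unique counts, e.g. from
#'   [uniqueDifferenceCounts()].
#' @return list with `nUniqueA`, `nUniqueB`, `chiSquare`, `pValue`,
#'   `degenerate`.
#' @examples
#' tajimaRRT(30, 10)  # chi2 = 10, p ~ 0.00157
#' @export
tajimaRRT <- function(nUniqueA, nUniqueB) {
  if (nUniqueA < 0 || nUniqueB < 0)
    stop("parameter error: counts must be non-negative")
  tot <- nUniqueA + nUniqueB
  if (tot == 0)
    return(list(nUniqueA = nUniqueA, nUniqueB = nUniqueB,
                chiSquare = NA_real_, pValue = NA_real_, degenerate = TRUE))
  chi2 <- (nUniqueA - nUniqueB)^2 / tot
  list(nUniqueA = nUniqueA, nUniqueB = nUniqueB, chiSquare = chi2,
       pValue = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       degenerate = FALSE)
}

## enumerate shortest mutational paths between two codons along the given
## changed positions; returns average fractional (syn, nonsyn) counts over
## paths that avoid intermediate stop codons, or NULL if none exists
.pathAverage <- function(anc, der) {
  diffPos <- which(anc != der)
  k <- length(diffPos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) list(diffPos)
  else if (k == 2L) list(diffPos, rev(diffPos))
  else {
    out <- list()
    for (i in 1:3) for (j in setdiff(1:3, i))
      out[[length(out) + 1L]] <- diffPos[c(i, j, setdiff(1:3, c(i, j)))]
    out
  }
  acc <- c(syn = 0, nonsyn = 0); nPaths <- 0L
  for (ord in perms) {
    cur <- anc; steps <- c(syn = 0, nonsyn = 0); ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- der[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (to %in% .stopCodons && to != paste(der, collapse = "")) {
        ok <- FALSE; break   # path through an intermediate stop: discarded
      }
      if (.translateCodon(from) == .translateCodon(to))
        steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + steps; nPaths <- nPaths + 1L }
  }
  if (nPaths == 0L) return(NULL)
  acc / nPaths
}

#' Assign codon changes to the neo-X and neo-Y branches
#'
#' Over an in-frame codon alignment of the two gametologs and an autosomal
#' outgroup, each differing position is polarized by the lineage-unique
#' logic of [uniqueDifferenceCounts()]: the gametolog disagreeing with the
#' outgroup-supported state carries the change.  Per branch and codon, the
#' changes are classified synonymous/nonsynonymous by translation, with
#' multi-change codons averaged over all shortest mutational paths
#' (Nei-Gojobori pathway averaging, stop-traversing paths discarded).
#' Codons containing a gap or unresolved base, an observed stop, or a
#' position where all three sequences differ are skipped and tallied.
#'
#' @param neoX,neoY,outgroup in-frame coding sequences, equal length, a
#'   multiple of 3.
#' @return list with per-branch `data.frame`s (`neoX`, `neoY`: codon index,
#'   fractional syn/nonsyn counts), the ancestral codon string
#'   `ancestral`, and `skipped` tallies.
#' @export
assignBranchChanges <- function(neoX, neoY, outgroup) {
  tochar <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]
  x <- tochar(neoX); y <- tochar(neoY); o <- tochar(outgroup)
  if (length(x) != length(y) || length(x) != length(o))
    stop("identity error: sequences differ in length")
  if (length(x) %% 3L != 0L)
    stop("coding alignment length must be a multiple of 3")
  nCodon <- length(x) %/% 3L
  skipped <- c(unresolved = 0L, unpolarized = 0L, stop_codon = 0L,
               no_valid_path = 0L)
  ancC <- rep("---", nCodon)
  recX <- list(); recY <- list()
  for (k in seq_len(nCodon)) {
    ii <- (3L * k - 2L):(3L * k)
    cx <- x[ii]; cy <- y[ii]; co <- o[ii]
    if (!all(.isResolved(c(cx, cy, co)))) {
      skipped["unresolved"] <- skipped["unresolved"] + 1L; next
    }
    anc <- character(3L); bad <- FALSE
    for (p in 1:3) {
      if (cx[p] == cy[p]) anc[p] <- cx[p]
      else if (cx[p] == co[p]) anc[p] <- cx[p]
      else if (cy[p] == co[p]) anc[p] <- cy[p]
      else bad <- TRUE
    }
    if (bad) { skipped["unpolarized"] <- skipped["unpolarized"] + 1L; next }
    codX <- paste(cx, collapse = ""); codY <- paste(cy, collapse = "")
    codA <- paste(anc, collapse = "")
    if (any(c(codX, codY, codA) %in% .stopCodons)) {
      skipped["stop_codon"] <- skipped["stop_codon"] + 1L; next
    }
    ancC[k] <- codA
    okCodon <- TRUE; tmp <- list()
    for (br in c("X", "Y")) {
      der <- if (br == "X") cx else cy
      counts <- .pathAverage(anc, der)
      if (is.null(counts)) { okCodon <- FALSE; break }
      if (sum(counts) > 0)
        tmp[[br]] <- data.frame(codon = k, syn = counts[["syn"]],
                                nonsyn = counts[["nonsyn"]])
    }
    if (!okCodon) {
      skipped["no_valid_path"] <- skipped["no_valid_path"] + 1L
      ancC[k] <- "---"
      next
    }
    if (!is.null(tmp$X)) recX[[length(recX) + 1L]] <- tmp$X
    if (!is.null(tmp$Y)) recY[[length(recY) + 1L]] <- tmp$Y
  }
  empty <- data.frame(codon = integer(0), syn = numeric(0),
                      nonsyn = numeric(0))
  list(neoX = if (length(recX)) do.call(rbind, recX) else empty,
       neoY = if (length(recY)) do.call(rbind, recY) else empty,
       ancestral = ancC, skipped = skipped)
}

#' Nei-Gojobori synonymous/nonsynonymous site counts
#'
#' For each codon, the synonymous site count at a position is the fraction
#' of its three possible base changes that preserve the amino acid (changes
#' to stop codons count as nonsynonymous), summed over positions; so
#' `N + S = 3` exactly for every sense codon.
#'
#' @param codons character vector of sense codons (use `"---"` to skip).
#' @return list with totals `N`, `S` and the per-codon matrix `perCodon`.
#' @examples
#' ng86Sites("TTT")$S  # 1/3
#' @export
ng86Sites <- function(codons) {
  perCodon <- matrix(0, nrow = length(codons), ncol = 2L,
                     dimnames = list(NULL, c("N", "S")))
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (cod == "---" || is.na(cod)) next
    ch <- strsplit(cod, "", fixed = TRUE)[[1L]]
    if (!all(.isResolved(ch)) || cod %in% .stopCodons) next
    aa <- .translateCodon(cod)
    s <- 0
    for (p in 1:3) for (b in setdiff(.BASES, ch[p])) {
      mut <- ch; mut[p] <- b
      mcod <- paste(mut, collapse = "")
      if (!(mcod %in% .stopCodons) && .translateCodon(mcod) == aa)
        s <- s + 1 / 3
    }
    perCodon[i, "S"] <- s
    perCodon[i, "N"] <- 3 - s
  }
  list(N = sum(perCodon[, "N"]), S = sum(perCodon[, "S"]),
       perCodon = perCodon)
}

#' Per-branch dN/dS by counting
#'
#' Combines branch-assigned change counts with Nei-Gojobori site counts on
#' the ancestral sequence: `pN = n/N`, `pS = s/S`, `omega = pN/pS`.  Raw
#' proportions by default; `jukesCantor = TRUE` applies the standard
#' multiple-hit correction `-3/4 log(1 - 4p/3)` to both proportions
#' (erroring when a proportion is 3/4 or more).  `omega` is `NA` with
#' `omegaDefined = FALSE` when no synonymous change was assigned.
#'
#' @param changes one branch's `data.frame` from [assignBranchChanges()].
#' @param ancestral ancestral codon vector from the same call.
#' @param branch branch label carried into the result.
#' @param jukesCantor apply Jukes-Cantor correction to the proportions.
#' @return one-row `data.frame` with `branch`, `NSites`, `SSites`,
#'   `nChanges`, `sChanges`, `pN`, `pS`, `omega`, `omegaDefined`.
#' @export
ng86BranchDnds <- function(changes, ancestral, branch = NA_character_,
                           jukesCantor = FALSE) {
  sites <- ng86Sites(ancestral)
  n <- sum(changes$nonsyn); s <- sum(changes$syn)
  pN <- if (sites$N > 0) n / sites$N else NA_real_
  pS <- if (sites$S > 0) s / sites$S else NA_real_
  if (jukesCantor) {
    jc <- function(p) {
      if (is.na(p)) return(NA_real_)
      if (p >= 0.75) stop("Jukes-Cantor correction undefined for p >= 3/4")
      -0.75 * log(1 - 4 * p / 3)
    }
    pN <- jc(pN); pS <- jc(pS)
  }
  defined <- !is.na(pS) && s > 0
  data.frame(branch = branch, NSites = sites$N, SSites = sites$S,
             nChanges = n, sChanges = s, pN = pN, pS = pS,
             omega = if (defined) pN / pS else NA_real_,
             omegaDefined = defined, stringsAsFactors = FALSE)
}
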