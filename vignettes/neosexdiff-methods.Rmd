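---
title: "Methods: substitution-direction spectra and gametolog divergence"
author: "neosexdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substitution-direction spectra and gametolog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and design choices behind
`neosexdiff`, in the spirit of a methods supplement: what each statistic
assumes, why the defaults are what they are, and what the bundled simulator
does and does not emulate.

## The scientific setting

Recombination shapes base composition through GC-biased gene conversion
(gBGC): heteroduplex repair during meiotic recombination favors G/C alleles,
so chromosome regions with high crossover rates accumulate an excess of
A/T→G/C substitutions and drift toward GC-richness, while regions where
recombination has been suppressed drift the other way. On young neo-sex
chromosomes this yields a readable map of recombination activity: a
peritelomeric segment that still recombines (a nascent pseudoautosomal
region) should show an A/T→G/C excess on the focal lineage, whereas a
pericentromeric segment where X–Y recombination has ceased should show a
G/C→A/T excess and incipient neo-X/neo-Y divergence — male-specific
heterozygosity, an accelerated neo-Y rate, and eventually degenerative
lesions such as frameshifts.

## Parsimony direction assignment

**Three taxa.** For a column with resolved bases in the focal species and
two relatives, exactly one taxon differing from the base shared by the
other two is interpreted as a substitution on that taxon's terminal branch,
from the shared (ancestral) base to the odd (derived) base. Columns with
three distinct bases cannot be polarized and are excluded; columns with all
bases equal are invariant. This is the classical unrooted
maximum-parsimony argument and is exact when at most one change hit the
column. Its known artifact: a change on the internal branch joining the
focal species and its sister appears as a derived state shared by those
two, and is mis-polarized onto the third lineage.

**Four taxa.** Adding an outgroup on the fixed topology
`((focal, sister), third, outgroup)` removes that artifact. The engine
scores all 16 internal-state assignments (exhaustive Fitch parsimony on the
two internal nodes) and calls a substitution only when *every*
most-parsimonious reconstruction places exactly one change on the same
terminal branch with the same ancestral and derived state. Changes whose
unique placement is the internal branch, and all ambiguous patterns, are
excluded — a deliberately conservative rule that matches the 3-taxon logic
(when the outgroup agrees with the shared allele, the two engines agree on
every focal call; this is tested exhaustively). A unique placement on the
outgroup terminal is reported with the outgroup's label; spectra ignore it,
so the convention is invisible to every downstream tally.

Both engines are verified against independently written exhaustive
enumeration oracles over all 64 (3-taxon) and 256 (4-taxon) resolved
columns. The vectorized column caller used by `buildSpectrum()` is a lookup
table *generated by the scalar engines themselves*, so it cannot drift from
them.

**Direction categories.** The 12 directed base changes pool into 6
strand-symmetric categories (A→G and T→C are both A/T→G/C, and so on); the
map is invariant under complementing both bases, which makes every spectrum
strand-invariant — reverse-complementing all rows of an alignment leaves
the six percentages and the G+C content unchanged (tested on random
fixtures).

## Site accounting and masking

* Coordinates in all external formats (partition metadata, BED masks,
  simulator truth logs) are 0-based half-open on the focal species'
  ungapped sequence; human-readable reports are 1-based. In-memory R
  column indices follow R's native 1-based convention.
* The "ORF" site class is operationalized as **third codon positions
  only** — the near-neutral coding site class — with codon positions
  assigned by walking the focal species' non-gap sites through each
  declared ORF interval (GFF-style phase; split intervals must continue
  the frame, which is validated).
* Any column with a gap, `N`, or IUPAC ambiguity in a taxon used by the
  current comparison is masked: parsimony needs every analyzed taxon
  resolved. Because of this rule, the reported "number of bases" is both
  the count of filtered alignment columns and the count of focal non-gap
  sites — the two definitions coincide by construction. 3-taxon and
  4-taxon runs can therefore analyze different column sets; each mode
  reports its own base counts, and all species rows within one comparison
  share a single filtered column set.
* Repeat and unalignable-region exclusion is delegated to a user-supplied
  BED mask: no repeat detector is built in, because no specific
  tool/threshold generalizes across inputs.
* The exclusion log written by `runSpectrum()` reconciles exactly:
  masked + ORF positions 1–2 + analyzed third positions + analyzed
  noncoding = total columns, per region.

## CpG-deamination context

Methylated CpG dinucleotides deaminate to TpG/CpA at more than ten times
the rate of other transitions, which can mimic or mask gBGC signals. The
CpG report therefore restricts noncoding parsimony calls to sites preceded
by C or followed by G and reports the percentage that are C→T-before-G or
G→A-after-C. Context is evaluated on the focal lineage's own sequence with
the ancestral allele restored at the called column, because deamination
acts on the pre-substitution state; neighbors are the *physical* adjacent
columns of the gene alignment (never adjacent columns of a concatenation,
which would splice unrelated sites together — this is why `cpgSpectrum()`
takes the per-gene alignments rather than the concatenated selection).
Calls whose informative neighbors are gapped or unresolved, with no
qualifying neighbor on the other side, are excluded and tallied.

## Male-specific variants and gametologs

Males are modeled as neo-X/neo-Y heterozygotes whose direct Sanger
consensus shows IUPAC double-peak codes; females are neo-X homozygotes. A
position is called male-specific when **every** male shows a signature
consistent with one shared variant allele — the two-base code containing
the female base, or the plain variant base, since PCR can amplify one
gametolog preferentially — and **every** female shows the same unambiguous
homozygous base. Conflicting male variants are reported as
polymorphic-unclassified, never called. Length variants use the gap
signature: a run of columns where all males show the neo-Y gap state and
all females the neo-X state becomes one indel call. This is one plausible
operationalization of how superimposed Sanger traces manifest for
heterozygous length variants; a trace-level model is out of scope.

The minimum panel accepted for calling is 2 males + 1 female; reports
record the actual panel sizes so users can filter at stricter designs
(the motivating study used two-to-six males and four females). The
error tolerance is zero by default — every male must support — with an
optional per-site male-support fraction for error-tolerant scans.

ORF integrity flags (i) indel runs relative to the aligned partner
gametolog whose length is not a multiple of 3 (frameshifts) and (ii)
premature stop codons in the declared frame. A gene flagged frameshifted is
excluded from combined coding-rate rows but keeps contributing its
noncoding sites, mirroring how degenerate gametologs are handled in
comparative analyses.

## Rate tests

**Tajima's relative rate test** compares lineage-unique substitution
counts of two sequences against a shared outgroup:
χ² = (n_A − n_B)²/(n_A + n_B) on 1 df, upper tail. Sites with any gap or
unresolved base are dropped (complete deletion across the three
sequences — the handling assumed for the reference implementation whose
site treatment is not documented). Equal counts give χ² = 0, p = 1; two
zero counts are an explicit degenerate result rather than a number.

**Counting dN/dS.** Codon changes are polarized to the neo-X or neo-Y
branch by the same unique-difference logic at the nucleotide level;
multi-change codons are averaged over all shortest mutational paths with
stop-traversing paths discarded (Nei–Gojobori pathway averaging), and
observed stop codons are excluded from counting (they feed the integrity
report instead). Site counts use fractional degeneracy on the ancestral
codon with changes to stops counted as nonsynonymous, so N + S = 3 exactly
per sense codon. ω = pN/pS on raw proportions by default; a Jukes–Cantor
correction is available and errors when a proportion reaches 3/4. This
counting pipeline is a declared substitute for maximum-likelihood codon
branch models: it recovers orderings (neo-Y ω above neo-X ω under relaxed
constraint, verified by simulation), not calibrated ω magnitudes, and no
likelihood-ratio machinery is provided.

## The simulator: what it emulates, and what it does not

`simulateStudy()` draws a root sequence per gene at the region's G+C
composition and evolves it along `((focal, mouse), rat, outgroup)` with an
exact event-by-event (Gillespie) algorithm: exponential waiting times over
the total rate, one substitution at a time, local rates recomputed after
every event. This is required, not a luxury: CpG hypermutability makes the
process context-dependent and non-reversible, so site-independent matrix
exponentiation does not apply. The core loop is C++ (a Fenwick tree gives
O(log n) site sampling), driven by R's RNG stream so a single
`set.seed()`-controlled seed makes every run bit-reproducible.

Defaults were fixed once, from the study design the package targets:

* **Regions**: peritelomeric / middle / pericentromeric with 51 / 29 / 40
  genes; per-gene ORF lengths 1338 / 1614 / 1362 nt and noncoding lengths
  6713 / 11963 / 14404 nt (the published per-region analyzed-base totals
  divided by gene counts); root G+C 0.524 / 0.482 / 0.455 (the observed
  noncoding G+C contents).
* **Branch lengths** (expected substitutions/site): focal 0.065, sister
  0.055, third lineage 0.07 — the observed per-lineage noncoding
  substitution loads — plus internal 0.03 and outgroup 0.25 as realistic
  murid-scale values.
* **CpG multiplier 10**: CpG transitions are reported as more than ten
  times faster than other transitions.
* **Direction bias**: A/T→G/C transitions ×2 on the focal branch in the
  peritelomeric region and G/C→A/T transitions ×1.5 in the pericentromeric
  region, back-of-envelope magnitudes from the published category
  frequencies relative to the sister-lineage baseline. The middle region
  is unbiased.
* **Base matrix**: HKY-style with κ = 2, scaled to unit leave-rate so
  branch lengths read as substitutions/site.

Coding partitions freeze codon positions 1–2 and forbid third-position
changes that would create a stop. This guarantees frame and stop integrity
without a selection model — appropriate because the spectrum analysis
consumes only third positions — but it means the cross-species simulator
cannot generate nonsynonymous divergence; dN/dS ordering checks use
separate codon-level simulations. Other simplifications: no
within-species polymorphism (leaves are haploid lineages), no indels in
the cross-species alignments, no recombination or demography, and no
rate heterogeneity beyond CpG context. Passing tests on these data
therefore validate the *inference machinery*, not robustness to
alignment error, repeats, or polymorphism in real data — which is exactly
why repeat masks and the exclusion accounting exist.

`simulateGametologPanel()` plants a known set of neo-Y SNVs and indels on
one haplotype, encodes males as IUPAC heterozygotes with the neo-Y gap
signature at length variants, and can inject spurious ambiguity codes at a
configurable per-base rate. Planted variants never collide with or touch
each other (rejection sampling with a one-base buffer), so every truth
record maps to exactly one expected call.

## Numerical conventions

* Percentages print to 1 decimal, rounding half away from zero; undefined
  percentages (zero substitutions) print blank, never `0.0`.
* All tables are tab-separated with a single header line.
* Reported positions are 1-based; stored call objects carry 0-based
  positions (`pos0`).
* The simulator requires an explicit seed; there is no wall-clock seeding
  anywhere in the package.

## Problem sizes used by the test suite

The suite exercises the statistical checks at desk scale, chosen so the
binomial/Poisson tolerances stated with each check have comfortable power:
null calibration and bias recovery on 20 kb of noncoding sequence per
seed, ten seeds per condition; the G+C equilibrium law on 100 kb at branch
length 20 (about 2 million substitution events, exact simulation);
male-specific detection on ten 5 kb panels with 20 SNVs + 2 indels each.
Enumeration checks (64 and 256 parsimony columns, 61 sense codons, 12
direction pairs) are exhaustive rather than sampled.

## Known limitations

* The 4-taxon ambiguity rule is conservative; decision rules that call
  some internal-branch-adjacent patterns would count slightly more
  substitutions at the cost of polarization errors.
* The relative rate test inherits the multiple-hit blindness of counting
  statistics; on deep divergences its counts saturate.
* The gap-signature indel caller assumes the alignment represents length
  variants consistently across individuals; it does not model superimposed
  chromatogram traces.
* Counting dN/dS without distance correction underestimates rates on long
  branches; the Jukes–Cantor option mitigates but does not replace codon
  maximum likelihood.
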