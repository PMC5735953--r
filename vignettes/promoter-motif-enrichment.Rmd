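---
title: "Scanning promoter classes for cis-elements and testing enrichment"
author: "auxrescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning promoter classes for cis-elements and testing enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxrescan)
```

## The model

The package asks a single statistical question in several guises: is a DNA
element more often *present* in the upstream regions of one class of genes
than another? "Present" is deliberately binary — a promoter either contains
at least one occurrence of the element or it does not — because
transcription-factor binding sites act largely as switches and because
presence/absence is robust to the heavy-tailed occurrence counts that
degenerate motifs produce in AT-rich plant genomes.

Three ingredients define the analysis.

**Motif grammar.** Two motif kinds cover the elements of interest. A
*consensus motif* is an IUPAC degenerate string (`CACGTG`, `CANNNNCATGTG`,
`CAMNNANGTG`, ...): each position admits a fixed set of bases, and a window
matches when every position admits the corresponding sequence character. A
*spaced dyad* is two IUPAC cores separated by an unconstrained spacer of
variable length; the combined auxin response element is the dyad
`TGTC[N11-13]GACA`, where the spacer counts the bases strictly between the
cores (so the 11-spacer variant spans a 19-nt window). Auxin response
factors bind this as a homodimer on an *everted repeat*: `GACA` is the
reverse complement of `TGTC`, so the dyad's whole pattern family is its own
reverse complement.

**Strand algebra.** Scanning must not double-count. The rules, applied
uniformly by scanner and generator:

* motifs whose pattern (family) equals its reverse complement —
  palindromic consensus like `CACGTG`, everted-repeat dyads like
  `TGTC[N]GACA` — are scanned on the forward strand only and each site is
  reported once;
* all other motifs are scanned in both orientations (the reverse
  orientation by matching the reverse-complemented pattern on the forward
  sequence), and a window matching in both orientations is reported once
  per orientation;
* a sequence character outside A/C/G/T matches *no* pattern position, not
  even `N`, and voids a dyad spacer: assembly gaps cannot create hits.

**Exact contingency statistics.** For motif *m* and classes A (size
$n_A$) and B (size $n_B$), the presence counts form the table
$(a, b \,|\, c, d)$ with $a + b = n_A$, $c + d = n_B$. Conditional on the
margins, $a$ is hypergeometric under independence. The two-sided p-value
uses the point-probability criterion — the sum of $P(X = k)$ over all
tables with the same margins whose point probability does not exceed that
of the observed table — with probabilities accumulated in log space
(log-scale hypergeometric mass, log-sum-exp totals), so tables with a
500-promoter background margin lose no accuracy. Point probabilities are
compared with a relative tolerance of $10^{-7}$, so ties that differ only
in floating-point representation are included in the sum; this mirrors the
tie handling users will have met in standard exact-test implementations,
and the suite verifies exact agreement with an enumeration oracle for all
tables with total $\le 40$ and with an independent implementation on
larger ones. One-sided p-values (`p_greater`: enrichment in A) are
reported alongside. The companion effect size is the sample odds ratio
$ad/bc$, with $\infty$ when only the denominator vanishes and 1 when both
products vanish. Raw p-values are reported — the design tests a handful of
a-priori motifs, not a genome-wide library — and the report's `n_tests`
column supports downstream correction when users scan larger catalogs.

### Sidedness

Directional enrichment questions ("is the element over-represented in the
auxin-induced class?") are answered by the one-sided test; the two-sided
test treats depletion as equally interesting. For presence counts like
11/50 vs 0/20 the two differ noticeably (0.017 vs 0.027), and for 10/50 vs
0/20 they fall on opposite sides of 0.05 (0.026 vs 0.053). Reports
therefore always carry both columns, and users should pick the hypothesis
before looking. Historical analyses of these particular motif sets quote
the one-sided values.

## Promoter handling

Upstream windows are fixed-length (default 3000 nt), taken strand-aware
from the annotated 5'-most gene/mRNA start: for a plus-strand gene with
0-based start $s$ the window is $[\max(0, s - L), s)$; for a minus-strand
gene ending at $e$ it is $[e, \min(\mathrm{chrom}, e + L))$
reverse-complemented. Stored promoters always read 5'→3' towards the
transcription start, so a hit's distance upstream of the TSS is just its
start minus the promoter length (the `tss_offset` column of hit tables).
Windows may overlap neighbouring genes — matching the behaviour of bulk
upstream-sequence retrieval from genome databases — and genes closer than
$L$ to a chromosome edge yield clipped, flagged records. All internal
coordinates are 0-based half-open; GFF3 input is converted on read and
BED6 output keeps the convention.

## What the synthetic generator emulates

`study_design()` defaults describe the study conditions the analysis
assumes: 50 Class I, 20 Class II and 500 background promoters of 3000 nt.
Sequences are i.i.d. draws from a base composition whose default,
$A = T = 0.33$, $C = G = 0.17$, reflects the AT-richness of plant
intergenic DNA. That choice matters: under it, chance occurrence alone
puts the combined AuxRE in roughly 7–9% of 3000-nt windows — the right
order for real background promoter sets — where a uniform composition
would roughly double that.

Planting works per promoter: for each (motif, class, rate) row of the
design, each promoter of that class independently receives one concrete
instance with probability *rate*. An instance samples each degenerate
position uniformly from its admitted bases, the dyad spacer length
uniformly over its range with spacer bases from the background
composition, and a strand uniformly for motifs that are not their own
reverse complement. Planting overwrites in place (length stays exactly
3000), never overlaps an earlier planting in the same promoter, and is
recorded in a ground-truth table; the suite verifies that every recorded
instance is recovered by the scanner.

Two consequences deserve emphasis. First, *total* presence exceeds the
planting rate, because chance matches from the background process are
real hits and are deliberately counted — exactly as in real promoters,
where nothing distinguishes a "planted" site. With the default rates the
Class I combined-AuxRE presence is therefore ≈ 0.22 planted plus
≈ 0.07 × 0.78 chance. Tests that want the planting rate itself read the
ground-truth table. Second, the default planting rates (combined AuxRE
0.22 / 0 / 0.07; G-box 0.20 / 0 / 0; PIF5-like 0.56 / 0.10 / 0.112 for
Class I / Class II / background) reproduce the per-class presence
structure reported for real auxin-responsive promoter sets, so the
synthetic study exercises the pipeline at realistic signal strengths. The
G-box background rate is 0 because chance G-box occurrences in 3000 nt
already supply abundant background presence.

What the generator does *not* emulate: dinucleotide structure, TATA/CpG
organisation, positional preference of elements relative to the TSS,
conservation, and correlation between motifs within a promoter. Passing
synthetic-recovery tests therefore demonstrates that the scanner and
statistics behave correctly under the stated model, not that any
particular biological promoter set will show enrichment.

### Seed policy

One master seed defines a study. Promoter $i$ uses the derived stream
seed $(\mathrm{seed} + 9973\,i) \bmod 2147483629 + 1$, and all of that
promoter's randomness (sequence, planting decisions, instances,
positions) comes from its own stream. Hence any single promoter can be
regenerated in isolation, and growing or shrinking one class leaves the
other classes' sequences untouched. Identical designs give byte-identical
FASTA bundles.

## Operating characteristics

The suite and `analysis/04_power.R` measure the pipeline end to end over
200 seeded replicates of the default design, scanning the PIF5-like
element only (the motif whose rates differ): with planted rates 0.56 vs
0.10 at $n = (50, 20)$ the two-sided test rejects at $\alpha = 0.05$ in
93% of replicates; with equal rates the rejection rate is 1.5% —
conservative, as expected for an exact test on small discrete tables,
where the achievable size at nominal 0.05 sits below the nominal level.
These replicate counts keep the whole validation suite to a few minutes
on one core; the estimates' Monte-Carlo standard errors (≈ 1.5 points at
the nominal level) are accounted for in the assertions.

## Numerical and design choices

* Overlapping hits are all reported; the scan never skips past a match.
  Presence is unaffected and counts stay well defined.
* Dyad spacers must be unambiguous A/C/G/T; relaxed-core or
  altered-spacing variants of the combined AuxRE are separate catalog
  entries and are never merged into the strict element's presence calls.
* `fisher_exact` returns 1 for any table with an empty margin; the odds
  ratio conventions are stated above.
* The motif catalog round-trips through a TSV definition format, so user
  catalogs are first-class; the built-in catalog of nine elements is the
  default everywhere.
* The heavy lifting for standard formats is delegated: Biostrings for
  FASTA, rtracklayer for GFF3/BED, GenomicRanges for genomic provenance.
  The scanner and the exact test are implemented in the package and
  verified against brute-force oracles, because their exact semantics
  (strand algebra, tie handling) are the package's contract.

## Limitations

Consensus matching is binary: no position weight matrices, log-odds
scores or mismatch tolerance, so information-rich but degenerate sites
are either captured by an explicit IUPAC pattern or missed. Enrichment is
tested per motif independently; co-occurrence and spacing between
*different* elements (e.g. an AuxRE–G-box pair ~100 bp apart) is visible
in the hit tables but not tested. Background sampling assumes the user's
universe of promoters is itself unbiased.
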