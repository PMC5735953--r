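# auxrescan

Cis-element scanning and enrichment analysis for promoter classes, built
around the regulatory grammar of auxin-responsive genes.

## The problem

Plant genes that respond to auxin tend to carry characteristic DNA elements
in their upstream regions: single auxin response element (AuxRE) cores such
as TGTCTC, and — because auxin response factors bind as homodimers to an
everted repeat — the *combined* element `TGTC[N11-13]GACA`: two AuxRE cores
on opposite strands separated by an 11–13 nt spacer. Related elements
(the BZR1-bound G-box `CACGTG`, the PIF core box `CATGTG`, and extended
PIF5-like consensus patterns such as `CANNNNCATGTG`) mark cross-talk with
brassinosteroid and light signalling. Given two classes of genes — say,
auxin-induced versus not auxin-regulated — the question is whether any of
these elements is over-represented in one class's promoters.

`auxrescan` implements that analysis end to end:

1. **Promoter extraction** — strand-aware, fixed-length (default 3000 nt)
   upstream windows from a genome FASTA + GFF3 annotation, or promoters
   read directly from FASTA with a gene→class label table.
2. **Motif scanning** — IUPAC degenerate consensus patterns and spaced
   dyads with variable spacers, scanned with the correct strand algebra:
   palindromes and everted repeats match identically on both strands and
   are counted once; all other motifs are scanned in both orientations.
   Occurrences are reduced to per-promoter presence/absence.
3. **Enrichment statistics** — for each motif and each class pair, a 2×2
   contingency table of presence counts, the sample odds ratio, and the
   exact conditional (hypergeometric) test, computed in log space. For a
   table (a, b | c, d) with fixed margins the two-sided p-value is

   p = Σ { P(X = k) : P(X = k) ≤ P(X = a) } ,  X ~ Hypergeom,

   the point-probability criterion; one-sided (enrichment-direction)
   p-values are also reported.
4. **Synthetic studies** — a seeded generator that emulates the study
   design (50 Class I + 20 Class II + 500 background promoters, 3000 nt,
   AT-rich base composition) with motifs planted at per-class rates and
   full ground truth, so the whole pipeline is testable with no external
   data.

## Worked example

The exact test on published presence counts — the combined AuxRE found in
11 of 50 auxin-induced promoters and 0 of 20 non-responsive ones:

```r
library(auxrescan)
fisher_exact(contingency_table(11, 39, 0, 20), "greater")
#> [1] 0.01726269
fisher_exact_two_sided(contingency_table(11, 39, 0, 20))
#> [1] 0.02675368
odds_ratio(contingency_table(28, 22, 2, 18))
#> [1] 11.45455
```

A complete synthetic study — simulate, scan, test:

```r
ana <- run_synthetic_analysis(study_design(seed = 2026))
subset(ana$report, comparison == "class_I vs class_II" &
                   motif == "ClassI_PIF5like")
#>             motif          comparison n_A hits_A frac_A n_B hits_B frac_B
#> 22 ClassI_PIF5like class_I vs class_II  50     28   0.56  20      3   0.15
#>    odds_ratio p_two_sided p_greater n_tests
#> 22      7.212     0.00285   0.00161      27
```

At seed 2026 the PIF5-like element, planted at rate 0.56 in Class I and
0.10 in Class II, is detected in 28/50 vs 3/20 promoters (planting plus a
small number of chance matches) and flagged as enriched at p ≈ 0.003
(two-sided). The full report holds one row per motif × comparison (9 × 3),
with raw p-values and an `n_tests` column for downstream multiple-testing
correction.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` writes the synthetic bundle (FASTA, labels,
ground truth, design echo) under `results/`, `02_scan.R` produces the hit
table and presence matrix, `03_enrich.R` the enrichment report and the
exact tests on the published count tables, and `04_power.R` the
Monte-Carlo operating characteristics of the pipeline (power 0.93 at
planted rates 0.56 vs 0.10; type-I rate 0.015 at equal rates, 200
replicates each).

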