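---
title: "Methods: codon usage bias, strand asymmetry and ortholog divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias, strand asymmetry and ortholog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the statistics it
computes, the conventions and numerical choices behind them, what the
synthetic-data generator does and does not emulate, and the known limits of
each method. The running organism is *Corynebacterium glutamicum*, a GC-rich
actinobacterium whose codon usage reflects three superimposed forces:
compositional (mutational) bias towards G/C, translational selection in
highly expressed genes, and replication-strand asymmetry.

## Gene inclusion

All analyses run on CDS sets (multi-FASTA or GenBank CDS features). A gene
is retained when it has at least 100 codons (the terminal stop is counted —
the conventional length threshold leaves this ambiguous, and we commit to
one reading), starts with an accepted initiation codon, ends with a stop,
and has no internal stop. The bacterial table 11 start set defaults to
{ATG, GTG, TTG}: actinobacteria initiate a substantial minority of genes at
GTG/TTG, and requiring ATG alone would bias the retained set towards one
gene class. The terminal stop is kept in the codon list but excluded from
every index. Ribosomal-protein genes — the classical "putatively highly
expressed" reference class — are flagged by the case-insensitive substring
"ribosomal protein" in the product annotation.

## Per-gene indices

All indices ignore Met, Trp and stop codons, i.e. they work on the 59
synonymously variable codons; single-codon families carry no usage signal
and would only dilute the statistics.

**RSCU.** `RSCU(c) = k n_c / N` for a family of degeneracy *k* with total
*N*. A family absent from a gene has no defined RSCU; we return `NA` rather
than 0, and only coerce to 0 where a complete matrix is required (see the
ordination section).

**Nc (effective number of codons).** Wright's estimator from per-family
codon homozygosity `F = (n Σ p² − 1)/(n − 1)`. Families with fewer than two
observations are skipped; degeneracy classes are the classical 2-, 3-, 4-
and 6-fold sets (Ile is the sole 3-fold family; Leu, Ser, Arg are kept as
6-fold wholes rather than split 2+4). When the 3-fold class is unobserved
its homozygosity is interpolated as `(F̄2 + F̄4)/2`, the CodonW-compatible
fallback; if any other class is entirely missing the statistic is undefined
(`NA`) rather than guessed. Results are clamped to [20, 61]. The null curve
under pure compositional bias is `Nc(s) = 2 + s + 29/(s² + (1−s)²)`. Note
that this curve is *not* symmetric about s = 0.5 — the linear term gives
`Nc(0) = 31` but `Nc(1) = 32` — although its dominant compositional
component is; one acceptance-level check records that asymmetry explicitly.

**CAI.** Relative adaptiveness weights are built from the pooled codon
counts of the ribosomal-protein genes: `w(c) = n_c / max(family)`, with
unobserved codons given a 0.5 pseudo-count *before* weighting so no weight
is zero (log-domain safety; the common CAI practice). CAI is the geometric
mean of `w` over the gene's eligible codon occurrences. A gene using only
per-family maximal codons scores exactly 1.

**Fop.** Fraction of codon occurrences belonging to the optimal set, with
the denominator restricted to families containing at least one optimal
codon, so amino acids without an optimal codon neither help nor hurt.

**GRAVY.** Mean Kyte–Doolittle hydropathy of the encoded protein.

## Correspondence analysis

The gene × 59-codon matrix (per-gene RSCU by default; raw counts exposed as
an alternative, since the choice is a genuine open point — both are in
common use and we make no claim about which matches any particular published
inertia figure) is decomposed by standard chi-square-metric CA: with
`P = X/N`, row masses `r` and column masses `c`, the SVD of
`D_r^{-1/2}(P − r cᵀ)D_c^{-1/2}` gives principal coordinates
`D_r^{-1/2} U Σ` (genes) and `D_c^{-1/2} V Σ` (codons), and per-axis inertia
fractions `σ_k²/Σσ²`. Undefined per-gene RSCU entries are set to 0 to keep
the matrix complete and non-negative. Numerical conventions: all-zero
columns are dropped and recorded; a matrix of proportional rows (zero total
inertia) returns all-zero coordinates instead of erroring; rank below 2
errors as "too few distinct genes"; the rank tolerance is
`max(dim) · σ_max · 100ε`. CA axis signs are arbitrary, so axis 1 is
oriented to put the mean ribosomal-protein coordinate at the positive end —
"high" then means "towards the highly expressed class" by construction.
The test suite verifies the chi-square-distance identity (row coordinates
reproduce chi-square distances between row profiles, tolerance 1e-8 on
≤10-gene matrices), the inertia/Pearson-chi-square identity, permutation
invariance up to sign, and agreement of axis 1 with `MASS::corresp`.

## Optimal codons

Genes at the two extremes of axis 1 (default fraction 0.05 per end,
configurable; group membership ties broken by gene id) are pooled, and each
of the 59 codons is tested with a 2×2 Pearson chi-square — codon vs the
rest of its family, high vs low pool — with no continuity correction
(pooled counts are large; a Yates option exists) and no multiple-testing
correction, at α = 0.01. A codon is *optimal* when significant **and** its
within-family proportion is higher in the high pool: proportions, not raw
counts, because the pools differ in size, and not RSCU > 1 — a codon can be
significantly enriched yet still below parity (the shipped worked table
contains exactly such a case, GAA). The per-codon 2×2 design mirrors tables
that star individual codons; a family-wide k×2 test answers a different
question. The shipped *C. glutamicum* extreme-group table reproduces all
published RSCU values at 2 d.p. and yields 22 optimal codons over 18 amino
acids (14 C-ending, 3 G-ending) under exactly this test.

## Replication strand analysis

GC skew `(G − C)/(G + C)` is computed in 24 kb windows stepped by 3 kb
(configurable), windows wrapping circularly; a window without G or C gets
skew 0. Origin and terminus come from the extrema of the cumulative per-base
skew walk (+1 for G, −1 for C): the walk falls across the replichore where
the plus strand is C-rich and rises where it is G-rich, so the global
minimum marks the origin and the maximum the terminus (ties resolve to the
smallest coordinate; a flat walk is flagged degenerate and defaults to
positions 1 and L/2 with a warning). This is deliberately simpler than
gene-walk methods that track coding-frame composition: for classifying genes
into replichores the skew extrema are adequate and dependency-free, but the
positions should not be over-interpreted — on real genomes, inversions and
recent horizontal transfers distort the walk locally.

A gene is *leading* when transcribed co-directionally with fork movement:
on the replichore covered by the fork moving towards increasing coordinates
(ori → ter), plus-strand genes are leading; on the other replichore,
minus-strand genes are. Replichore membership uses the gene midpoint, which
is stable for genes spanning ori or ter. Leading fractions are tabulated by
CAI bin (default edges 0.35 and 0.65, boundary values to the lower bin —
published binnings with overlapping inequalities leave boundaries ambiguous,
so one convention is fixed), with named special sets (ribosomal proteins)
as extra rows.

## Ortholog divergence

Ortholog pairs come either from two 12-column tabular hit files (reciprocal
best hits under ≥60% identity, E ≤ 1e-5, coverage ≥60% of the longer
protein, both proteins ≥100 aa; best hit by bit score with ties by E-value
then subject id) or from direct pairing of simulated genes. Identity is
measured over aligned columns (the hit-table convention). E-values are only
ever read from files — the package does not compute them, and the internal
alignment path simply does not evaluate that criterion.

Protein pairs are aligned globally (BLOSUM62, gap open 11, extension 1 —
a gap of length L costs 11 + L, the BLAST-style convention) via
`Biostrings::pairwiseAlignment`, then back-translated: each residue is
replaced by its source codon, each gap by `---`, with translation mismatches
raised as validation errors naming the position.

Ka and Ks use Nei–Gojobori (1986) counting. Synonymous site counts give
each codon position the fraction of its three single-base changes that are
synonymous, with changes creating a stop counted as nonsynonymous — this
keeps sites summing to exactly 3 per codon, and site totals are averaged
between the two sequences so the estimate is symmetric in sequence order.
Differences average over all substitution orders between differing codons,
excluding paths that pass through a stop (falling back to all paths when
every path is blocked). Columns with gaps, ambiguity codes or stop codons
are excluded. The Jukes–Cantor correction `d = −3/4 ln(1 − 4p/3)` is applied
per class; proportions at or beyond 3/4 return `NA` as a saturation marker.
Pairs with Ks ≥ 1.0 are dropped before divergence–expression correlations
(Ka–CAI, Ks–CAI, Ka–Ks, Ks–Fop; Pearson, undefined below 3 pairs). Counting
methods are not numerically interchangeable with maximum-likelihood codon
models: with unequal codon frequencies and transition/transversion bias, ML
estimates on real data will differ systematically, so comparisons should
stay within one estimator.

## The synthetic genome generator

The simulator plants exactly the causal structure the analyses are meant to
detect, with ground truth for every label:

- **Expression**: log-normal levels (meanlog 0, sdlog 1), converted to a
  rank score *e* in [0, 1]. A small high-expression tail mimics the
  ribosomal class; the top genes (4% by default) are annotated as ribosomal
  proteins and thereby become the CAI reference.
- **Codon choice**: amino acids uniform; within a family, baseline
  probabilities split G/C-ending vs A/T-ending codons by the target GC3
  (default 0.57, matching a GC-rich actinobacterial genome), then optimal
  codons are boosted by `exp(s_expr · e)` and renormalised. `s_expr = 1.5`
  gives a strong but not caricatural gradient (a ~4.5-fold boost at the top
  of the expression range). The default planted optimal set is the
  22-codon *C. glutamicum* set, so fixtures echo the real biology.
- **Placement**: genes laid end to end with A/T spacers on a circular
  chromosome, origin at position 1 and terminus at the midpoint;
  top-quartile-expression genes are placed leading with probability
  `leading_bias` (default 0.85), all others 0.5.
- **Divergence**: ortholog simulation applies Poisson numbers of synonymous
  (`target_ks · S` sites) and nonsynonymous (`omega · target_ks · N`)
  single-base codon substitutions, never creating internal stops; multiple
  hits per site occur naturally and are what the JC correction absorbs. The
  realised event counts are returned as ground truth.

Default genome size is 500 genes of 200–500 codons. Two considerations set
the length range: per-gene CAI standard error scales roughly as 1/√L, and
with shorter genes that noise smears the CAI > 0.65 bin across the
top-quartile boundary, so the bin no longer isolates the gene class whose
placement probability was planted and the leading-fraction readout becomes a
biased estimate of `leading_bias`. At 200–500 codons (mean ≈ 1 kb CDS,
typical of bacterial genes) the top bin is essentially pure and the readout
is calibrated. The recovery experiment in the test suite uses extreme-group
fraction 0.1, seed 42, and checks three planted signals at once: positive
axis-1–CAI correlation, ≥90% recovery of the planted optimal set, and a
top-bin leading fraction inside the exact binomial 95% interval of the
planted probability (that interval check is a single calibrated 95% test by
construction).

What the generator does **not** emulate: amino-acid composition differences
between genes (amino acids are uniform, so GRAVY carries no planted signal),
indels in orthologs, operon structure, intragenomic GC gradients, mutational
strand asymmetry within codons (spacers are pure A/T, so the planted
origin/terminus — not skew-detected ones — anchor the strand tests), and
annotation errors. Passing the recovery tests therefore demonstrates that
the estimators detect the planted signals at realistic effect sizes, not
that they are robust to every artefact of real annotations.

## Problem sizes and runtime envelope

The test suite runs the chi-square-distance CA oracle on ≤10-gene matrices
(tolerance 1e-8), the independent Wright-formula transcription on 200 random
genes (1e-9), the exhaustive NG86 pathway enumeration on all 4,096 ordered
codon pairs, Ka/Ks parameter recovery on a 10,000-codon simulated pair
(within 10%), the null calibration of the optimal-codon test on ~10,000
simulated null 2×2 tables (rejection rate 1% ± 0.5%), and the full
end-to-end recovery experiment described above. These sizes were chosen so
the whole suite stays desk-scale while keeping every estimator's sampling
error well below the tested tolerances.
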