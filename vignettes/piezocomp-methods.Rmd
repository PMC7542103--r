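---
title: "Methods: comparative proteome and gene-content analysis of piezophiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative proteome and gene-content analysis of piezophiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezocomp)
```

`piezocomp` contrasts piezophilic (pressure-adapted) and piezosensitive
bacterial strains through four connected analyses: proteome-wide
isoelectric point (pI) profiling, directed amino-acid substitution
asymmetry between single-copy orthologs, pan-genome partitioning, and COG
functional-category comparison. This vignette documents the models, the
tunable parameters, the design decisions taken where the procedure was
genuinely open, and what the synthetic validation does and does not show.

## The charge model and pI

A protein's net charge at a given pH is modeled with the standard
Henderson–Hasselbalch treatment of the two termini and the seven
ionizable side chains (K, R, H positive; D, E, C, Y negative):

$$Q(\mathrm{pH}) = \frac{1}{1+10^{\mathrm{pH}-pK_N}}
 + \sum_{r \in \{K,R,H\}} \frac{n_r}{1+10^{\mathrm{pH}-pK_r}}
 - \frac{1}{1+10^{pK_C-\mathrm{pH}}}
 - \sum_{r \in \{D,E,C,Y\}} \frac{n_r}{1+10^{pK_r-\mathrm{pH}}}.$$

Ambiguity and rare codes (X, B, Z, J, U, O) carry no charge. $Q$ is
strictly decreasing in pH for any sequence (both termini are always
present), so the pI is the unique zero crossing, found by bisection on
$[0, 14]$ to a tolerance of $10^{-4}$ charge units (at most 100
iterations; the interval then spans $14/2^{100}$ pH units, so
non-convergence is effectively impossible and is treated as an error).
The implementation bisects all proteins of a proteome simultaneously on
residue-count matrices, which keeps a 2,000-protein genome under a
fraction of a second.

Two named pKa sets ship with the package: `"expasy"` (the
Bjellqvist-style values used by the ExPASy Compute pI/MW tool, with a
single N-terminal pKa of 7.5) and `"emboss"` (the EMBOSS `iep` values).
Published pI servers differ in their termini treatment and table
versions; keeping the set selectable makes the sensitivity of downstream
statistics to this choice testable rather than baked in. All defaults use
`"expasy"`.

## The pI bias statistic

Each proteome is split into an acidic set ($N_a$: pI < 7) and a basic set
($N_b$: pI > 7); the bias is $100\,(N_b-N_a)/(N_b+N_a)$. Three choices
matter here:

- $N_a$/$N_b$ are computed on the **unrounded** pI values with strict
  inequalities; a protein at exactly pI 7 counts in neither set (a
  measure-zero event in practice).
- Rounding to the nearest tenth (half away from zero, since base R's
  `round()` is banker's) applies only to the plotted/binned histogram,
  not to the bias — the bias is defined on the sets, not the bins.
- Group comparison uses **Welch's** two-sample t-test on the per-genome
  biases (unequal variances are the norm between groups of 3–4 genomes),
  with no multiplicity correction for this single comparison. Degenerate
  zero-variance inputs use the convention $t = 0,\ p = 1$ for equal
  constant groups.

## Ortholog substitution asymmetry

The directional question — which residues systematically replace which,
reading from the piezosensitive reference to the piezophile target — is
answered in five steps:

1. **Single-copy orthologs.** Only clusters with exactly one member in
   both genomes are used; multi-copy or patchy clusters are dropped.
   Cluster tables from dedicated tools are ingested as TSV; for the
   two-genome synthetic setting a reciprocal-best-hit pairing over global
   alignment scores is built in.
2. **Alignment.** Needleman–Wunsch global alignment under BLOSUM62 with
   affine gaps (open 11, extend 1; a gap run of length $k$ costs
   $11 + k$). The aligner is a per-gene stand-in for a production MSA
   tool; externally aligned pairs can be supplied instead.
3. **Ambiguity masking.** A column is excluded when it, or any column
   within `window = 2` columns of it, has a gap in either row, or when
   either residue is an ambiguity code. The named window value admits a
   lenient reading (gap columns only); we implement the strictest
   plausible one and expose `window` so the lenient variant
   (`window = 0`) is one argument away. Masking is provably monotone:
   larger windows never keep more sites.
4. **Counting.** Over kept columns, ref = a, tgt = b with $a \ne b$
   increments the directed count $c_{ab}$; equal residues increment the
   conserved count. The invariant
   $\sum_{a\ne b} c_{ab} + \mathrm{conserved} = \mathrm{kept\ sites}$ is
   asserted at construction. Both raw and kept site totals are reported,
   since "sites examined" is ambiguous between the two.
5. **The index and its uncertainty.** Per directed pair,
   $(c_{ab}-c_{ba})/(c_{ab}+c_{ba})$; per residue, gains vs losses in the
   same form. The upstream asymmetry programs this mirrors do not
   reprint their scaling formula, so the index is a documented stand-in
   isolated behind one function (`asymmetry()`) and can be swapped
   without touching counting. A pair with no observed substitutions in
   either direction is reported as missing, never as zero. Standard
   errors come from resampling **clusters** with replacement (default
   100 replicates, seeded) — sites within one protein are correlated, so
   a site-level bootstrap would be anti-conservative. Significance is
   $|z| \ge 1.96$ with no multiple-testing correction across the 190
   pairs by default (Benjamini–Hochberg is available via `bh = TRUE`).
   Indices are rounded to three decimals in output tables only.

Reciprocal-best-hit pairs with under 30% ungapped identity or under 50
kept sites are discarded before pooling; these guard against spurious
pairings between unrelated sequences and are configurable. The consensus
rule across independent comparisons flags a directed pair only when it is
significant with the same sign in **all** comparisons.

## Pan-genome partition and COG comparison

Partitioning counts **clusters**: core = present in all $G$ genomes,
cloud = exactly one, shell = 2..$G-1$. A cluster is group-exclusive when
present in every genome of one group and in none of the other. The COG
comparison divides each category count by the genome's total
COG-annotated genes (unannotated genes are excluded — the conventional
denominator when only annotated counts are available) and applies Welch's
t per category, raw p by default and BH behind a flag.

## The synthetic generator

The generator emulates the statistical structure the analyses are
designed to detect, with truth records for every planted effect:

- **Proteomes**: per-protein designed class (basic with probability
  `basic_fraction`, else acidic), with basic compositions enriched 3× in
  K/R and depleted 4× in D/E over a typical bacterial background (and the
  mirror image for acidic). Defaults are 4 piezophile vs 3 piezosensitive
  genomes of 2,000 proteins with basic fractions 0.50 vs 0.35 — a
  +30-point bias shift toward the piezophiles, the direction and rough
  magnitude separating obligate piezophiles from their shallow-water
  relatives. Protein lengths are lognormal with mean 300 sd 150 residues,
  floored at 30.
- **Ortholog families**: ancestral sequences mutated independently down
  two lineages, each site substituted with probability `divergence`
  (default 0.10) to a **uniformly** chosen alternative. The uniform
  kernel is deliberate: it makes the symmetric null exact by
  construction, which is what the null-calibration guarantee of the
  significance machinery is tested against; realism of the kernel is
  irrelevant to that property. Planted directional excesses (default
  E→A and E→K at 0.02) apply on the target lineage only, mirroring the
  directional reading from the piezosensitive reference. With the default
  100 families this yields roughly 30,000 aligned sites per comparison.
  Optional uniform deletions (`indel_prob`) exercise the gap mask; truth
  counts are exactly recountable from the emitted FASTA only in the
  indel-free setting.
- **COG tables**: multinomial draws per genome (3,000 genes) from a fixed
  base category frequency vector with group multipliers (default 1.5× on
  L for the piezophiles) renormalized in.

What passing tests on this generator show: the pipeline recovers planted
shifts of realistic size with the advertised error rates, and its
significance calls are calibrated under an exactly symmetric null. What
they do not show: robustness to composition heterogeneity along real
proteins, empirical substitution processes, alignment error on distant
orthologs, or annotation noise in real COG assignments — all properties
of real data the generator intentionally omits.

## Validation problem sizes

The shipped validation uses: 100 random sequences against a
$10^{-5}$-step grid-search pI oracle (agreement within $10^{-3}$ pH);
exhaustive enumeration of all global alignments for 200 random pairs of
length ≤ 6; 20 seeded null-calibration runs of ~30,000 sites each (pooled
significant fraction ≤ 10%); 20 seeded planted-E→K runs through the full
align–mask–count–bootstrap path; and 100 replicates of the
5-vs-5-genome, 2,000-protein bias-shift detection. These sizes were
chosen to give the binomial/bootstrap margins used in the assertions
while keeping the suite comfortably fast on a laptop.

## Known limitations

- The charge model ignores post-translational modification,
  structure-dependent pKa shifts, and terminal-residue-specific pKa
  values; it reproduces pI-server conventions, not experimental pI.
- Pairwise (not multiple) alignment; no ancestral-state reconstruction,
  so "direction" means reference→target, not ancestral→derived.
- The asymmetry index is a normalized imbalance, not a rate: it does not
  correct for residue availability in the reference proteome (the
  per-residue gains/losses view partially addresses this).
- Ortholog clustering itself (MCL/Roary) is out of scope; the package
  ingests its output and the built-in RBH pairing is only intended for
  controlled two-genome settings.
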