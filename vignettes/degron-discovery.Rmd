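---
title: "Degron discovery from FACS-seq stability screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degron discovery from FACS-seq stability screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronscan)
```

# The screen and its statistic

A GPS reporter screen expresses each member of a tiled peptide library
(17-mers stepped every 5 residues along source proteins) as a GFP fusion
next to an internal control fluorophore. Cells are sorted by the
GFP/control ratio into four gates holding equal cell numbers, and each
gate's peptide DNA is sequenced. Because the gates hold equal cells but are
sequenced to different depths, counts are first converted to within-gate
frequencies $f_{ig} = c_{ig} / \sum_j c_{jg}$. The Protein Stability Index
is the gate-index-weighted mean

$$\mathrm{PSI}_i \;=\; \frac{\sum_{g=1}^{4} g \, f_{ig}}{\sum_{g=1}^{4} f_{ig}},$$

bounded in $[1, 4]$: 1 means every read fell in the least-stable gate, 4 in
the most-stable. PSI is invariant to rescaling any single gate's counts
(depth invariance) and monotone under moving read mass to higher gates;
both properties are enforced by tests against a brute-force oracle.

Screen conventions carried through the package:

* tiles with **more than 50 reads** across the four gates enter training
  (strict inequality);
* training labels: **unstable if PSI < 2.2, stable if PSI > 2.8**, the
  intermediate band is excluded;
* degron calls at **PSI < 1.7** (strict by default; the `le` comparator is
  available because published figure legends vary between `<` and `≤`),
  and **PSI ≤ 1.62** for high-confidence degrons;
* probability-level degron calls at **P ≥ 0.85** (inclusive by default,
  configurable for the same reason).

# The composition model

The degron predictor is a logistic regression with exactly one parameter
per amino acid applied to a tile's composition fractions:

$$P(\text{degron} \mid s) = \sigma\!\Big(\sum_{a} w_a\, x_a(s)\Big),
\qquad x_a(s) = \tfrac{1}{17}\,\#\{a \in s\}.$$

Two design choices deserve explanation:

**Fractions, not counts.** At fixed tile length the two parametrizations
differ only by a factor 17 on the weights; fractions were chosen so the same
weights apply unchanged to any window length in `region_score()`. A
consequence is that the *numerical values* of trained weights are not
comparable across feature conventions — only probability outputs and weight
*correlations* are.

**No intercept.** Since $\sum_a x_a = 1$ exactly, an intercept is
non-identifiable: adding $b$ to the intercept and subtracting $b$ from every
weight leaves all predictions unchanged. The default fit therefore has none;
a flag enables one for sensitivity analysis.

The fit is ridge-penalized maximum likelihood,
$-\tfrac1n \ell(w) + \tfrac{\lambda}{2}\lVert w\rVert^2$, solved by Newton
iterations to a gradient norm of $10^{-8}$ — fully deterministic. No
published penalty exists for this model, so $\lambda$ is chosen by 5-fold
cross-validation over the grid $10^{-4}, \dots, 10^{2}$ with a fixed fold
seed; ties resolve to the stronger penalty. The test suite cross-checks the
solver against an independent ridge implementation (`glmnet`) at fixed
$\lambda$ and against parameter-recovery simulations.

Because the model sees only composition, `predict()` is exactly
permutation-invariant — scrambled variants of a peptide score identically,
which is both a biological claim of the model (degron potency here is
composition-driven) and a hard test-suite invariant.

## Scanning and regional averaging

`scan_protein()` scores every 17-mer window and assigns each probability to
the window's **center residue** (position start+8). Residues within 8
positions of either terminus carry `NA` rather than an extrapolated value —
we prefer an honest undefined to an invented terminal score; users needing
coverage to the termini can use the reported full tile extents
(center-run ± 8). Degron regions are maximal runs of center residues at or
above the cutoff; the region *center* is `floor((start+end)/2)`, ties
resolving to the N-terminal side. `region_score()` averages all $L-16$
window probabilities of a longer peptide (7 windows for a 23-mer), reducing
to `predict()` at $L = 17$.

# Transmembrane-segment overlap

Transmembrane annotations are an *input* (TMHMM long format or a plain
interval TSV); the package does not run or re-implement the HMM, which
keeps analyses deterministic and download-free. Residue-level intersection
counts degron-only / TMD-only / both over residues with defined
probability. A TM segment is summarized by the **maximum** defined
per-residue probability: typical segments (~21 residues) are longer than
the 17-residue window, and a degron call anywhere in the segment makes it
act as a degron; the mean is available by option. Segments with no defined
residue (too close to a terminus) are excluded rather than guessed.
Histogram bins over the callable range default to three equal widths on
$[0.85, 1]$ since no published bin edges exist.

The composition contrast between high- and low-probability TMD groups uses
an omnibus chi-square on the pooled $2 \times 20$ residue-count table
(df = 19) followed by per-amino-acid two-sided Mann–Whitney U tests on
per-segment fractions, with normal-approximation 95% CIs for plotting.

# E3 knockout analysis

For each knockout strain, $\Delta\mathrm{PSI} =
\mathrm{PSI}_{E3\Delta} - \mathrm{PSI}_{control}$ is computed over control
degrons (PSI ≤ 1.7) present in both strains (presence in both is required
by default and logged, since the alternative is not specified anywhere).
The stabilization threshold is "two standard errors from the mean": we read
SE as the standard error of the strain's $\Delta$PSI distribution,
$\mathrm{sd}/\sqrt{n}$ (default), with $2\,\mathrm{sd}$ selectable — the
former matches the small thresholds needed for the published ~10–30%
stabilized fractions, the latter is the conservative reading. Top-10%
$\Delta$PSI sets (size `ceiling(0.1 n)`, ties broken by peptide id) feed
the Venn overlap counts.

# The screen simulator

`facs_sim` is first-class, tested code that emulates the data-generating
process end-to-end:

1. **Library**: random 17-mers drawn from an approximate *S. cerevisiae*
   proteome residue distribution (embedded, rounded to 3 decimals);
2. **Truth**: degron probability through the composition link with a
   chosen true weight vector (default: the Kyte–Doolittle scale, i.e.
   hydrophobicity-driven degrons); mean fluorescence ratio by a linear
   monotone-decreasing map from 1.0 at $P=0$ to 0.2 at $P=1$ — the map is
   arbitrary by design, as only monotonicity matters for rank-based
   recovery;
3. **Cells**: each tile contributes `cells_per_tile` cells whose ratio is
   the tile mean times lognormal noise ($\sigma = 0.3$ by default, the
   standard flow-cytometry noise model);
4. **Sort**: the pooled population is ranked and cut at the configured
   quantiles (default quartiles), so gates hold equal cell numbers within
   rounding; ties (exactly at $\sigma = 0$) are broken by pool order,
   keeping a tile's cells contiguous;
5. **Sequencing**: per-gate reads are multinomial over tiles proportional
   to gate occupancy.

Default validation scale is 20,000 tiles × 100 cells with ~100 reads per
tile (~2M reads over four gates), which the full pipeline — sort, PSI,
label, train — processes in seconds; the test suite asserts weight
recovery at Pearson r ≥ 0.9 and PSI–truth Spearman ρ ≥ 0.9 at this scale.

**What the simulator does not emulate** — and hence what passing tests do
not show about real screens: position-dependent degron effects (the truth
is composition-linear by construction), sequencing error, PCR duplication,
cell-cycle or expression heterogeneity beyond lognormal ratio noise, and
mechanistic E3 biology (knockout stabilization is injected as
user-specified ratio offsets). Recovery results therefore validate the
*pipeline arithmetic and estimator*, not the biological adequacy of the
composition model — the latter rests on the screen data themselves.

# Numerical and edge-case choices

* Nonstandard residues (X, U, B, Z, \*) are unscorable by a 20-parameter
  model; the FASTA reader either drops affected proteins (default for
  training/scanning) or skips only affected tiles.
* All reported coordinates are 1-based inclusive.
* The Kyte–Doolittle table is embedded verbatim with provenance to avoid
  silent scale drift; the panel GRAVY regression must agree with published
  values to ±0.005 (printing precision).
* Tiles with zero reads in all gates are dropped with a logged count;
  an all-zero count table is an error.
* `train()` errors on single-class input and on non-convergence, rather
  than returning a silently bad fit.
* The simulator records its seed; `scramble()` and all seeded operations
  restore the caller's RNG state.

# Worked-example panel

The packaged 14-peptide panel (ten screen peptides re-tested individually,
two scrambles, two charge mutants) is the package's hard regression gate
for GRAVY. Model probabilities for the panel are *reported, never
asserted*, because weights are re-derived from whatever training data the
user supplies: a retrained model reproduces the published probabilities
only approximately, while the scramble identities (P1 = SC1 = SC2) hold
exactly for any model by construction.

# Known limitations

* Terminal residues (first and last 8) never receive probabilities; true
  terminal degrons are invisible to the per-residue track.
* Proteome-scale published counts (e.g. the number of high-probability
  TMDs) depend on proteome and TMHMM versions and are environment-dependent;
  the operations that compute them are tested on synthetic annotations
  instead.
* The ΔPSI scale is screen-relative: thresholds derived from one
  experiment's distribution are not comparable across experiments in
  absolute terms.
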