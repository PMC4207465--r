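---
title: "Methods: saturation-mutagenesis MPRA analysis with mpradisect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturation-mutagenesis MPRA analysis with mpradisect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpradisect)
```

This vignette is the package's account of its statistical machinery: the
models it fits, the constants it assumes, the parts of the design that were
genuinely open and how they were decided, and what the synthetic-data
generator does and does not emulate.

## The assay and its outcome

A saturation-mutagenesis MPRA library contains on the order of 10,000
haplotypes of one enhancer, synthesized from doped oligonucleotides: every
position except the flanking primer-landing sites carries the designated base
with probability 0.97 and each other base with probability 0.01. Each
haplotype is cloned with a unique degenerate 20-bp tag transcribed with the
reporter. After delivery, RNA is split into 16 RT-PCR aliquots per biological
replicate (two replicates) and the tags are sequenced per aliquot.

The activity proxy is deliberately coarse: reads are first filtered on the
mean Phred quality of their first 20 bases (the tag; default minimum 20), the
reads per tag are counted per aliquot, and a tag counts as *present* in an
aliquot only with at least 10 supporting reads. The outcome for haplotype $i$
is its **aliquot count** $y_i \in \{0, \dots, K\}$, the number of aliquots in
which its tag is present, with $K = 32$ under the default design. Replicates
are combined by summing aliquot counts, which is also how the package's
default pipeline fits its models; per-replicate fits are available for
concordance checks (`y_rep1`, `y_rep2` travel with every presence table).

Two readings of the ten-read rule are possible — per aliquot or summed over
aliquots. Because the outcome is per-aliquot presence, the per-aliquot
reading is the default; `presence_filter(scope = "total")` implements the
other.

## Effect-size regression

For position $j$, the univariate model regresses $y$ on a single binary
indicator $X_{ij}$ (1 = haplotype $i$ mutant at $j$). For a binary predictor
the OLS solution is the group-means identity: $\hat\beta_0$ is the mean
aliquot count of position-$j$ wild-type haplotypes and $\hat\beta_j$ the
mutant minus wild-type difference. The trivariate model replaces the single
indicator with three, one per possible substitution; since the indicators are
mutually exclusive, this is again a group-means fit, and when only one
alternate base was sampled at a position the trivariate estimate equals the
univariate one exactly.

The **effect size** is defined on model-predicted activity:

$$E = \log_2\frac{\hat\beta_0 + \hat\beta}{\hat\beta_0}.$$

It is reported as missing when $\hat\beta_0 \le 0$ or
$\hat\beta_0 + \hat\beta \le 0$ (e.g. a mutant group never observed in any
aliquot); the p-value — the usual two-sided t-test on the coefficient — is
retained. For the univariate model "predicted" and "raw group mean" coincide;
for the trivariate model they coincide too under the one-hot design, so the
distinction is immaterial here, but we state the predicted-value definition
because it is the one that generalizes.

Internally the fits are computed by vectorized closed-form OLS (group sums
per position) rather than by looping `lm()` over 560 positions; the test
suite verifies coefficient-level agreement with `lm()` to $10^{-9}$.
Haplotypes carrying several mutations enter every per-position model — their
other mutations act as noise, exactly as the binary-indicator formulation
implies; there is no single-mutant filtering. P-values are raw: the display
convention flags estimates at $p \le 0.01$, and no multiple-testing
correction is applied (a Benjamini-Hochberg column is trivial to add with
`p.adjust` on the tidy table, and deliberately not the default).

The windowed profile fits, at every start position, one multiple regression
of $y$ on the mutation indicators of ten adjacent positions (step 1; window
positions without variation are dropped from that window's model) and records
the overall model F statistic — a region-level measure of how predictive
local mutation status is of activity. A constant outcome yields $F = 0$; a
window with no varying position yields a missing $F$.

Fold-change classification calls a substitution functional at threshold $T$
when $|E| \ge \log_2 T$ (defaults 1.2 and 2.0). Coding consequences are
annotated by translating the affected codon before and after substitution
with the standard genetic code (stop changes count as non-synonymous), and
the synonymous-versus-functional association is tested with a two-sided
Fisher exact test.

## Spatial clustering of effects

To ask whether nearby positions carry similar effects, the lag statistic

$$S(d) = \sum_i |E_i - E_{i+d}|$$

is compared with its permutation distribution: the defined effect sizes are
shuffled uniformly (missing positions stay missing and are excluded
pairwise), $S(d)$ is recomputed, and
$p(d) = \frac{1 + \#\{S_{perm}(d) \le S_{obs}(d)\}}{n_{perm} + 1}$
over 1000 permutations by default. Two deliberate choices: the $+1$
smoothing keeps p-values away from exactly zero (a raw fraction is the
historical convention; ours is the standard finite-sample correction, and the
difference is at most one part in a thousand), and one permutation per
replicate is shared across all lags, preserving the cross-lag dependence of
the permutation distribution (per-lag permutations are available via
`share_permutations = FALSE`).

## PSSM mark scores

Each observed variant is scored against a motif collection in a 51-bp window
centred on the variant (truncated at the sequence ends while keeping the
variant as central as possible). For a motif of length $L$ with column
probabilities $m_{i,j}$ and background $B$, every $L$-subsequence overlapping
the central base is scored as $\sum_j \log_2 (m_{b_j, j} / B_{b_j})$ bits;
`Score_r` and `Score_m` are the maxima for the reference and mutant alleles,
over offsets and (by default) both strands. A TF is admitted only if either
score exceeds its relative entropy
$H = \sum_j \sum_i m_{i,j} \log_2(m_{i,j}/B_i)$ — an information-content
gate that suppresses matches no stronger than the motif's own divergence from
background — and the admitted TF with the largest $|Score_m - Score_r|$ is
reported, with deterministic ties broken by name. Both $H$ and the scores
are in bits so the gate compares like with like; count matrices are
normalized with a pseudocount, $(c + 0.25)/(\text{total} + 1)$ per cell, so
no log is taken of zero. An all-background matrix has $H = 0$ and would admit
everything; it is uninformative and should be excluded upstream.

JASPAR (`>` header plus four base rows) and TRANSFAC (`P0`-headed numbered
blocks) parsers are included; the TRANSFAC dialect accepted is the common
`ID`/`P0`/`XX`/`//` block form.

## Cross-condition comparison

Per-position effect profiles of two conditions are standardized to mean 0,
sd 1 over defined positions, differenced, and smoothed with loess (degree 1,
tricube, default span 0.1). Differential clusters are maximal runs with
$|smoothed| \ge 1.5$ of width $\ge 4$. The span, threshold and width are
configuration, not statistics: the comparison is descriptive, and clusters
should be read as annotations, not tests. The bundled pipeline uses span
0.05 — a bandwidth comparable to the TFBS-scale (~10 bp) features its
landscape plants — because a smoother twice the feature width would average
a real differential cluster into the baseline. Standardization uses all
defined positions, not only significant ones.

## The synthetic-data generator

The generator exists so that every downstream stage has inputs with the
statistical structure the analysis assumes:

- **Library**: each mutable position of each haplotype independently retains
  the designated base with probability `doping` (default 0.97) or becomes one
  of the other three bases uniformly; tags are uniform 20-mers, re-drawn on
  collision. At the defaults a haplotype diverges at ~3% of mutable
  positions, i.e. ~17 substitutions on a 560-position element.
- **Effect landscape**: zero outside `n_clusters` (default 5) non-overlapping
  clusters of `cluster_width` (default 8) adjacent mutable positions —
  TFBS-sized functional elements; within clusters each substitution's
  magnitude is uniform on [0.5, 2] log2 units and negative with probability
  0.9, reflecting that strong regulatory variants predominantly reduce
  activity.
- **Readout**: haplotype activity is multiplicative in fold change,
  $A_i = 2^{\sum E + \varepsilon}$ with $\varepsilon \sim N(0, 0.25)$ log2
  units of lognormal noise (~19% CV, a realistic clone-to-clone scale); the
  tag is detected in each aliquot independently with probability
  $\min(1, c \cdot A_i)$, capture efficiency $c = 0.2$ by default so a
  wild-type haplotype is seen in ~6 of 32 aliquots and two-fold increases
  stay in the linear regime (clipping at 1 is counted and warned about).
  Detected cells receive Poisson(50) read counts so the quality and
  ten-read filters are exercised. The true activity-to-presence relation of
  the assay is not published; this detection model is an assumption of the
  simulator, chosen as the simplest mechanism whose expectation is linear in
  activity, and it is the package's own construct rather than a described
  property of the assay.
- **Subassembly reads**: fragment breakpoints fall uniformly along the cloned
  construct — including the cloning context flanking the tested sequence —
  so coverage is uniform across the element; terminal reads are clipped to
  the reference span (the flanking context is not part of the reference), and
  substitution errors are injected per base (default $10^{-3}$), with
  constant Q37 qualities and the exact tag on the index read. Had breakpoints
  been restricted to fully-internal starts, edge coverage would ramp down to
  ~0.2x and edge haplotypes would be unrecoverable at any nominal depth;
  allowing construct-wide breakpoints mirrors how tagmentation of a larger
  amplicon actually covers the element's ends.

What the generator does **not** emulate: PCR amplification bias, indels,
positional quality decay, tagmentation insertion bias, UMI structure, or
cross-contamination between aliquots. Passing tests on synthetic data
therefore demonstrate the pipeline's correctness under its stated model, not
robustness to those artefacts.

Every generator is a pure function of its parameters and a seed, and
`run_mpra_experiment()` derives all stages from the single seed in its
configuration.

## Subassembly design

Because doped libraries contain substitutions only, read placement is
ungapped: every exact 15-mer of a read is looked up in a reference k-mer
index (ambiguous reference k-mers are excluded), the offset consistent with
the most anchors wins, ties or anchor-free reads are unplaced, and an
accepted placement must have at most $\lceil 0.1 \cdot \text{read length}
\rceil$ mismatches. Per tag, bases are called by majority vote: a call
requires coverage $\ge 3$ and majority fraction $\ge 0.8$; a position with
sufficient coverage but a split vote marks the whole call `conflicted`
(this is how tag collisions — two haplotypes sharing a tag — surface, and
they are never silently averaged); positions below the coverage floor are
assumed wild type by default (`assume_wt = FALSE` demotes such calls to
`low_coverage` instead). The thresholds are this package's declared choices,
not published values, and are reported in the call table. One consequence
worth knowing: near the coverage floor a single sequencing error can push a
position's majority below 0.8 and mark the haplotype conflicted — at 20x
mean coverage this affects well under 1% of tags, at 8x several percent, so
depth buys yield, not correctness.

## Problem sizes and numerical choices

The packaged tests and the default experiment use the study-scale geometry:
a 600-bp element with 20-bp masked flanks (560 mutable positions), 10,000
haplotypes, 16 aliquots x 2 replicates, 20x subassembly coverage, 1000
permutations. The complete default experiment runs in about two minutes on
one CPU. Calibration checks (null p-value uniformity, lag-test size) are
Monte Carlo and asserted with binomial/Kolmogorov-Smirnov tolerances stated
in the tests themselves. Coordinates are 1-based along the tested sequence
everywhere in tables (matching how variants like "325 G>C" are written);
BED exports are 0-based half-open. Degenerate inputs error early and
explicitly: no variation at a requested position, constant profiles under
standardization, windows wider than the element, motifs longer than their
scan window.

## Limitations

The inference is deliberately the assay's classical one: ordinary least
squares on a bounded count outcome, raw p-values, no dispersion modelling —
adequate for ranking and display thresholds, but not a calibrated generative
model of aliquot counts near the boundaries ($y$ near 0 or $K$). Tag
sequencing errors are filtered by quality, not corrected (no
Hamming-distance-1 merging). Indels are out of scope throughout, by library
design. The comparison stage annotates differential clusters descriptively
and attaches no significance to them.
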