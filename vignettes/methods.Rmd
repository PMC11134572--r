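---
title: "Methods: population-weighted HLA-DRB1 immunogenicity scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-weighted HLA-DRB1 immunogenicity scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemrisk)
```

This vignette is the package's own account of the model it implements: the
scoring machinery, the population-weighting and individual (allele-pair)
variants, the statistical comparison, the synthetic-data generator the test
suite rests on, and the numerical and design choices that were genuinely
open.

## The scanning model

A protein of length $L$ is decomposed into its $L-8$ overlapping 9-mer
frames (1-based start positions, step 1), the canonical binding-register
length for HLA class II. Each frame is scored against one
position-specific scoring matrix (PSSM) per HLA-DRB1 allele: a $9 \times
20$ table of real-valued scores, with the raw frame score the sum of the
nine indexed entries. Additivity over register positions is the standard
PSSM convention and the only functional form this package supports.

Raw scores are calibrated per allele against a background amino-acid
distribution $b$ (uniform by default; a proteome composition can be
supplied). Under the null that the nine residues are drawn i.i.d. from
$b$, positions are independent, so the null mean and variance are sums of
the per-position background-weighted row moments:

$$\mu = \sum_{k=1}^{9} \sum_r b_r M_{kr}, \qquad
  \sigma^2 = \sum_{k=1}^{9}\Big(\sum_r b_r M_{kr}^2 - \big(\sum_r b_r M_{kr}\big)^2\Big).$$

The frame Z-score is $(\text{raw}-\mu)/\sigma$. This calibration is
analytic and deterministic — no Monte-Carlo reference set — which is why
every downstream quantity is reproducible bit-for-bit. Whether production
scoring systems calibrate per-allele against a peptide reference set or
fixed tables is not public; the analytic background calibration is this
package's documented stand-in, and the matrices themselves are inputs (the
package ships none).

Cells with $Z \ge 1.64$ (upper ~5% of the null) are **hits**; $Z \ge
1.28$ (upper ~10%) are **likely** hits. Both comparisons are inclusive:
a tie at the cutoff classifies upward. Only the 1.64 tier contributes to
protein scores; the 1.28 tier is reported but unscored, since there is no
public statement that the likely tier enters the aggregate, and scoring a
single well-defined tier keeps the null expectation exact.

## The protein score

With $A = \text{frames} \times \text{alleles}$ assessments and $O$ the sum
of Z-values over hit cells, the length-normalized score is

$$\mathrm{score} = \frac{O - A\,e_0}{A} \times 1000,
  \qquad e_0 = \mathbb{E}\big[Z\,\mathbf{1}(Z \ge \theta)\big] = \varphi(\theta)$$

with $\varphi$ the standard-normal density and $\theta = 1.64$, so $e_0 =
0.10396$. The score of a protein with no hits is therefore $-1000\,e_0 =
-103.96$ (the floor), and the expected score of a background-random
protein is zero. The published score scale this mirrors spans roughly
$-70$ to $+60$ for real biologics, with reference medians $-9.05$ (human
proteome) and $-23.08$ (secreted proteins) shipped as annotation constants
(`reference_annotations()`); those two numbers summarize external
proteome-wide runs with proprietary matrices and are flagged
non-recomputable. The choice of *hit-Z mass* (rather than hit counts) as
$O$ was open; Z-mass is retained because it makes the score continuous in
the underlying binding strengths and gives the closed-form null $e_0$.

**Tregitope adjustment.** Registry peptides (regulatory T-cell epitopes
conserved in antibody frameworks) are located by exact substring match;
overlapping or abutting matches merge into maximal covered runs. A frame is
masked only when its entire 9-mer lies inside a covered run — frames
straddling a boundary are kept, since a straddling frame is not a peptide
the Tregitope evidence speaks to. Masked frames contribute zero to $O$
while $A$ is unchanged, which gives the invariant
$\text{adjusted} \le \text{raw}$, with equality exactly when no hit frame
is masked. No fuzzy matching is attempted.

## Population frequencies and differential pairs

Carrier frequencies (fraction of individuals carrying an allele, as
population surveys report them) are aggregated across studies by
sample-size-weighted mean; an allele unreported by a study counts as 0
there (renormalizing over reporting studies is available as a flag, but
treating silence as absence is the conservative default for surveys that
enumerate all observed alleles). The analysis panel keeps alleles strictly
above 1% carrier frequency in at least one population; all three filters in
the package (1% panel, 5% joint probability, 5% difference) are strict
inequalities, matching how the cutoffs are stated.

The joint carrier probability of a pair is modeled as the product of the
two carrier frequencies, with the homozygote the square — carriage of the
two alleles treated as independent. A Hardy–Weinberg genotype alternative
($p = 1-\sqrt{1-P}$ conversion, `carrier_to_allele_freq()`) is provided as
a utility but is not the default: the carrier-product convention is the one
validated against the packaged two-population table, where it yields
exactly six Japanese-dominant pairs (over DRB1\*09:01, \*04:05, \*15:02)
and three Caucasian-dominant pairs (over DRB1\*03:01, \*07:01). All panel
pairs are enumerated; no restriction to disease-associated alleles is
applied.

The packaged table carries a representative aggregate sample size per
population (5000 Japanese, 20000 Caucasian) because the per-study sizes
behind the aggregation are not part of the table. These sizes matter only
to the resampling stage below — differential pairs and panel filtering
never use them — and were chosen once as plausible multi-study totals for
allele-frequency registries, the Caucasian compilation being several times
larger than the Japanese one.

## Frequency-weighted scores and resampling

For a weight vector $w$ (carrier fractions restricted to the panel and
renormalized to sum to 1) and per-allele hit-Z content $o_a$ over $F$
frames,

$$\mathrm{score}_w = \Big(\frac{\sum_a w_a o_a}{F} - e_0\Big) \times 1000,$$

which reduces exactly to the unweighted score under uniform weights.
Renormalization makes scores comparable across populations with different
panel coverage.

Population score distributions use a parametric bootstrap: each resample
draws, for every panel allele, a carrier count from
$\mathrm{Binomial}(n, P_a)$ at the table's aggregate size $n$ and divides
by $n$. Alleles are resampled independently; a joint (Dirichlet-style)
alternative was considered and rejected because carrier frequencies, unlike
genotype frequencies, are not sum-constrained. Resample $i$ uses a
deterministic substream of the run seed shared by both populations, so
resample $i$ of population A and population B form a pair under common
random numbers — this is what justifies the *paired* signed-rank test
downstream on two otherwise independently resampled populations. The
default of 100 resamples matches the design this emulates; distributions
are summarized by median and quartiles (type-7 linear interpolation).

## Individual (iTEM) scores

The score for an individual carrying alleles $\{a,b\}$ restricts the
aggregation to that pair:

$$\mathrm{iTEM}(a,b) = \frac{o_a + o_b - 2Fe_0}{2F} \times 1000 \quad (a \ne b),
  \qquad \mathrm{iTEM}(a,a) = \frac{o_a - Fe_0}{F} \times 1000.$$

A homozygous pair counts the allele once; duplicating numerator and
denominator would give the identical value, so the convention is
value-neutral and the homozygote equals the single-allele protein score
exactly. Earlier published formulations of individual scores used different
normalizations (including cross-conservation corrections that are not
applicable to antibody frameworks without modification); this package keeps
the same per-1000-assessment normalization as the protein score so that
pair scores, panel scores, and weighted scores live on one scale, with
$\min_\text{pairs} \le \text{panel score} \le \max_\text{pairs}$.

Quartile placement of a pair within the all-pairs adjusted-score
distribution uses type-7 quantiles with boundary ties assigned downward
(score $\le Q_1$ is quartile 1, $> Q_3$ is quartile 4).

## Statistical comparison

Paired population scores are compared with the Wilcoxon signed-rank test
(two-sided; zero differences dropped, the classical convention — a Pratt
mode is a flag). The exact null is used for $n \le 25$ without ties,
otherwise the normal approximation with tie and continuity correction; the
implementation delegates the p-value to `stats::wilcox.test` and is
cross-checked in the tests against brute-force enumeration of all $2^n$
sign patterns. Multiplicity across biologics is handled by the six
canonical adjustments {Bonferroni, Holm, Hochberg, Hommel, BH, BY} via
`stats::p.adjust` — the canonical six, fixed because no specific set is
mandated. The effect size is the matched-pairs rank-biserial correlation
$r = (W^+ - W^-)/(W^+ + W^-)$, with categorical interpretation tables
(Cohen-style and Evans-style) shipped as editable data frames rather than a
single hard-coded authority. ATA rates across clinical studies are
aggregated by participant-weighted mean over non-excluded studies, with
optional monotherapy-only filtering.

Note one deliberate reading: "comparing medians by signed-rank test"
conflates a median contrast with a paired test; the package tests the
paired resample scores and reports medians descriptively.

## The synthetic-data generator

The generator exists so the full pipeline runs and is testable with no
proprietary inputs; it is first-class, seeded, and emits the same file
dialects the pipeline consumes.

- **Matrices** have i.i.d. Gaussian entries. Averaged over the entry
  distribution the raw-score null is exactly normal, so the analytic
  $e_0$ and the ~5% hit rate are exact expectations rather than
  approximations — this is why the null-calibration checks draw a fresh
  matrix panel per protein.
- **Planted proteins.** Plant residues are chosen greedily: per register,
  from the target allele's top candidates, preferring residues with low
  off-target load, then locally swapped until every off-target allele at
  the planted frame stays below the likely tier. A feasibility bound then
  checks each frame overlapping a plant (its fixed residues plus row minima
  for the free ones); infeasible picks are re-drawn with jittered candidate
  choice. Background residues are repaired by coordinate descent on the
  summed Z-excess above a cap just under the likely tier (1.26), with
  random perturbation of a stalled frame's free residues, bounded restarts,
  and a generation error if the specification is truly unsatisfiable.
  The result is a protein whose planted cells score $Z \ge$ target and
  whose every other cell sits below 1.28 — ground truth is exact, so
  scanning must recover the plants with zero misses and zero extras.
- **Tregitope spans** are registered from the finished sequence at the
  requested coordinates, so they match exactly where planned.
- **Population tables** carry exactly the requested carrier fractions
  (optionally binomially noised), giving closed-form control over which
  pairs clear the differential floors; **paired samples** add a location
  shift to one arm over a shared component, for power and type-I
  calibration of the test layer.

What the generator does *not* emulate: real biologic sequences and their
framework/CDR structure, genuine binding matrices (entry correlations,
anchor-position structure), linkage between HLA loci, or per-study
heterogeneity behind a frequency table. Passing tests therefore demonstrate
that the machinery is correct and calibrated under its stated null — not
that any particular real biologic is risky or safe.

## Problem sizes and numerical choices

The shipped checks use: 200 random length-300 proteins (5 fresh alleles
each) for null calibration; 50 seeded planting specifications for exact
recovery; 1000 random length-100 proteins for the adjustment invariant; 100
resamples per population; 200 replicates for type-I calibration at
$n = 100$ pairs. These sizes give Monte-Carlo standard errors comfortably
inside the asserted tolerances while keeping a full run in tens of seconds.

Numerical conventions, collected: inclusive thresholds; strict filter
inequalities; type-7 quantiles with boundary ties down; variance of null
moments computed in centered form (so constant matrices are exactly
degenerate, $\sigma = 0$, and are refused for Z-scoring); percentages on
the 0–100 scale in every file, fractions internally; 1-based inclusive
coordinates in all outputs; all randomness flows from explicit seeds
through per-index substreams, and the run manifest records config,
checksums and seed (the manifest's timestamp is the one run output that is
not byte-stable).

## Limitations

Absolute scores depend entirely on the supplied matrices: with synthetic
matrices the package's scores are calibrated but not comparable to
published values for named biologics, and no claim about a real drug should
be made from them. The frequency machinery treats allele carriage as
independent (no linkage), class II scope is HLA-DRB1 only, and ATA
aggregation is a weighted mean, not a meta-analysis.
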