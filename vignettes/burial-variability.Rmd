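---
title: "Burial versus variability in channel domains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burial versus variability in channel domains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardscan)
library(dplyr)
```

`ardscan` joins two kinds of evidence about a residue: how buried it is in
the folded structure, and how many distinct amino-acid substitutions the
human population tolerates there. Under near-neutral expectations the two
agree — exposed residues accumulate variant types, buried ones do not — so
a buried residue with many variant types is informative. This vignette
records the model and every consequential design decision, in the order
the pipeline runs.

## Variant spectra

Variant exports carry one row per (nucleotide-level) variant with a protein
consequence in HGVS p. notation and an allele count. We define a **variant
type** as a distinct alternate amino acid at a position, regardless of the
underlying nucleotide change: two different codons both producing Val at
position 309 are one type. Duplicate (position, alt) rows are therefore
*summed*, never deduplicated. Type counts deliberately ignore allele
abundance; abundance enters only the per-position spectrum (counts
normalized to the most common alternate amino acid, so the top allele is
exactly 1).

Rows that are not missense — nonsense (`Ter`), frameshift (`fs`), indels,
synonymous — are rejected with a distinct error class per cause so file
readers can count skip reasons. Rows lacking an allele count default to 1
with a warning: an observed variant implies at least one allele. Numbering
conventions between orthologs (human TRPV1 M309 vs rat M308) are handled
by constant-offset maps; per-segment offset maps can be composed by
applying different maps to row subsets. Anything beyond constant offsets
(true liftover, transcript-level consequence calling) is out of scope.

## Solvent accessibility

SASA is computed by the Shrake–Rupley method with a probe radius of 1.4 Å
(water) and 960 test points per atom. The point set is a golden-spiral
(Fibonacci) lattice — deterministic, seedless, near-uniform — so results
are bit-reproducible and the isolated-sphere closed form 4π(r+p)² is
matched to well under 1% at the default point count (the test suite checks
1%). Doubling the point count moves helix-fixture totals by less than 1%,
which is why 960 is the default rather than something larger. Hydrogens,
heteroatoms and waters are excluded; for alternate locations the
highest-occupancy conformer is kept; coincident atoms are a hard error
(degenerate geometry) rather than silently producing garbage. Van der
Waals radii are a fixed per-element Bondi-type table; unknown elements
fall back to 1.8 Å with a warning.

Fractional SASA divides residue SASA by the Tien et al. (2013)
*theoretical* maximum for that amino acid. Theoretical (rather than
empirical) maxima keep the normalization geometry-independent; values
above 1 can then occur for highly exposed residues and are reported as-is,
with a warning above 1.2.

**Assembly context.** Burial is computed in the context of all chains
selected for the calculation and then reported for one chain. For a
tetrameric channel the biologically meaningful default is the full
assembly — a residue at a subunit interface is buried in the tetramer even
if exposed in an isolated subunit — so `compute_sasa()` defaults to every
chain present in the file. Whether a published ranking used the assembly
or an isolated domain is often unstated; this choice shifts ranks of
interface residues and is the first thing to vary when reconciling ranks
against external analyses.

## The burial profile and discordance score

Residues are sorted by fractional SASA ascending (most buried first), ties
broken by ascending residue number, ranks 1..N. Residues present in the
sequence but absent from the structure have no SASA and are dropped with a
warning, never imputed. Variant-type counts are joined onto the ranking
(absent positions count 0 types) and smoothed along the rank axis with a
**centered moving mean of width 20 ranks, truncated at the edges** (the
divisor is the number of in-window points). The truncated mean is linear,
constant-preserving and bounded by the input range; window 1 is the
identity and an interior impulse smooths to 1/20. A mean was chosen over a
sum or kernel because it keeps the smoothed series on the same scale as
the raw counts, which is what makes the discordance score below
interpretable as "excess types over local expectation".

The discordance raw score at residue *i* is `n_types_i − smoothed_i`.
Significance uses the exchangeable null "type counts carry no burial
information": counts are permuted across ranks, the permuted profile is
re-smoothed, and the p-value at rank *i* is the fraction of permutations
(plus one, over B+1) whose permuted raw score *at that rank* reaches the
observed one. These are **marginal, unadjusted** p-values — exactly
uniform at any fixed rank under the null, which the test suite verifies by
KS test over 200 seeded null replicates — and a whole-profile screen
should apply `p.adjust()`. A family-wise alternative (comparing each score
against the permutation distribution of the buried-half *maximum*) was
considered and rejected: because permutations relocate an outlier's own
count into the buried half about half the time, the maximum-based p-value
of even a dramatic planted outlier never becomes small, and the statistic
ends up dominated by window-edge effects rather than by the signal.

Conservation of the candidate position is read from an aligned FASTA: the
reference's non-gap letters are counted from its stated first residue
number to locate the alignment column, and identity is the fraction of
sequences with a non-gap letter there that match the reference letter
(gaps leave the denominator).

## Functional assays

**Hill fits.** Normalized responses are fitted to
`I = I_max·[L]ⁿ/(EC50ⁿ + [L]ⁿ)` with all three parameters free, by
Levenberg–Marquardt under bounds EC50 ∈ (0, 100] µM, n ∈ (0, 10].
Because the Hill surface has local minima when n starts far from truth,
the optimizer is started from the 3×3 grid EC50 ∈ {0.03, 0.3, 3} µM ×
n ∈ {1, 2, 4} (I_max started at the largest response) and the
lowest-residual fit is kept. Convergence tolerances are set tight
(ftol = ptol = 1e-15) so that the noiseless forward model is inverted to
below 1e-6 relative error — the package's own exactness test. A fit that
fails to converge is returned flagged, not raised, so batch analyses keep
going. Normalization divides by the response at the 5 µM capsaicin
reference (mean, if replicated); a missing or zero reference is an error.

**Single-channel open probability.** The analysis segment (+80 mV by
default) of each sweep is extracted and concatenated in sweep order. The
baseline is a rolling 10th percentile over 1 s windows (evaluated on a
quarter-window stride and linearly interpolated — at 20 kHz an exact
per-sample rolling quantile buys nothing but cost). A low percentile
tracks drift while ignoring openings, but it sits a fixed noise-quantile
below the closed level, so the subtracted trace is recentred by the mode
of its amplitude density; this assumes the closed state is the dominant
state (Po below about one half), which holds for the recordings this
analysis targets. Idealization assigns each sample the occupancy level
`m ∈ [0, k]` whose band `((m−½)i, (m+½)i]` contains it — half-amplitude
thresholds — and Po is mean occupancy over k channels. Openings are
treated as positive deflections; a polarity flag covers −80 mV segments.
This estimator is exact on square waves and unbiased on two-state Markov
simulations within Monte-Carlo error (checked at Po = 0.3, 60 s at
20 kHz, noise 0.1·i, where the misclassification probability at
half-amplitude is Φ(−5) ≈ 3·10⁻⁷ per sample). Event durations, hidden
Markov idealization and drift modelling beyond baseline subtraction are
out of scope.

**Macroscopic approximate open probability** is the current under a
condition divided by the maximal 5 µM capsaicin response. It approximates
Po only under the assumption that the reference saturates the channel
(Po ≈ 1 at 5 µM); the assumption is documented, not asserted, and ratios
above 1 are reported with an `over_unity` flag rather than clipped.

**Temperature relations.** Each cell's steady-state +100 mV currents are
normalized by that cell's mean current inside the room-temperature window,
defined as 20–25 °C (the term "room temperature" made concrete). Cells
are pooled and summarized per 2 °C half-open bin (centers at odd degrees)
with the median across cells and its standard error. The room-window bins
sit at ~1 by construction, which the tests check.

**Calcium-imaging responder fractions.** The published counting procedure
this replaces was a manual brightness judgment on contrast-adjusted
movies; here it operates on per-cell traces (segmentation is out of
scope) with an explicit rule: baseline F₀ is the mean of pre-capsaicin
frames; a cell responds to capsaicin if peak ΔF/F₀ between the capsaicin
and ionomycin additions reaches θ, is ionomycin-only if the threshold is
reached only after the ionophore, and is otherwise excluded — including
cells that start bright and stay flat, and cells with non-positive
baseline. θ defaults to 0.5, a deliberately conservative stand-in for a
qualitative judgment, and should be reported with any result. The
response fraction is responders over healthy cells (responders +
ionomycin-only); excluded cells never enter the denominator; same-day
control normalization is a plain ratio with identity at self.

## Synthetic data: what it does and does not show

The generators produce the statistical structure the analysis assumes, at
the acquisition settings of the real experiments (20 kHz sampling, 60 s
single-channel stretches, the capsaicin series 0.03–10 µM, capsaicin at
30 s and ionomycin at 2 min of a 3 min movie at 0.5 s frames), so every
operation can be validated against known ground truth:

- variant tables with type counts ~ Poisson(exp(a + b·fracSASA))
  truncated at 19, allele counts 1 + Geometric(0.3), and optional planted
  buried outliers;
- ideal α-helix (or extended-strand) PDB files built from standard
  backbone geometry, used to round-trip the reader and to provide
  end-exposed / maximally-exposed fixtures;
- two-state Markov gating sampled from stationary initial conditions,
  with Gaussian noise and linear drift;
- Hill dose–response tables with additive noise (σ = 0.05 by default, a
  typical normalized-current scatter);
- two-state van 't Hoff temperature activation (default ΔH = 100
  kcal/mol, T½ = 45 °C — the steep heat sensitivity characteristic of
  TRPV1) on a 10–60 °C ramp with a leak floor;
- cell fields with step responses and multiplicative noise.

Recovery under these conditions shows the estimators are correctly
implemented and calibrated; it does not show robustness to what real data
add — filtering artifacts, correlated noise, multi-state gating, bleaching,
rundown, solution-exchange kinetics, mis-segmented cells. Those belong to
the acquisition and preprocessing stages the package deliberately leaves
outside its scope.

Every generator takes an explicit integer seed, restores the caller's
random state (`withr::with_seed`), and is bit-reproducible: same seed and
configuration, identical output.

## Problem sizes and test budget

The shipped checks use sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping the default suite fast on a
laptop: 200 replicates for Hill EC50 recovery and for null-calibration KS
(199 permutations each), 100 seeds for the burial-correlation premise,
999 permutations for single discordance analyses, one 60 s × 20 kHz
(1.2 M sample) trace for open-probability checks, and 150–200 residue
profiles. The full suite runs in well under a minute.

## Known limitations

- SASA is numerical (point-sampled), not analytic; accuracy is set by the
  point count, and only heavy atoms of standard residues are supported.
- The discordance score formalizes a visual outlier reading; its p-values
  are marginal and the score inherits the smoothing window: outliers
  within ~10 ranks of the burial edge gain or lose a little from window
  truncation.
- The rolling-percentile baseline assumes the closed state dominates;
  patches spending most of their time open need the polarity/percentile
  assumptions revisited.
- Numbering maps are constant-offset; indel-containing ortholog pairs
  need an externally supplied alignment instead.
- Fractional SASA, and hence ranks, depend on the chosen assembly context
  (isolated domain vs full assembly); report the context alongside ranks.
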