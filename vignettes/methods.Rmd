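---
title: "Methods: chromatin states, cell programs, synergy and interactor filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin states, cell programs, synergy and interactor filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette describes the statistical procedures implemented in
`plastichrom`, the choices made where the design was genuinely open, and
what the synthetic data do — and do not — establish about behaviour on
real data. The biological setting is EZH2/PRC2-driven phenotypic
plasticity in prostate cancer models: promoters poised between activation
(H3K4me3) and Polycomb repression (H3K27me3), lineage programs shifting
under EZH2 inhibition, drug combinations probed for Bliss synergy, and
EZH2 protein partners nominated from RIME spectral counts.

## Four-state chromatin classification

Each promoter in each condition is classified from the presence of two
histone marks in a window around its TSS:

| H3K4me3 | H3K27me3 | state     |
|---------|----------|-----------|
| +       | −        | Active    |
| −       | +        | Repressed |
| +       | +        | Bivalent  |
| −       | −        | Unmarked  |

Presence means "any peak interval overlaps `[tss − w, tss + w)`",
computed on BED-style 0-based half-open coordinates with
GenomicRanges. The window default is ±2,000 bp: wide enough to absorb
peak-summit jitter around annotated TSSs, narrow enough that promoters of
neighbouring genes rarely collide; it is a parameter everywhere. Peak
calling itself is out of scope — the package consumes peak calls. State
calling from peak overlap (rather than signal thresholds or HMM
segmentation) is a deliberate, documented choice; it is the simplest
operationalisation of "marked", and the round-trip tests show it is exact
on data generated under that definition, not that it is optimal on noisy
signal.

Transitions between two conditions are tabulated over genes called in
both (genes seen once are reported separately, never counted), giving a
4×4 count matrix whose row-normalisation estimates the transition kernel.
Under multinomial sampling each empirical cell has standard error
`sqrt(p(1−p)/n_row)`; the recovery tests require agreement within three
of these.

To ask which chromatin classes are most targeted by EZH2 inhibition,
each condition-2 state (and each state1→state2 pair) is tested for
over-representation of up- (or down-) regulated genes with a one-sided
hypergeometric test against the background of all jointly-called genes,
Benjamini–Hochberg-adjusted within each level. Both the enrichment
ranking and raw DE counts are reported, since either reading of "most
significantly targeted" is defensible.

## Single-cell program scoring

Counts are depth-scaled to the median cell total and `log1p`-transformed.
A program score is the mean of per-gene z-scores (across cells) over the
member genes — the "average Z-score" construction. Zero-variance genes
carry no ranking information and are dropped with a warning; a fully
constant set is an error rather than a silent NaN. A binned
control-gene scheme (as in some single-cell scoring tools) was
considered and rejected: the plain z-mean is what the downstream
visualisations assume, and it is exactly verifiable by hand.

Subtype assignment is argmax over marker-set scores, by default at
cluster level (clusters, not cells, carry subtype labels in this
setting), with the margin to the runner-up reported and exact ties
labelled `ambiguous`. Master-regulator TF modules use the field's
numbering — NEPC-associated TFs module 0, transition-associated module 1,
adenocarcinoma-associated module 2 — as an argmax over the three group
scores with a fixed-order tie-break (NEPC, transition, adeno). How the
original analysis combined pseudotime, subtype and TF expression into
modules is not fully specified; argmax over group scores is this
package's explicit choice, and per-module pseudotime and subtype
composition are attached as diagnostics so the assignment can be
inspected rather than trusted.

Pseudotime is consumed, not computed. Profiles along pseudotime use
`stats::smooth.spline` at a user-set degrees of freedom (default 5,
minimum 3) evaluated on a 100-point grid; a constant score short-circuits
to a constant fit. The spline df must stay below the number of distinct
pseudotime values.

Differential expression between cell groups is a Wilcoxon rank-sum test
per gene on normalized expression (normal approximation with tie and
continuity correction), with effect size `log2((mean_A + 1)/(mean_B + 1))`.
The ranking statistic for GSEA is `sign(lfc) × (−log10 p)`, with exact
ties broken by gene id so rankings are reproducible. The per-gene test is
not named in the source analyses; rank-sum was chosen as the common
robust default for single-cell contrasts.

## Pre-ranked GSEA

The enrichment score is the classical weighted Kolmogorov–Smirnov running
sum: walking down the ranking, member genes add `|stat|^p` (normalized to
sum 1 over the set; `p = 1` by default) and non-members subtract
`1/(N − n)`. ES is the extreme deviation; when the positive and negative
deviations tie exactly in magnitude (which happens for symmetric hit
placements) the positive one is reported — the comparison tolerates
floating-point noise of about `1e-9` so the tie-break is stable. By
construction `|ES| ≤ 1`.

The null is gene-label permutation: random sets of the same size drawn
from the ranked list, which is why null distributions can be shared
between sets of equal size. NES divides ES by the mean `|permutation ES|`
of matching sign; the FDR q-value is the standard NES-ratio estimator
pooling permutation NES across sets. Defaults mirror the study's
reporting conventions: q < 0.25 for bulk contrasts (with 10,000
permutations at full scale), FDR < 0.01 and |NES| > 1 for single-cell
subtype contrasts; both are configuration keys, and the package default
of 1,000 permutations keeps routine runs fast while remaining well above
the enforced minimum of 100.

## Bliss synergy landscapes

Plates are normalized well-wise to the mean of the (0, 0) control wells
of the same replicate; replicates are averaged after normalization.
Inhibition `1 − viability` is clamped into [0, 1] with a logged count —
stimulation above control is not propagated because the Bliss formula
`E_a + E_b − E_a·E_b` is undefined outside the unit square. Monotherapy
effects are read directly off the plate's own zero-dose margins (no
dose–response fitting), so the synergy score
`δ = 100 × (observed − expected)` is a per-well quantity in percentage
points, computed per replicate and then averaged. The landscape summary
is the arithmetic mean of δ over combination wells only (δ is identically
zero on the margins, so including them would only dilute the average
toward zero). Margin-smoothing via a fitted logistic was considered and
rejected for the default: it trades transparency for model dependence,
and the summary definition in use is the plain landscape average.

## RIME interactor nomination

Two filters are implemented as explicit modes because the source
describes two non-identical procedures, and reconciling them silently
would misrepresent both:

* **venn** — spectral count ≥ 5 in *every* bait replicate, and absent
  from the IgG-passing set (count ≥ 5 in *any* IgG replicate
  disqualifies). Used for single-condition lists.
* **fdr** — counts summed per arm; one-sided Poisson rate-ratio test of
  bait vs IgG rates, conditional on the protein total (a binomial test
  with the bait arm's share of total counts as success probability — the
  per-arm totals act as offsets); BH adjustment across tested proteins;
  a hit needs q ≤ 0.1, detection (count > 0) in ≥ 2 of the 4 bait
  samples, and bait rate above IgG rate. Default for differential
  comparisons.

"Detection" in fdr mode deliberately means count > 0, not ≥ 5, because
the source separates detection from enrichment. The count-based test is a
documented stand-in: whether the original FDR came from a count test or
from search-engine decoy FDR is ambiguous. Both modes are monotone —
raising a bait count can never remove a hit, raising an IgG count can
never create one — and the null simulations check that BH at 0.1
actually controls the realised false-discovery proportion.

## Synthetic data: what it emulates and what it does not

The generator fixes the study conditions: 10,000 promoters with an
Active-dominant state mix (45/15/15/25) and a mostly-diagonal transition
kernel with net bivalency gain; negative-binomial counts
(variance `μ + μ²·φ`, dispersion φ = 0.5) for 2,000 cells × 1,000 genes
over five clusters with 25-gene programs shifted 1 log2 unit, and an
EZH2i-response program planted in the genes bivalent in condition 2;
five-dose Bliss surfaces with a +10-point planted interaction and 5%
lognormal plate noise; Poisson spectral counts with 20 bait-enriched
proteins at 20× over a background rate of 5. One master seed fans out to
per-generator child seeds through fixed slot indices
(`(seed × 48271 + slot) mod (2³¹ − 1)`), so adding a generator never
perturbs existing streams and every output is byte-reproducible.

Deliberate simplifications: peaks are exactly promoter-centred (real
peaks have variable width and offset); cells have no depth gradients,
batch structure, doublets or ambient RNA; pseudotime is cluster ordinal
plus jitter, not an inferred trajectory; plate noise is i.i.d. lognormal
with no edge effects; spectral counts ignore peptide-level structure.
Passing tests therefore certify the *procedures* — exact truth-table and
round-trip behaviour, calibrated error control, unbiased recovery of
planted effects — not robustness to artefacts the generator does not
model.

## Numerical and scale choices

Problem sizes in the routine test and acceptance runs are chosen to make
the statistical assertions sharp but cheap: 10,000 promoters for state
and transition recovery; 300 cells × 10,000 genes for the
bivalency–DE integration; 200 simulations for each calibration
(GSEA null, Bliss recovery, RIME FDR) and 20 seeded replicates for the
scoring/subtyping checks. Degenerate inputs fail loudly: mixtures not
summing to one, non-stochastic kernels, empty gene-set overlaps,
missing zero doses, control means ≤ 0 and all-zero count tables are all
errors, not warnings. The pipeline orchestrator isolates stages through
files, records every parameter (including defaults) in output headers,
and writes an MD5 manifest so reproducibility is checkable byte-wise.
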