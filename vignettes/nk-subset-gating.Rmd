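---
title: "Simulating and gating NK-cell chemokine-receptor cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and gating NK-cell chemokine-receptor cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkckr)
```

## The problem

Blood natural killer (NK) cells, identified by flow cytometry as
CD3−CD56+ lymphocytes, divide into a dominant CD56+low CD16+ subset and
a minor CD56+high CD16−/low subset with sharply different chemokine
receptor (CKR) repertoires: CD56+low cells are CXCR1/CXCR2+ (the
neutrophil-like pattern), CD56+high cells CXCR3/CCR5+ (the Th1-like
pattern). When anti-CXCR3 and anti-CCR5 are carried on the *same*
fluorochrome (PE) in one tube, the pooled channel separates a third,
transitional population — CD56+int, pooled-positive, with intermediate
CD56, CD16, CD62L, CD94 and CD122 — whose expansion is of interest in
chronic NK-cell lymphoproliferative disorders (CLPD-NK).

No event-level data from the reference cohort are publicly available,
only per-subset cohort summaries (percent positive, MFI on a linear
0–10,000 a.u. scale, and CV, each as mean ± SD with min–max across
subjects). This package therefore couples three things:

1. a **synthetic-cohort generator** whose event-level model is
   parameterised directly from those published summary cells;
2. a **hierarchical gating pipeline** (isotype-calibrated thresholds,
   CD3/CD56 gate, conventional and pooled-channel three-way splits)
   that re-measures the same statistics from events; and
3. the **inferential layer** used in the original analysis
   (Mann-Whitney contrasts, subject-level correlation, an intermediacy
   verdict, a CLPD-NK-style expansion screen).

The generator's defining contract is that **gated statistics of a
simulated cohort reproduce the published tables**, so that the gating
and statistics code can be validated end to end by parameter recovery.

## The event-level model

Each acquired event belongs to a latent population (T, B, "other",
NK_low, NK_int, NK_high) drawn by frequency. Scatter channels are
Gaussian. Every stained channel is a two-component mixture: a Bernoulli
positivity indicator selects between a *negative* lognormal (background,
mean 3 a.u., CV 100%, matching the near-zero MFI printed for negative
subsets) and a *positive* lognormal. Lognormal components are
moment-matched: `lognormal_from_moments(mean, cv)` returns the
log-location/scale whose arithmetic mean and CV equal the targets
(`cv = 0` degenerates to a point mass). Positivity indicators are
independent across markers within a cell — the reference data report
only marginal per-marker statistics, so no cell-level joint structure is
identifiable; the single quantified association (between %CXCR3+ and
%CCR5+ within CD56+low cells, r = 0.656) is modelled at the *subject*
level instead.

Intensities are clipped to [0, 10000]; top-of-scale pile-up is counted
(`$pileup`) but never discarded.

### Between-subject variability

Every published table cell (a percent-positive or an MFI, with SD and
min–max) becomes a drawable parameter. Subjects draw each cell from a
normal with the cell's SD, truncated to the printed min–max (rejection
sampling, 1000-redraw cap). Two refinements matter:

* **Location adjustment.** A truncated normal centred on the printed
  mean has a realized mean pulled toward the middle of an asymmetric
  range (for the CXCR3-on-CD56+low cell the pull is ≈ +3 points). The
  location parameter is therefore solved numerically so the *truncated*
  mean equals the printed mean; cohort means then recover the tables.
* **Correlated pairs** are realized through a Gaussian copula with
  truncated-normal margins, preserving each margin exactly. The default
  sheet correlates the two CD56+low cells (CXCR3, CCR5) at r = 0.656 on
  the observed (gated) scale — the scale on which the coefficient was
  reported.

CVs are held at their cohort-level values rather than drawn per subject;
this halves the parameter count while the table CV columns are still
reproduced through the event-level model.

### Observed-to-latent calibration

The published numbers are *post-gate measurements*, not latent model
parameters, and the package treats them as such. Three deterministic
inversions connect the two scales; all are computed from the profile
sheet itself (never fitted to simulation output):

* **Mixture-moment inversion.** Tables that report MFI/CV over *all*
  subset events (the CKR table and the CD56/CD16 table) mix positive and
  background components; the positive component's mean and CV are
  recovered by inverting the two-component moment equations. (That the
  all-events convention is the right reading is forced by entries like
  CXCR2 on CD56+high: MFI 3.6 a.u. is background, impossible as a
  positives-only mean.) The adhesion/KLR/IL-2R table states its MFIs are
  over positively stained cells and is used directly. When a drawn
  (pct, MFI) pair is jointly infeasible — positives too dim to be
  observed at the drawn rate under a cutoff — the positive mean is
  raised to the smallest feasible value.
* **Cutoff calibration.** With an isotype cutoff at the 99.5th
  background percentile, a latent positive fraction f is observed as
  `f·P(pos ≥ c) + (1−f)·0.005`. The generator solves this for f, so dim
  populations (e.g. CCR5 on CD56+high, positives at ≈ 53 a.u. against a
  cutoff of ≈ 18) still measure at their printed percentages.
* **Gate-exchange inversion.** Hard gates on overlapping distributions
  exchange events: CD56+int and CD56+high trade places across the CD56
  boundary, pooled-PE false positives promote CD56+low events, CD56
  background false positives admit non-NK cells into the NK gate, and
  in the conventional split CD16+ CD56+high cells fold into the low
  gate. The expected 3×3 (three-way) and 2×2 (conventional) mixing
  matrices are computed from the sheet's own cohort parameters and
  inverted, so the *gated* per-subset percentages reproduce the printed
  ones. The printed CD56+int MFI is likewise a below-boundary clipped
  mean; the latent location is recovered by inverting the clipped-mean
  equation (615 observed ⇒ ≈ 710 latent).

### Protocol-1 tubes and the CD56+int population

The single-receptor (protocol-1) table characterises only the two
conventional subsets, and its "CD56+low" gate unavoidably pools the
true CD56+low and CD56+int populations. The generator therefore gives
NK_int the conventional-low cell for CXCR1/CXCR2/CXCR4/CCR4/CCR6 (so the
pooled gate reproduces the printed value exactly), while for CXCR3 and
CCR5 — for which CD56+int is definitionally positive — NK_int uses the
CD56+high cell and the true-low fraction is obtained from the printed
conventional-low value by the gate-exchange inversion above
(15.6% observed ⇒ ≈ 9% latent true-low CXCR3+).

The pooled PE channel has no printed intensity of its own; both
pooled-positive subsets draw from the bright positive component inverted
from the CD56+high CXCR3 cell. Frequencies of the non-NK populations
(T 73%, B 12%, other 2%, NK 13% of acquired lymphocyte events) are not
reported in the tables and use typical adult peripheral-blood values;
they only set the context the NK gate must cut through.

## Gating

Thresholds come from each subject's own isotype tube: the cutoff is the
order statistic at `ceiling(0.995 · n)` per channel (configurable,
monotone in the quantile; ties at a cutoff count positive). The NK gate
is CD3 below / CD56 at-or-above cutoff.

The CD56 low/high boundary formalises manual cluster selection as a
deterministic two-component Gaussian mixture on log10 intensity:
EM with centers initialised at the 25th/97.5th percentiles, tolerance
1e-6, 200-iteration cap, no randomness, hence exactly reproducible and
scale-equivariant. Because the CD56+high component can be rare (≈ 4% of
NK events), a run whose components collapse is retried once from a
99.5th-percentile initialisation before the fit is declared unimodal.
Collapse is declared when the center separation falls below 1.8× the
geometric-mean component SD — unimodal data split by EM sit near 1×,
genuinely bimodal CD56 data at 3× or more. The boundary is the
equal-density crossing between the centers (geometric mean of centers if
no crossing lies between them); a unimodal fit is flagged
`no_high_component`, the fallback boundary sits above the 99.9th
percentile, and *no* high gate is drawn for that sample — its high-subset
statistics are missing rather than computed from a handful of tail
events.

The three-way split classifies pooled-PE-negative NK events as CD56+low
and splits PE-positive events at the boundary fitted on PE-positive
events only (falling back to all NK events when fewer than 100 are
PE-positive). The conventional split follows the original protocol's
use of both CD56 level *and* differential CD16 positivity: CD56+high
requires CD56 at or above the boundary and CD16 below cutoff, which is
what keeps the rare high gate clean against the heavy upper tail of the
low subset; a consistency check warns when the low gate is under 95%
CD16+.

## Statistics and comparisons

Per subset and marker: percent positive (`≥ cutoff`), arithmetic-mean
MFI over all events or over positives only (an empty positives-only set
propagates as missing, never zero), and CV as 100·(n−1)-SD/mean.
Statistics are computed per subject and only then summarised across the
cohort (mean, sample SD, median with midpoint convention, min–max) —
events are never pooled across subjects, matching the structure of the
published tables.

The Mann-Whitney U test reports `min(U_a, U_b)` with an exact p-value by
full enumeration when both groups have ≤ 8 observations and no ties, and
a normal approximation with continuity and tie correction otherwise (at
the study's n = 13–15 the approximation is in force). Correlations are
Pearson by default with Spearman exposed, since the original method is
not stated; the pipeline reports both. The intermediacy verdict demands
the CD56+int mean strictly between the other two (direction-agnostic)
*and* both flanking contrasts significant. The expansion screen
(`flag_expansion`, default 3 reference SDs, strict inequality) is a
pragmatic rule for CLPD-NK-style screening, not a published procedure.
No multiple-testing correction is applied by default (raw p-values are
reported, as in the reference analysis); `adjust_bh()` is available.

## Problem sizes and reproducibility

All randomness descends from one integer seed; per-subject-per-tube
streams are derived from it, so restricting a configuration to fewer
tubes leaves the remaining tubes' events unchanged, and identical
configurations are byte-identical.

Default acquisition matches the study floor of 2×10^5 events per tube
for 15 subjects; at that scale the full pipeline over the eight tubes
needed for the headline statistics runs in about two minutes. The test
suite exercises the same checks at 2×10^4 events per tube with
tolerances widened 1.5×. Correlation recovery uses 500 replicate
15-subject cohorts at 4,000 events per stained tube (isotype 2,000);
smaller tubes were not used because the within-subject binomial error
then stops being negligible against the between-subject spread
(SD ≈ 8–11 points) and visibly attenuates the recovered coefficient —
at 4,000 events the attenuation is ≈ 0.03, within the recovery
tolerance; at 2,000 it is not.

## What the generator does and does not emulate

It emulates: subset structure and frequencies, marginal marker
distributions matching all printed percent/MFI/CV cells, between-subject
spread and ranges, the subject-level CXCR3–CCR5 association, isotype
background, and top-of-scale pile-up. It does not emulate: instrument
noise models (photon statistics, spillover/compensation), doublets,
acquisition-time drift, cell-level co-expression beyond marker
independence, or non-lymphocyte debris beyond a generic 2% "other"
class. Passing recovery tests therefore validates the pipeline's
measurement and inference logic on data *shaped like* the published
cohort; they cannot validate behaviour against instrument artefacts the
model omits.

## Known limitations

* Gate exchange between overlapping subsets is inverted in expectation,
  but subjects whose drawn values sit near a bound (e.g. 97–100%
  positive) cannot be fully compensated because latent fractions are
  capped at 100%; the CD62L-on-CD56+high recovery, whose printed SD is
  only 2.4 points, remains ≈ 1–1.5 points low at reduced event counts
  for this reason.
* Dim markers measured within bright-majority gates (CXCR4 with its
  ≈ 300% CV, the near-negative CCR4/CCR6 cells) are reproduced at
  background-dominated precision only.
* The CD56+int CV printed for the gated subset is used as the latent
  CV; after boundary clipping the generated gated CV runs a few points
  low. Only the MFI, not the CV, is clip-inverted.
* The mixture boundary is a 1-D formalisation of 2-D manual cluster
  painting; with the printed CVs the int/high overlap is larger than
  clean real-world data would show, so oracle accuracy bounds
  (≥ 98% label agreement) are asserted on well-separated fixtures, not
  on the default profile.
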