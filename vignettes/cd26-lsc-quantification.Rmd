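---
title: "Density-driven quantification of CD26-positive leukemic stem cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-driven quantification of CD26-positive leukemic stem cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd26lsc)
```

## The measurement problem

Chronic myeloid leukemia (CML) is sustained by a small compartment of
leukemic stem cells (LSCs) that are immunophenotypically
CD45+/CD34+/CD38−, like normal hematopoietic stem cells, but additionally
express CD26 (dipeptidyl peptidase-4), which their normal counterparts do
not. Counting CD26+ CD34+/CD38− events in peripheral blood by flow
cytometry therefore gives a cheap, non-invasive readout of leukemic stem
cell burden — at diagnosis, where it may support rapid triage before
molecular confirmation, and under tyrosine kinase inhibitor therapy, where
its decline tracks response.

The difficulty is that this is a rare-event problem: the quantity of
interest runs from roughly 1% down to 0.001% of CD45+ leukocytes, i.e.
single-digit event counts in a standard 100,000-event acquisition.
`cd26lsc` implements the full workflow as deterministic, auditable code:
sequential density-driven gating, an internal-control CD26 cutoff,
per-sample quantification, and the cohort-level nonparametric statistics.

## The gating model

Every gate is a one-dimensional threshold on a display scale on which
density estimation is well behaved: scatter channels stay linear,
fluorescence channels are mapped through `asinh(x / cofactor)` with a
common cofactor (default 150, the conventional order of magnitude for
instrument-processed fluorescence). Threshold gating only requires a
monotone axis, so the particular monotone scale cannot change which events
fall on which side of a density trough between two well-separated modes;
the arcsinh choice matters only for the numerical stability of the kernel
density estimate. Two-dimensional hand-drawn polygons are deliberately not
modeled: a manual-analysis figure does not define reproducible polygon
coordinates, while 1D troughs are fully determined by the data.

The hierarchy is:

1. **Debris exclusion** — events above the FSC density trough
   (debris sits near the scatter origin).
2. **CD45+ leukocytes** — above the CD45 trough within the debris-free
   population.
3. **CD34+ cells** — above the CD34 trough within CD45+; CD34+ cells are
   a small minority, so an absent positive mode falls back to the 99.9th
   percentile of the parent (yielding a near-zero, flagged gate rather
   than a fabricated population).
4. **CD38 split** — the CD34+ gate is partitioned at the CD38 trough;
   the CD38− side is the stem (LSC) compartment, the CD38+ side the
   progenitor compartment.
5. **CD26 calibration** — the positivity cutoff is *not* taken from the
   LSC events themselves (there may be almost none). Instead the sample's
   own CD3+ T lymphocytes serve as an internal control: CD26 expression on
   T cells is reliably bimodal, and the trough between their CD26− and
   CD26+ modes defines the sample-specific cutoff. Lymphocytes are
   pre-gated CD45-bright/SSC-low within the debris-free population, then
   the CD3+ subset is taken above the CD3 trough. The CD45-bright/SSC-low
   reading of the lymphocyte pre-gate is the conventional one; it is an
   interpretation, flagged as such in the design, since manual protocols
   rarely spell it out.
6. **CD26 classification** — LSC events above the calibrated cutoff are
   the CD26+ LSCs.

### Trough estimation

`density_trough()` fits a Gaussian-kernel density estimate with
Silverman's rule-of-thumb bandwidth on a 512-point grid spanning the
0.1–99.9 percentile range of the data (the trimmed range keeps isolated
extreme events from stretching the grid). Candidate modes are local maxima
of the fitted density, including grid edges, so a mode clipped by the
percentile trim is still seen.

Two numerical decisions matter in practice:

* **Mode significance.** A second "mode" is accepted only if the density
  between it and the main mode dips below 0.75 of the second peak's own
  height. Finite-sample KDE wiggles riding on the flank of a dominant
  mode have shallow valleys (ratio above ~0.9) and are rejected, while
  genuine expression modes have deep valleys (an equal-weight mixture of
  unit normals 3 SD apart has ratio ≈ 0.64, and real marker modes are
  separated much further). Without this screen, a noise wiggle on a
  dominant progenitor mode can masquerade as the second mode and the
  "trough" lands inside a single population.
* **Tie-breaking.** If several grid points attain the minimum density
  between the chosen modes — common when the inter-mode region is
  essentially empty — the lowest-intensity point is used. This is the
  conservative direction: marginal events are consistently *not* called
  positive.

Degenerate shapes fall back to a per-gate quantile with a warning flag:
1st percentile for the debris and CD45 gates (nearly everything retained),
99.9th percentile for the rare-positive CD34 gate and for the CD26
calibration (the upper tail of a negative control bounds negativity),
median for the CD38 split. Gates are never silently dropped; every
fallback is recorded in the report's flags.

A genuinely unbalanced mixture deserves a note: a 5%-weight component
placed 3 SD from a 95% component does not produce a second density mode at
all — the mixture is analytically unimodal — so no trough-based method can
separate it. The populations this pipeline must separate (debris vs.
cells, CD26− vs. CD26+ T cells, CD38+ vs. CD38− CD34+ cells) sit 5 SD or
more apart on their deciding axes, where the trough is well defined.

### Quantification

Three headline quantities per sample:

* `pct_cd26_of_cd45` — CD26+ LSC events as a percentage of CD45+ events
  (the denominator is CD45+ events, not all acquired events);
* `pct_cd26_of_lsc` — CD26+ share of the CD34+/CD38− compartment;
* `abs_cd26_per_ul` — `WBC/µL × pct_cd26_of_cd45 / 100`, the absolute
  CD26+ LSC concentration.

A failed gate yields an *undefined* (`NA`, flagged) quantity, never a
silent zero: a sample whose CD26 calibration failed must not be reported
as CD26-negative. Percentages are carried at full precision and rendered
to three significant figures, since values down to 0.001% are meaningful.

## Statistics

The cohort layer reports median/range summaries and four rank-based
procedures: Mann–Whitney U (absolute counts and percentages between WBC
strata, boundary 150×10³/µL inclusive on the low side), Kruskal–Wallis
across Sokal risk groups, Wilcoxon signed-rank for the paired
diagnosis/follow-up comparison, and Spearman correlation of the absolute
count with WBC. Conventions follow mainstream clinical software: midranks
for ties, the standard tie-correction terms, no continuity correction,
two-sided p-values, and per-group mean ranks reported alongside the
statistic. For small samples the reported p-value is the exact permutation
p (rank-sum and signed-rank distributions by dynamic programming over
doubled midranks; Kruskal–Wallis by full enumeration when at most 10⁵
assignments exist); the asymptotic Z or χ² is always reported as well.
Quartiles use linear interpolation between order statistics — a single
declared convention keeps the IQR testable. Paired tests use only
complete chronic-phase diagnosis/follow-up pairs: blast-crisis patients
do not enter the follow-up comparison, and the paired n is the number of
pairs, never the row count.

## The synthetic-data generator

No patient data ship with the package; every test runs against a seeded
generator whose ground truth is known per event. A simulated acquisition
is a mixture of nine populations (debris; CD3+CD26+, CD3+CD26− and other
lymphocytes; granulocytes; monocytes; CD34+CD38+ progenitors; CD26− and
CD26+ CD34+CD38− stem cells) with independent per-marker normal
distributions on the gating scale, mapped back to raw intensities through
the inverse arcsinh (scatter clamped at zero; fluorescence keeps its
negative tail, as compensated data do — clamping would pile dim events
into a zero spike and fabricate a density mode).

The template geometry encodes the population structure the gating strategy
assumes: debris far below cells on FSC; one broad CD45+ leukocyte mode
(CD34+ cells dim at 4.0 arcsinh units, granulocytes 4.3, monocytes 4.5,
lymphocytes 4.7 — spacing them further apart lets the KDE resolve them as
separate modes and breaks any threshold-on-CD45 strategy, which is also
why real CD45 gating is usually drawn against SSC); T-cell CD26 modes 6.6
pooled SD apart; CD38 modes 6 SD apart; and CD26+ LSCs sharing the
lymphocyte CD26+ mode location, which is exactly the assumption behind the
internal-control cutoff. Default mixture weights are realistic for CML
blood (12% debris, ~10% lymphocytes of which ~60% CD3+, 4% monocytes,
granulocyte-dominated remainder); the CD34+ fractions are solved from the
two CD26 targets so that the *expected* %CD26-of-CD45 and %CD26-of-LSC
equal the requested values exactly.

Cohort simulation defaults to a realistic single-center layout: 43 diagnosis samples with WBC
log-uniform over 42.6–828.3×10³/µL and %CD26-of-CD45 log-uniform over
0.001–1.77 (log-uniform because reported medians sit far below range
midpoints, indicating strong right-skew), 10 controls without a CD26+
stem population, and 28 chronic-phase follow-up pairs with %CD26
log-uniform over 0.001–0.2, never above the diagnosis value by default,
and WBC redrawn in the normal 4–11×10³/µL range. Sokal risk is drawn with
realistic 4/31/8 proportions. When a CD26 target implies fewer
than 5 expected CD26+ LSC events, the generator pins the exact count by
relabeling randomly chosen granulocyte events (hypergeometric-style),
so detection tests at the 0.001% regime are deterministic. All randomness
flows from one master seed through a per-sample seed stream.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: doublets, time drift, fluorescence
spillover and compensation artifacts, heavy-tailed or skewed expression
distributions, inter-instrument scale differences, and accelerated-phase
biology. The generator validates the *algorithmic* contract (the gates
find the troughs the data contain; the quantities are computed correctly;
the statistics behave), not instrument physics.

## Problem sizes and determinism

End-to-end checks run at the full acquisition size, 100,000 events per
sample: 10 simulated controls (expected: zero CD26-positive calls), 43
simulated diagnosis samples with at least 5 pinned CD26+ LSC events each
(expected: all detected), and a parameter-recovery sweep at targets 0.01,
0.1 and 1.0 %CD26-of-CD45 with 100 seeds per target, requiring the
pipeline estimate within 3 binomial standard errors of the realized
ground-truth percentage in at least 95% of seeds. Unit tests use 20,000-
to 50,000-event acquisitions where the full size adds nothing. Given a seed
and a configuration, every output — event matrices, gating reports,
cohort analyses — is bit-identical across runs; report serializations are
compared byte-for-byte in the tests.

## Known limitations

* All gates are 1D thresholds; samples whose populations separate only in
  a 2D projection (e.g. CD45 vs. SSC blast gating in heavily infiltrated
  marrow) are out of scope.
* The CD26 cutoff assumes the sample contains enough CD3+ lymphocytes
  (default: at least 50); lymphopenic samples yield a calibration error
  and are reported not-evaluable rather than negative.
* FCS support covers list-mode 3.0/3.1 with float or integer data, which
  is what current cytometers emit; FCS 2.0 and log-amplified integer
  reconstruction are not implemented.
* Asymptotic p-values are used for samples beyond the exact-computation
  limits; at cohort sizes of 28–43 the approximation error is negligible,
  but borderline p-values near 0.05 at such sizes should be read with the
  usual caution.
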