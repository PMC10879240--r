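---
title: "raftscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{raftscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftscape)
```

raftscape analyses lipid-raft composition profiles from human spinal
cord, contrasting ALS cases with controls without neuropathology (NSL).
Because the underlying per-subject measurements are not publicly
deposited, the package pairs the analysis pipeline with a synthetic
cohort generator whose defaults encode the published group contrasts.
This vignette explains each model, its assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Lipid profiles and derived indexes

A cohort is a data frame with one row per subject: metadata
(`subject_id`, `group`, `sex`, `age`, `pmd`), a fatty-acid table in
mol% of total fatty acids (including dimethylacetals, DMAs — the
transmethylation derivatives of plasmalogen vinyl-ether chains), and a
lipid-class table in % of total lipid. Both tables are compositional:
each should close to 100. Densitometry and GC tables rarely close
exactly, so closure is enforced with a warning band of ±1 and a hard
error beyond ±5.

Derived indexes follow the standard membrane-lipidomics definitions:

* **Unsaturation index** UIx = Σ mol% × double bonds, DMAs excluded.
* **Peroxidability index** PIx = 0.025·monoenes + 1·dienes + 2·trienes
  + 4·tetraenes + 6·pentaenes + 8·hexaenes, DMAs excluded. The steep
  weights reflect the growth of peroxidation susceptibility with the
  number of bis-allylic positions.
* **Sat/Unsat** = saturates / unsaturates with DMAs excluded from both
  sides. DMAs proxy plasmalogen ether chains and are analysed as their
  own total rather than inside the saturate/unsaturate split; whether
  published totals include them in "unsaturates" is not stated
  anywhere we could anchor to, so the exclusion is documented here as
  this package's convention, not asserted as anyone else's.
* **CHO/SE** = free cholesterol over cholesteryl esters, an indicator
  of cholesterol esterification (ACAT1) activity.
* **Anionic/zwitterionic** = (PG + PI + PS)/(PC + PE). Sphingomyelin is
  zwitterionic too but is counted with the sphingolipid total, because
  the phospholipid-charge contrast of interest is between the
  glycerophospholipid pools.
* **LCPUFA** = species with ≥ 20 carbons and ≥ 2 double bonds.

UIx and PIx are linear in the profile and all ratios are invariant
under renormalization — both properties are tested.

## The synthetic cohort generator

The generator draws each group from a logistic-normal model: a latent
Gaussian vector with mean `log(mean_profile)` (shifted so the lognormal
mean is exact), per-token log-scale dispersion `sqrt(log(1 + cv^2))`,
and a planned correlation structure; draws are exponentiated and each
table renormalized to 100. A logistic-normal rather than a Dirichlet is
used because arbitrary pairwise correlation signs must be plantable,
which the Dirichlet cannot do.

**Means.** The NSL baseline is an editorial, physiologically plausible
spinal-cord raft composition (myelin-influenced: high cholesterol,
sulfatides and plasmalogen DMAs, DHA-rich phospholipids); it is *not*
measured data. The ALS means are the NSL baseline multiplied by the
published percent changes (SE ×3.23, sulfatides ×0.821, PE ×0.871,
PG ×1.692, PI ×1.225, PS ×1.1746, arachidonic acid ×1.165,
20:3n-6 ×1.688, 16:1n-9 ×1.856, DHA ×0.935, and editorial monoene
rises for 18:1n-9, 16:1n-7, 20:1n-7). 18:0 (fatty-acid table) and CHO
(class table) absorb the residuals so the ALS mean tables still close
to 100; both balancing moves run in the reported direction (lower
saturates, lower free cholesterol in ALS). Default group sizes mirror
the study (6 NSL, 4 ALS); statistical recovery work should raise them.

**Dispersion.** Per-token coefficients of variation are tiered:
disease-reactive species (PE, PS, SE, PI, PG, sulfatides, the LCPUFAs,
the reactive monoenes, the DMAs) use cv = 0.15; cholesterol and PC use
0.06; the structural bulk species (16:0, 18:0, 18:1n-9, SM, ...) use
0.05. Biologically, bulk structural lipids are homeostatically
constrained while minor reactive pools vary more between subjects.
Numerically, the tiering also keeps closure noise — the spurious
variation each token inherits from dividing by its table's sum —
small relative to the planted signal, which is what makes strong
observed-scale correlations reachable at all (next paragraph).

**Correlations.** Correlation targets are stated on the observed
(closed) scale, because that is where the reported values live
(e.g. PE–arachidonate r = +0.72 in NSL but −0.94 in ALS; PS–DHA −0.97
in ALS). Two mechanisms separate the observed from the latent scale:
closure attenuates and distorts strong correlations, and a raw
pairwise target list is generally not positive semi-definite, so the
nearest-PSD repair (Matrix::nearPD) moves entries. The package handles
both explicitly:

1. The ALS plan's latent starting values are derived from a two-factor
   loading construction whose leading factor is the remodelling axis
   ({PS, PE, DMAs} against {arachidonate, DHA}); this makes the latent
   matrix consistent by construction, so the PSD repair is nearly a
   no-op.
2. `calibrate_correlation_plan()` closes the observed-scale loop: it
   simulates the group at n = 4000, measures the observed correlation
   of each anchored pair, nudges the latent targets by the residual,
   and iterates (8 rounds, step 0.8, drift bounded at ±0.45). Only
   anchored pairs are calibrated; completion pairs stay latent.

With the default configuration the anchored strong pairs are recovered
within ±0.05 at n = 500 per group. Weak targets (|r| ≤ 0.4) cannot be
pinned that tightly by any generator at n = 500 — the sampling standard
error of a correlation near 0.3 is ≈ 0.04 — so tests hold them to a
sampling-aware band instead.

**Anisotropy.** `generate_anisotropy()` synthesizes TMA-DPH
steady-state anisotropy readings through the forward viscosity model
(below) plus Gaussian noise truncated to the physical range `[0, r0)`.

Determinism: one seed fixes the cohort byte-for-byte; calibration uses
its own fixed internal seed so configs are reproducible objects.

## Perrin-based microviscosity

Steady-state anisotropy r of a membrane-anchored probe maps to an
apparent microviscosity via the classic hyperbolic Perrin form

η = C · r / (r0 − r),

with limiting anisotropy r0 = 0.362 and calibration constant
C = 2.4 poise by default (the standard DPH-probe conventions; both are
arguments). The inverse r = r0·η/(C + η) is exact, and the pair is
tested to round-trip at machine precision. Composition predicts η
through a linear model whose default predictors are Sat/Unsat, total
n-6 LCPUFA and %18:1n-9 — the variables whose changes the fluidity
shift tracks. The default slopes (+2.0, −0.03, −0.02 poise per unit)
encode the qualitative physics (saturate packing thickens, PUFA and
oleic acid fluidize); the intercept is solved so that, at the
configured group mean compositions, the contrast equals the target
+14.8% fluidity increase in ALS. Fluidity is defined as 1/η, and the
group contrast is 100·(mean(1/η_ALS)/mean(1/η_NSL) − 1), so a
viscosity drop reports as a fluidity rise; the contrast is invariant
to the calibration constant. The original regression coefficients
behind the study's absolute η estimates are not published in a form we
could anchor to, so the module makes no claim to reproduce absolute
viscosities — it ships fit/predict machinery validated by parameter
recovery against its own forward model.

## Statistical battery

* **Mann–Whitney U**, two-sided. Tie-free samples with n1 + n2 ≤ 12 use
  the exact null distribution; otherwise a normal approximation with
  tie and continuity corrections. The exact branch is verified against
  a full enumeration oracle over every split of a fixed value grid.
* **Cohen's d** uses the pooled-variance denominator and the sign
  convention NSL − ALS, so a decrease in ALS plots positive —
  matching the forest-plot orientation in which reduced saturates and
  sulfatides appear on the positive side. The 95% CI uses the
  normal-approximation SE sqrt((n1+n2)/(n1·n2) + d²/(2(n1+n2)));
  with groups of 4–6 subjects a noncentral-t CI would suggest more
  precision than the data support, and the approximation's coverage is
  exercised in the recovery tests at n = 200.
* **Forest tables** report d, CI, U, p and percent change per token,
  flagging |d| > 0.8 as a large effect. No multiplicity correction is
  applied by default (raw Mann–Whitney p-values are reported);
  `adjust_forest_fdr()` offers Benjamini–Hochberg.
* **PCA lipid signatures** are computed on the correlation matrix
  (lipid variables span 0.1–40%, so covariance PCA would be dominated
  by the big classes), with varimax rotation of the two retained
  components — the conventional rotation where none is named — and
  regression-method factor scores. Closed compositional tables make
  the correlation matrix exactly singular, so the score weights use
  the Moore–Penrose pseudoinverse. Scores feed a one-way ANOVA per
  component. The component count is an argument, since a Kaiser or
  scree rule was not stated.
* **Correlation heatmaps** give per-group Pearson r and R² = r² per
  (class, fatty-acid) pair. The between-group difference is expressed
  as Cohen's q = |z(r1) − z(r2)| on the Fisher scale; the original
  figure labels such differences "Cohen's f" without defining the
  statistic for correlation pairs, so q is this package's documented
  interpretation.
* **Slope heterogeneity** (the CHO→SE analysis) comes from the
  group × x interaction F of the pooled two-slope model with 1 and
  n − 4 degrees of freedom — the ANCOVA homogeneity-of-slopes test —
  alongside per-group OLS slopes.

## The agent-based membrane model

A periodic L × L lattice (default 64) carries one lipid agent per
site, from seven groups: CHO, SE, DHA, n-6 LCPUFA, MUFA, SFA, SL.
`composition_from_profiles()` maps a cohort's class and fatty-acid
tables onto these fractions (CHO, SE and the sphingolipid total from
the class table; the four acyl groups scaled into the
glycerophospholipid share), and initialization uses largest-remainder
rounding of fraction × L² followed by a seeded shuffle, so counts are
exact and deterministic.

Dynamics are conservative Kawasaki exchanges: per sweep, L² attempts
pick a random site and a random 4-neighbour and swap them with
Metropolis probability min(1, exp(−ΔE/T)), ΔE from nearest-neighbour
pair energies. Composition is conserved exactly — the model's input is
the measured composition, so dynamics must not change it. The default
interaction matrix encodes established raft physics in units of T:
J(CHO,SL) = J(SL,SL) = J(CHO,SFA) = −1 (the
cholesterol–sphingolipid–saturate condensation that makes rafts),
J(CHO,DHA) = J(CHO,N6LCPUFA) = +0.8 (sterol aversion to
polyunsaturated chains), J(SE,·) = +0.4 (sterol esters as packing
disruptors), all else 0, T = 1. Every entry is configuration-exposed;
no claim is made to reproduce any previously published
parameterization. Acceptance rates are recorded overall and per lipid
group (not additionally per raft membership: raft labels are a
detection output, and conditioning the recorded dynamics on them would
couple the detector into the physics).

**Raft detection.** A site's local order is the fraction of
raft-forming lipids (CHO, SFA, SL) in its 9-site Moore neighbourhood,
centre included; sites at or above `raft_theta` are raft sites, and
rafts are 4-connected components of at least `raft_min_size = 5`
sites. The default threshold is 7/9 (at least 7 of 9 neighbours
raft-forming). This was a genuinely open choice and the one place the
obvious default failed: with realistic spinal-cord raft compositions
the raft-forming groups occupy ~72% (NSL) and ~64% (ALS) of the
membrane, so any threshold at or below ~2/3 leaves the detector in a
percolating regime — one system-spanning cluster, degenerate counts,
and a mean raft size that flips between paired runs whenever the
spanning cluster splits. At 7/9 the control membrane resolves into a
handful of large rafts and the ALS membrane into many small ones, and
the group orderings are stable. The detector is verified exactly
(label-for-label) against an independent shift-sum + flood-fill
reference implementation, and its J = 0 area fraction against a
Monte-Carlo oracle over random lattices.

**Mobility.** All agents are tagged; each is classified by raft
membership at the start of a measurement window (≥ 10 sweeps) and its
periodically-unwrapped squared displacement is accumulated; mobility
is the mean squared displacement per sweep, reported separately for
raft and non-raft populations. Whether the original model was lattice
or continuum, and its exact mobility metric, are unknown to us; MSD
per sweep is the documented stand-in. With the default compositions the
ALS membrane shows smaller rafts, a lower raft area fraction and higher
raft mobility than NSL, with non-raft mobility changing far less — the
qualitative prediction pattern this module exists to reproduce.

`simulate_group()` expands one master seed into per-replicate streams
by drawing sub-seeds from the master-seeded RNG, so replicated runs
are exactly reproducible.

## Problem sizes and numerical choices

Recovery analyses run at n = 200/group (mean shifts, forest flags,
fluidity contrast) and n = 500/group (correlations), where sampling
error is small against the planted effects; membrane simulations use
L = 64 with 2000 burn-in sweeps and a 100-sweep mobility window, with
smaller lattices for unit-level property checks. Degenerate inputs are
handled as flags rather than surprises: zero denominators yield NaN
with the ratio marked undefined, zero pooled variance flags the effect
as undefined, constant variables are dropped from PCA with a warning,
and collinear viscosity predictors are rejected with the offending
pair named (condition-number threshold 1e8 on the scaled design).

## What passing tests do and do not show

The generator emulates group mean shifts, dispersion tiers and
group-specific correlation structure under compositional closure. It
does not emulate instrument noise models, chromatographic artefacts,
subject covariate structure (age, post-mortem delay) beyond decorative
metadata, or any dependence between the fatty-acid and class tables
other than the planted cross-table correlations. Passing recovery
tests therefore demonstrates that the pipeline's statistics faithfully
measure what the generator plants at realistic scales — not that the
original biological measurements would reproduce, which cannot be
established without the unpublished data. Similarly, the membrane
model's parameters were chosen to encode textbook raft physics, not
fitted to data; its predictions are qualitative orderings, and the
absolute raft sizes and mobilities have lattice units with no direct
experimental calibration.
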