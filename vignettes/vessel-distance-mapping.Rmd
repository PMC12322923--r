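---
title: "Vessel distance mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel distance mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdmap)
```

## The problem

The primary motor cortex is supplied by up to five arteries per hemisphere:
two branches of the anterior cerebral artery (A. pericallosa,
A. callosomarginalis) and three groups of the middle cerebral artery
(precentral, central, postcentral). Which of these vessels are present, and
how much of the cortex each one supplies, varies considerably between
hemispheres. Vessel distance mapping (VDM) turns a manually delineated
artery segmentation plus a gray-matter mask into a quantitative description
of that variability without any perfusion measurement: the assumption is
that proximity to a vessel is a reasonable proxy for being supplied by it.

`vdmap` implements the full analysis chain: exact per-artery Euclidean
distance maps, winner-takes-all parcellation of the cortical ROI into
supply territories, supply volume fractions, vessel-pattern and
vessel-dominance classification with threshold sweeps, majority-vote fusion
of co-registered parcellations into pattern-specific atlases, and the
statistical assessment of vascular configuration against mean cortical
thickness. Because subject imaging data of this kind generally cannot be
shared, the package also ships a synthetic phantom generator with analytic
ground truth, so that every stage is testable end to end.

## The core model

For artery $v$ with segmented voxel set $S_v$, the distance map is

$$ d_v(x) \;=\; \min_{y \in S_v} \lVert x - y \rVert_2 \quad [\mathrm{mm}], $$

evaluated at every voxel centre $x$, with physical spacing honoured per
axis. The supply territory of $v$ within the ROI $\Omega$ is the
winner-takes-all (Voronoi-like) region

$$ T_v \;=\; \{\, x \in \Omega : d_v(x) < d_w(x) \;\; \forall w \ne v \,\}, $$

and the supply volume fraction is $f_v = |T_v| / |\Omega|$ in voxel counts.
Arteries that are absent (no labelled voxels) are skipped and get
$f_v = 0$ exactly. From the fractions follow:

* the **vessel pattern**: the set and count (1–5) of vessels with
  $f_v > 0$;
* the four **dominance ratios**, each of the form
  $f_{\text{interest}} / (f_{\text{interest}} + f_{\text{counterpart}})$:
  ACA vs. total, pericallosa vs. ACA, central vs. central+precentral,
  postcentral vs. MCA. A ratio is 1 when the vessel of interest is the sole
  supplier of its pool, 0.5 at equal contribution, 0 when absent, and
  undefined (`NA`) when the denominator pool is empty;
* the categorical **dominance rating** under a lower/upper threshold pair:
  within `[lower, upper]` is equal contribution, outside is single-vessel
  dominance. The equidistant defaults are (0.33, 0.66).

## Numerical choices

**Distance transform.** Distances are computed with a separable exact
Euclidean distance transform (Felzenszwalb–Huttenlocher lower-envelope
algorithm, implemented in C++), with samples placed at physical voxel
centre positions so anisotropic spacings are exact, not approximated. The
test suite verifies equality with a brute-force minimum-pairwise-distance
oracle to 1e-9 mm on grids up to 16³ (observed agreement is at machine
precision).

**Tie-breaking.** At voxels exactly equidistant from two vessels the
smallest label id wins, everywhere in the package (parcellation, vessel
overlap, majority voting). The canonical id order is pericallosa (1),
callosomarginalis (2), precentral (3), central (4), postcentral (5). Ties
are a measure-zero event for generic geometry but must be deterministic for
reproducible fractions. Note that at a true tie two floating-point
algorithms may disagree about which distance is "smaller" by one ulp; the
oracle tests therefore demand identity only where the distance gap exceeds
1e-9 mm and near-minimal membership at ties.

**Fractions** are voxel-count ratios, not mm³ — equivalent on uniform
grids, and the nonzero test for pattern counting is exact (`> 0`, no
epsilon) because counts are integers.

**Thresholds.** Boundary ratios equal to a threshold count as equal
contribution (closed interval); this keeps the equidistant pair symmetric.
The sweep grid is `n` lower thresholds equally spaced on [0.05, 0.45] with
`upper = 1 - lower` (defaults give 100 pairs from (0.05, 0.95) to
(0.45, 0.55)). The agreement score between a rating frequency vector $f$
and a reference $g$ is $1 - \tfrac12\sum_c |f_c - g_c|$ (one minus the
total variation distance) — the simplest metric that is 1 at
self-agreement and decreases linearly in the mass that changes category.
The scorer is isolated inside `sweep_agreement()`, so another metric could
be substituted without touching the rating machinery. Undefined ratios are
excluded from the frequencies and reported as a separate count: real
hemispheres always have at least one ACA branch, but phantoms need not.

**NIfTI geometry.** NIfTI-1 headers store spacing and origin in single
precision. The reader snaps both to 6 significant digits, so that common
millimetre geometries (0.45, 0.9, ...) round-trip exactly through a
write/read cycle.

## The phantom generator

No geometric model of the vessels exists in the source data (they are
manual voxel delineations), so the phantom geometry is a free design
choice:

* **Cortex**: a 120° section of a cylindrical shell (default inner radius
  0.38 × grid extent, thickness 2.5 mm), a curved gray-matter-like ribbon.
* **Vessels**: five polyline curves running longitudinally 2 mm outside
  the shell, spread across the angular extent in canonical order, with a
  small fixed sinusoidal wobble (amplitude 0.015 rad) so the geometry is
  not axis-aligned degenerate. Marking vessels absent produces 3–5-vessel
  patterns whose wedges are absorbed by the angular neighbours — the same
  qualitative behaviour reported for real hemispheres, where a missing ACA
  branch's territory is taken over by its counterpart.
* **Rasterisation**: a voxel carries a vessel's label when its centre lies
  within one voxel spacing of the curve, emulating voxelised manual
  centreline delineations; overlaps resolve to the smallest id.
* **Ground truth**: each ROI voxel centre is assigned the present vessel
  with the smallest *continuous* point-to-polyline distance — independent
  of the voxel-grid distance transform — giving analytic expected
  fractions. The voxel-level pipeline converges to these as spacing
  shrinks; at 0.45 mm on a 64³ grid the per-vessel deviation stays below
  0.05 (observed ≈ 0.002).

The default grid is 64³ at 0.45 mm isotropic (≈ 29 mm extent), the
resolution of the motivating acquisitions. The geometry needs a physical
extent of roughly 25 mm or more for all five default vessels to fit inside
the grid; smaller grids should use coarser spacing.

What the phantoms do **not** emulate: true cortical folding, vessel
tortuosity and branching, partial-volume effects, delineation noise, and
registration error. Passing tests therefore demonstrate the correctness of
the computations, not the anatomical validity of VDM as a supply proxy.

```{r phantom}
ph <- generate_phantom(default_phantom_config(n = 48, spacing = 0.6))
parc <- parcellate(ph$volume, ph$roi)
fr <- supply_fractions(parc, ph$roi)
round(rbind(vdm = as.numeric(fr),
            truth = as.numeric(ph$truth$fractions)), 3)
classify_pattern(fr)
dominance_ratios(fr)
```

## Synthetic cohorts

`cohort_config()` fixes the study conditions for cohort-level tests: by
default 38 hemispheres with pattern mix {3-vessel: 10, 4-vessel: 19,
5-vessel: 9}. Three-vessel hemispheres get one ACA branch plus the
precentral and central groups; four-vessel ones get both ACA branches plus
precentral and central (the dominant variant in real cohorts); five-vessel
ones get all arteries. Mean thickness follows

$$ t_i = 2.75 - 0.09\,[\mathrm{male}_i] - 0.005\,\mathrm{age}_i
   + \varepsilon_i,\quad \varepsilon_i \sim N(0, 0.055^2)\ \mathrm{mm}, $$

with ages uniform on [22, 45] years. These defaults were chosen once to
match the scale of published healthy-cohort values (group means around
2.51–2.57 mm, a strong sex difference of d ≈ 1.6, a weak negative age
trend) and are not tuned further. Gaussian noise is the standard choice
for testing OLS recovery.

## Statistics

The covariate tests follow a conventional operationalisation of
"normality, homoscedasticity, number of groups": Shapiro–Wilk per group at
α = 0.05, median-centred Levene at α = 0.05; all-normal + homoscedastic
gives the pooled t-test / one-way ANOVA, normal + heteroscedastic the
Welch variants, any non-normal group the Kruskal–Wallis H-test, and the
paired t-test for paired two-group designs.

The thickness models are OLS fits `thickness ~ age + sex (+ vasculature)`
with treatment coding (references: female; 3-vessel pattern; equal
contribution) and HC3 heteroscedasticity-consistent standard errors with
t-based p-values — the standard HC3 practice, not a bootstrap. The full
and reduced models are compared with the classic partial F-test on
residual sums of squares; no multiple-testing correction is applied across
the three vascular models, matching the raw-p-value reporting convention
of this literature. Covariate-adjusted thickness values are the reduced
model's intercept plus its residuals, preserving the baseline level and
the residual variance.

Hemispheres are treated as independent observations (two per subject).
This mirrors the hemisphere-wise analysis the method was designed for, but
ignores within-subject correlation; a mixed model would be the natural
extension and is deliberately out of scope.

```{r stats}
tab <- simulate_cohort_table(cohort_config(seed = 42))
full <- fit_thickness_model(tab, vascular = "pattern")
reduced <- fit_thickness_model(tab)
compare_models(full, reduced)
```

## Atlas fusion

Registration to a common space is out of scope (it is the job of
established registration toolchains); the atlas module consumes volumes
already on one grid. Right hemispheres are mirrored along the first axis
onto the left-hemisphere convention (`flip_lr()`, an involution that
preserves label histograms). `majority_vote()` assigns each voxel the most
frequent non-zero label; background never outvotes a present label, so a
voxel labelled by a single hemisphere is still labelled in the atlas, and
vote ties resolve to the smallest id. ROI masks are fused by a simple
≥ 50% vote (exact halves included) rather than intensity-weighted joint
fusion, which would require the MR images themselves. Atlases are intended
to be built per vessel pattern, one atlas per composition.

## Problem sizes and limitations

The shipped tests use grids up to 64³ and cohorts of 38 hemispheres
(plus 1000-replicate null simulations for the type-I-error calibration of
the model comparison); these sizes keep the full suite in the order of a
minute while exercising every code path at the study's native resolution.

Known limitations: Euclidean (not geodesic, vessel-tree-following)
distances; no perfusion ground truth — territories are proximity proxies;
no partial-volume handling (fractions are voxel counts); no registration,
bias-field correction or template handling; phantoms are geometrically
idealised as described above.
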