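# vdmap — vessel distance mapping and arterial supply territories

`vdmap` quantifies which arteries supply a cortical region, and how much
each contributes, from a labeled vessel segmentation and a gray-matter
mask — the kind of data produced by manual artery delineation on
high-resolution (7 T) structural MRI. It targets researchers studying
inter-individual variability of the motor cortex vasculature (vessel
patterns, vessel dominance, pattern-specific territory atlases) and its
possible relation to cortical structure.

## The method

For each artery *v* with segmented voxel set *S<sub>v</sub>*, the vessel
distance map is

&nbsp;&nbsp;&nbsp;&nbsp;d<sub>v</sub>(x) = min<sub>y ∈ S<sub>v</sub></sub> ‖x − y‖₂ (mm),

computed exactly for every voxel centre with anisotropic spacing honoured.
Each ROI voxel is assigned to its nearest artery ("winner takes all"),
giving supply territories T<sub>v</sub> and supply volume fractions
f<sub>v</sub> = |T<sub>v</sub>|/|Ω|. From the fractions the package
derives:

- **vessel patterns** — the set and count (up to five: A. pericallosa,
  A. callosomarginalis, MCA precentral/central/postcentral group) of
  arteries with f<sub>v</sub> > 0;
- **vessel dominance (VDom)** — ratios
  f<sub>interest</sub>/(f<sub>interest</sub> + f<sub>counterpart</sub>)
  (1 = sole supplier, 0.5 = equal contribution, 0 = absent), categorised
  under a lower/upper threshold pair (equidistant default 0.33/0.66) with
  a systematic 100-pair threshold sweep and agreement scoring against
  reference frequency tables;
- **pattern-specific atlases** — majority-vote fusion of co-registered
  parcellations, with left-right flipping, mean distance atlases and ROI
  mask fusion;
- **thickness statistics** — data-driven test selection (t / Welch /
  ANOVA / Kruskal–Wallis), OLS models of mean cortical thickness with HC3
  robust errors, full-vs-reduced model F-comparison, and covariate-adjusted
  thickness values.

A synthetic phantom generator (curved cortical sheet + parametric vessel
curves with analytic ground-truth territories, plus cohort covariate
tables with known effects) makes the whole pipeline testable without any
subject data.

## Worked example

```r
library(vdmap)

# a synthetic hemisphere with four of the five arteries present
ph <- generate_phantom(default_phantom_config(
  c("pericallosa", "precentral", "central", "postcentral")))
parc <- parcellate(ph$volume, ph$roi)   # winner-takes-all territories
(fr <- supply_fractions(parc, ph$roi))
#> <supply_fractions>
#>   pericallosa        0.2973
#>   callosomarginalis  0.0000
#>   precentral         0.3075
#>   central            0.1999
#>   postcentral        0.1952
#>   ROI: 13816 voxels (1259.0 mm^3)
```

The pericallosal artery supplies ~30% of the ROI; the callosomarginal
artery is absent, so its fraction is exactly zero.

```r
classify_pattern(fr)
#> <vessel_pattern> 4 vessels: pericallosa + precentral + central + postcentral

dominance_ratios(fr)
#> <dominance_ratios>
#>                aca_mca peri_callosomarginalis     central_precentral
#>              0.2973364              1.0000000              0.3939524
#>        postcentral_mca
#>              0.2778121
```

A 4-vessel pattern; the pericallosa-to-ACA ratio is exactly 1 (sole ACA
supplier), and the central/precentral ratio 0.394 rates as equal
contribution under the equidistant thresholds
(`rate_dominance(0.394)` → `equal`).

```r
# a 38-hemisphere cohort: does the vessel pattern explain thickness?
tab <- simulate_cohort_table(cohort_config(seed = 42))
full <- fit_thickness_model(tab, vascular = "pattern")
full
#> <thickness_fit> thickness_mm ~ age + sex + pattern  (n = 38)
#>         term  estimate       se statistic   p.value
#>  (Intercept)  2.755000 0.040650   67.7900 5.215e-37
#>          age -0.005824 0.001204   -4.8370 2.981e-05
#>      sexmale -0.078280 0.022060   -3.5480 1.187e-03
#>     pattern4  0.024940 0.023400    1.0660 2.942e-01
#>     pattern5  0.022090 0.027100    0.8151 4.208e-01
#> adjusted R-squared: 0.4613   (HC3 robust standard errors)

compare_models(full, fit_thickness_model(tab))
#> <thickness_comparison> F(2, 33) = 0.679, p = 0.5139
#> adjusted R-squared: reduced 0.471, full 0.461
```

Sex and age effects are recovered (the generator injected −0.09 mm and
−0.005 mm/yr); the pattern term, which has no effect in the generator,
does not improve the model — as the F-comparison reports.

A thin command-line wrapper over the same functions is installed at
`inst/cli/vdm.R` (`compute`, `patterns`, `dominance` subcommands) for use
on NIfTI segmentations from a shell.

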