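# cctopo

Topography of the corpus callosum (CC) from probabilistic tractography
streamline counts, for longitudinal rodent neuroimaging studies.

Probabilistic tractography with a CC seed and cortical targets yields, per
scan and hemisphere, a matrix of streamline counts p(v, b, s) from each
midsagittal CC voxel v to each cortical area b. `cctopo` aggregates such
matrices into population connectivity maps, parcels the CC into
area-specific bilateral *passage fields*, quantifies left–right symmetry,
and models sex and age effects with linear mixed-effects regression — the
kind of analysis needed to track white-matter topography across the adult
lifespan in unbalanced longitudinal cohorts (different entry ages, 1–4 scans
per animal, dropout).

## The statistic at the core

Per scan, counts are row-normalized to connection probabilities

P(v, b, s) = p(v, b, s) / Σ_j p(v, b_j, s),

binarized at thresholds thr ∈ {0.100, 0.125, 0.150, 0.175, 0.200} (strict
`>`, evaluated exactly on integer counts), and averaged over the M
thresholds and S sample units into the population map

Ṗ(v, b) = (1/S)(1/M) Σ_s Σ_m 1[P(v, b, s) > thr_m] ∈ [0, 1].

Area b's passage field is the voxel set where the two hemispheres agree,
Ṗ_L · Ṗ_R > 0.05², with hole-free outer boundaries traced per 8-connected
component. Symmetry is the OLS slope/adjusted-R² of Ṗ_R on Ṗ_L voxelwise
(symmetric: slope within 1 ± 0.5, adjusted R² > 0.7). Field size and
streamline density are modelled as

outcome ~ sex + age + (1 | subject),

fitted by maximum likelihood (male reference, age in months), with
Benjamini–Hochberg FDR at α = 0.05 across the relevant family.

A seeded synthetic-cohort generator with known topographic, sex and age
structure (negative-binomial counts on log-linear area templates) provides
the ground truth that every pipeline stage is validated against.

## Worked example

Simulate the default 66-subject, 3-cohort longitudinal world and run the
stages:

```r
library(cctopo)

grid      <- cc_grid(60, 12, 0.18)
templates <- cc_area_templates(grid, cc_default_area_specs(grid))
dataset   <- cc_simulate_cohort(cc_cohort_design(seed = 42), grid, templates)
#> <cc_dataset> 66 subjects, 163 scans (x2 sides), 48 areas on 424 voxels

sides  <- vapply(dataset$scans, function(s) s$side, character(1))
scheme <- cc_threshold_scheme()
left   <- cc_population_average(lapply(dataset$scans[sides == "left"],
                                       cc_normalize), scheme, side = "left")
right  <- cc_population_average(lapply(dataset$scans[sides == "right"],
                                       cc_normalize), scheme, side = "right")

table(cc_classify_detectability(left, right)$class)
#> passage_field  undetectable
#>            13            35
```

13 of 48 cortical areas have detectable concentrated passage fields — the
13 the generator planted. Parcel and check symmetry for the orbital area:

```r
cc_combine_bilateral(left, right, "ORB", grid)
#> <cc_field> ORB: 60 voxels, 1 component(s), thr_sq=0.0025

cc_fit_symmetry(cc_paired_values(left, right, "ORB"), "ORB")
#> <cc_symfit> ORB: slope=0.992, intercept=0.0067, adj R2=0.998 (n=64)
```

The slope near 1 with adjusted R² near 1 reflects the generator's exact
left–right rate sharing (asymmetry 0). Longitudinal field-size model:

```r
sizes <- cc_per_scan_fields(dataset, "ORB")
sizes$age <- sizes$scan_age_months
cc_fit_lme(sizes, fixed = c("sex", "age"), outcome = "size_voxels")
#> <cc_lme> ML fit, 163 obs / 66 subjects, residual df=160
#>          term estimate      se      t          p
#> 1 (Intercept)   55.031 0.20636 266.68 7.815e-214
#> 2   sexfemale    3.049 0.18097  16.85  2.776e-37
#> 3         age   -0.139 0.01312 -10.60  3.304e-20
```

Both planted effects are recovered: females have larger ORB fields
(+3.0 voxels) and the field shrinks with age (−0.14 voxels/month).

## Command line

```sh
Rscript -e 'cctopo::cc_cli()' simulate --seed 7 --out sim/
Rscript -e 'cctopo::cc_cli()' run --counts sim/counts.tsv \
    --metadata sim/metadata.tsv --out results/ --seed 7
Rscript -e 'cctopo::cc_cli()' report --dir results/
```

Subcommands `aggregate`, `parcellate`, `symmetry` and `stats` run individual
stages. Outputs are TSV (maps, field sizes, symmetry and model tables),
JSON (boundaries, manifest with the fully resolved configuration), and
optional single-slice NIfTI-1 voxel maps.

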