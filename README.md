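# MorphoDev

Developmental trajectories and hemispheric asymmetry of regional brain
morphometry in early childhood.

## The problem

Cross-sectional pediatric MRI studies quantify how regional brain
structure matures by extracting, per child, regional gray-matter
volumes and cortical thickness (FreeSurfer-style aseg/aparc tables,
Desikan–Killiany parcellation), and then asking two questions:

1. **How does each region change with age?** Regional measures are
   normalized for head size — relative volume = volume / eTIV × 1000,
   relative thickness = thickness / hemisphere mean thickness — and
   modelled with a sex-adjusted generalized additive model,

   value = β₀ + β_sex·1[male] + s(age) + ε,

   where s(·) is a penalized regression spline. The smooth's effective
   degrees of freedom (edf) summarize trajectory shape (edf = 1 is
   linear, edf > 1 curved); candidate models {intercept, linear,
   smooth} are compared by BIC; p-values are Benjamini–Hochberg
   corrected within region families (8 cortical pairs for thickness,
   11 pairs for volume).

2. **When does lateralization emerge?** Per subject and region the
   asymmetry index AI = (L − R)/(L + R) is computed (positive =
   left-ward), subjects are binned into sliding 12-month age windows,
   each window's AI values are tested against zero with the Wilcoxon
   signed-rank test, q-values are BH-corrected across regions per
   window, and a region's *initial point* of lateralization is the
   midpoint of the earliest significant window.

MorphoDev implements this whole post-imaging pipeline as a tested R
package for researchers analyzing pediatric morphometry tables: a
SummarizedExperiment-backed cohort container (`MorphoCohort`), readers
for FreeSurfer-style stats files and long-format cohort tables,
population z-score QC, the normalizations and AI, mgcv-based
trajectory fits, the sliding-window emergence detector, demographics
with ANOVA + Fisher's LSD, and a synthetic cohort generator with known
ground truth so every stage can be validated without any imaging data.

## Worked example

```r
library(MorphoDev)

# a synthetic 57-child cohort, ages 14-71 months, with known ground truth
cohort <- simulateCohort(cohortConfig(seed = 7))
cohort
#> MorphoCohort: 57 subjects, 150 morphometric features
#>   age range (months): 14.5-70.8 | sex: 41 male / 16 female
#>   measures: thickness, volume | fronto-limbic features: 38
#>   provenance: synthetic cohort (seed 7)

# sex-adjusted developmental trajectories of eTIV-relative volume
traj <- fitAllRegions(cohort, measure = "volume")
head(traj[order(traj$q_value), c("region", "hemisphere", "edf", "f_stat",
                                 "p_value", "q_value", "selected_model")], 3)
#>                 region hemisphere      edf    f_stat      p_value      q_value selected_model
#> 20            thalamus      right 2.346582 15.911991 6.346996e-07 6.981695e-06         linear
#> 5  medialorbitofrontal       left 1.000007 18.174328 8.158056e-05 8.973862e-04         linear
#> 9             thalamus       left 1.753270  9.878861 1.714715e-04 9.430933e-04         linear

# sliding-window asymmetry emergence
ai  <- computeAsymmetry(cohort, measures = "volume")
s   <- subjectData(cohort)
win <- buildWindows(s$age_months, ids = s$subject_id, width = 12, stride = 1)
emergence <- detectEmergence(testWindows(ai, win, alpha = 0.05))
emergence[1:4, c("region", "asymmetry_direction", "initial_point_months")]
#>                    region asymmetry_direction initial_point_months
#> 1 caudalanteriorcingulate               right             25.49616
#> 2                fusiform                left             33.49616
#> 3        inferiorparietal               right             23.49616
#> 4    lateralorbitofrontal                <NA>                   NA
```

Reading the output: the thalamus volume grows with age (tiny q), with
edf near 1–2 (close to linear); the emergence table says, e.g., that
caudal-ACC volume is significantly right-lateralized from the window
centred at 25.5 months on, while lateral OFC never lateralizes
(`NA`) — matching that generator's planted ground truth
(`groundTruth(cohort)`).

The full pipeline (ingest → QC → normalize → trajectories → asymmetry
→ demographics, with every table written to disk) is one call:

```r
report <- runPipeline(pipelineConfig(generator = cohortConfig(seed = 7),
                                     seed = 7, outdir = "results/run1"))
```

A thin command-line wrapper lives at
`inst/scripts/morphodev-cli.R` (`simulate`, `run`, and single-stage
subcommands).

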