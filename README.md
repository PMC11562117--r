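# texd50

Voxel-wise T1-MRI texture mapping and D50 disease-progression modelling for
amyotrophic lateral sclerosis (ALS) cohorts.

ALS progresses at wildly different speeds between patients, so cross-sectional
imaging cohorts mix people at very different points of their individual
disease course. `texd50` implements the two ingredients of a
pseudo-longitudinal analysis of such cohorts, plus everything needed to test
them without patient data:

1. **The D50 progression model.** Each patient's ALSFRS-R functional score
   series (48 = full function) is fit with a sigmoidal decline

   `F(t) = 48 / (1 + exp((t − D50) / dx))`

   where `D50` is the number of months from symptom onset until half of motor
   function is lost (disease *aggressiveness*; LA if D50 > 30 months, HA if
   ≤ 30) and `dx` is the decline time constant. Normalising time so that the
   value 0.5 is reached at `t = D50` gives the relative D50,
   `rD50 = t / (2·D50)`, a measure of *disease accumulation* independent of
   aggressiveness, which stratifies patients into Phase I (rD50 < 0.25),
   Phase II (0.25 ≤ rD50 < 0.50) and Phases III/IV (rD50 ≥ 0.50).

2. **Voxel-wise GLCM autocorrelation texture maps.** For every voxel of a
   masked, co-registered T1 volume, a grey-level co-occurrence matrix (GLCM)
   is accumulated on each of the three orthogonal planes through the voxel
   (radius 1, distance 1, 8 grey levels from global min–max quantization, all
   four in-plane directions, symmetric), the Haralick autocorrelation
   `Σᵢ Σⱼ i·j·p(i,j)` is evaluated per plane, and the three-plane average is
   stored — no smoothing is applied to the map.

3. **Mass-univariate inference.** Subject texture maps are analysed voxel-wise
   with OLS general linear models — group contrasts (Phase I vs II, HA vs LA,
   bulbar vs spinal, patients vs controls) and continuous regressions on D50
   or rD50 — with sex, age, onset site and the congruent progression
   parameter as nuisance covariates. t-maps are thresholded one-sidedly at
   P < 0.0005 and connected components (18-connectivity by default) of at
   least 10 voxels are reported as clusters; both directions of every
   contrast are always evaluated.

4. **Synthetic data.** A seeded cohort generator reproduces the clinical
   marginal structure (log-normal D50 with median ≈ 30 months, Beta rD50 at
   scan, noisy sigmoid visit scores), and a seeded 3D phantom generator
   injects group differences in local spatial autocorrelation (Gaussian
   smoothing strength inside a spherical ROI), so every pipeline stage is
   testable end to end.

## Worked example

```r
library(texd50)

coh     <- simulate_cohort(n = 40, seed = 7)           # clinical tables
records <- fit_d50_cohort(coh$scores, coh$patients)    # one row per patient
dplyr::select(records, patient_id, d50, dx, rd50_at_mri, phase, aggressiveness)
#> # A tibble: 40 × 6
#>   patient_id   d50    dx rd50_at_mri phase aggressiveness
#>   <chr>      <dbl> <dbl>       <dbl> <fct> <fct>
#> 1 P001       130.  19.1        0.270 II    LA
#> 2 P002        16.0  4.71       0.278 II    HA
#> 3 P003        20.8  5.40       0.284 II    HA
#> 4 P004        26.5  5.16       0.202 I     HA
```

A single fit, its broom-style summary, and its plot:

```r
fit <- fit_d50(c(6, 12, 18, 24, 30), c(47, 44, 37, 27, 15))
fit
#> <d50_fit> D50 = 25.39 months, dx = 5.75, RSS = 1.139, n = 5
glance(fit)
#> # A tibble: 1 × 5
#>     d50    dx   rss n_obs converged
#> 1  25.4  5.75  1.14     5 TRUE
autoplot(fit)
```

This patient loses half their motor function an estimated 25.4 months after
symptom onset — a high-aggressiveness course.

Texture phantoms through the voxel-wise pipeline (here at a deliberately
lenient threshold so the small example shows a cluster):

```r
ph     <- simulate_phantoms(rep(c("HA", "LA"), each = 20),
                            shape = c(24, 24, 24), roi_n_voxels = 300,
                            fwhm_roi = c(HA = 2, LA = 0.5), seed = 8)
maps   <- lapply(ph$volumes, texture_map)              # radius 1, distance 1, Ng 8
design <- build_design(ph$subjects, "group_contrast")
tmap   <- fit_voxelwise_glm(maps, design)
tmap
#> <t_map> HA > LA (group_contrast), df = 38, 5616 voxels, max |t| = 4.64
threshold_clusters(tmap, p_threshold = 0.01, extent = 10)
#> # A tibble: 1 × 9
#>   cluster_id size_vox peak_t peak_i peak_j peak_k peak_x_mm peak_y_mm peak_z_mm
#> 1          1       22   4.33     15     14     16        14        13        15
```

The one surviving cluster (22 voxels, peak t = 4.33) sits at the centre of
the phantom's 300-voxel ROI, where the HA group's noise was smoothed more
strongly. `autoplot(tmap)` renders a t-map slice; `tidy(tmap)` gives the
per-voxel table.

Cohort report (Table-1 style, Shapiro–Wilk-gated):

```r
summarize_cohort(records)
#> # A tibble: 13 × 11   (variable, kind, …, label)
#>   age_at_mri  continuous_skewed  66.74 ± 17.63 (38.63–81.86)
#>   d50         continuous_skewed  36.86 ± 26.86 (14.49–500.00)
#>   sex M       categorical        22 (55.0%)
#>   …
```

`run_pipeline(config, out_dir)` chains all stages (cohort → D50 → texture →
GLM both directions → report) and writes a manifest with seeds and MD5
digests so any run is bit-reproducible.

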