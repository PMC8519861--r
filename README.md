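# hicfinder

Contrast-agent-free detection of cerebral hypoperfusion from resting-state
BOLD fMRI.

In acute ischemic stroke, the clinical reference for delayed tissue
perfusion is the T<sub>max</sub> map from gadolinium-bolus DSC-MRI. The
same haemodynamic disturbance leaves a fingerprint in contrast-free
resting-state BOLD data: the systemic low-frequency oscillation (sLFO) that
travels with the blood arrives late in hypoperfused tissue, loses power to
the lowest frequencies, and stays confined to the affected vascular
territory. `hicfinder` turns that fingerprint into an automated detector:

1. **Decompose** the preprocessed 4D signal by spatial ICA into components
   `X ≈ Sᵀ A` (spatial maps `S`, mutually independent and non-Gaussian over
   voxels; time courses `A`), maps Z-scaled and thresholded at |Z| > 2.33.
2. **Summarise** each component by nine features: delay of its time course
   behind the global and venous-sinus references (cross-correlation over
   ±20 s with parabolic sub-sample refinement), percentage of spectral
   power in six bands (0–0.01, 0.01–0.025, 0.025–0.05, 0.05–0.1, 0.1–0.15,
   0.15–0.2 Hz), and percent restriction to a single vascular territory —
   each min–max normalized within subject, z\_i = (x\_i − min S)/(max S − min S).
3. **Classify** hypoperfusion independent components (HICs) against all
   other components with an elastic-net regularised logistic model
   (mixing α = 0.5, shrinkage λ by leave-one-out CV, probability cut by
   Youden's index J = sensitivity + specificity − 1), trained on a
   50/50-balanced subsample and evaluated over repeated 1:10 imbalanced
   test draws. Odds ratios are `exp(coef)`; penalised-away features have
   OR exactly 1.

A synthetic phantom generator (`phantomConfig()`, `simulateSubject()`)
produces 4D BOLD series with a band-limited sLFO, territory-restricted
delayed sources, bilateral network sources, noise, drift, motion traces
and matched ground-truth T<sub>max</sub>/lesion volumes, so the entire
pipeline is testable at desk scale. Companion tools cover voxelwise
time-shift (BOLD lag) mapping with a recursively refined regressor,
framewise-displacement motion QC, and Dice-overlap validation.

The intended audience is stroke-imaging researchers who want a
reproducible, scriptable reference implementation of ICA-based
hypoperfusion detection, and methods developers who need a ground-truthed
sandbox for BOLD-lag analyses.

## Worked example

```r
library(hicfinder)

sub <- simulateSubject(phantomConfig(seed = 1))   # 1 HIC at +7 s, 2 RSNs
pp  <- preprocessBold(sub$series)                 # discard 4, detrend, 6 mm FWHM
cs  <- spatialICA(pp, seed = 1)                   # k chosen automatically
cs
#> ComponentSet: 4 components over 7528 voxels x 146 time points
#>   (fixed-point logcosh, symmetric decorrelation ICA)
#>   explained variance: 1.4% 7.5% 5.0% 86.0%

ft <- componentFeatureTable(cs, pp, sub$atlas, sub$venousMask,
                            tmax = sub$truth@tmaxMap)
ft[, c("component", "delayGlobal", "occupancy", "band1", "band2",
       "meanTmax", "dominantTerritory")]
#>   component delayGlobal occupancy  band1 band2 meanTmax dominantTerritory
#> 1         1        7.74      15.0  0.962 16.42     2.27             FALSE
#> 2         2       18.40      50.0  1.372 24.91     1.31             FALSE
#> 3         3        1.95      42.5  0.306  4.86     1.57             FALSE
#> 4         4        6.46     100.0 16.111 45.60     8.30              TRUE
```

Component 4 carries the hypoperfusion signature: its time course lags the
global signal by ~6.5 s (truth: 7 s), it sits entirely inside one vascular
territory, it holds the most power below 0.025 Hz (band1 + band2), and it
overlaps the high-T<sub>max</sub> lesion (mean 8.3 s vs ~1.3 s elsewhere).
The lesion-overlap validator agrees:

```r
ov <- identifyHicByOverlap(cs, sub$truth@lesionMask)
round(ov$dice, 3)
#> [1] 0.088 0.000 0.014 0.832
ov$argmax
#> [1] 4
```

The full classifier protocol on a synthetic 57-HIC / 471-non-HIC feature
table (train 23+23 balanced, LOO-CV elastic net, Youden threshold; test
50 draws of 5 HICs + 50 non-HICs):

```r
res <- runClassifierProtocol(seed = 1)
res$metrics
#> MetricsReport over 50 iterations (medians):
#>              auc balancedAccuracy      sensitivity      specificity
#>            0.982            0.930            1.000            0.880
#>            kappa
#>            0.547
round(oddsRatios(res$model), 3)
#> delayGlobal delayVenous   occupancy       band1       band2       band3
#>     378.689  148237.828     227.162       3.851       1.000       0.002
#>       band4       band5       band6
#>       1.000       1.000       0.053
```

Both delays and territory occupancy push a component toward HIC (OR > 1 on
the normalized 0–1 scale); power at 0.025–0.05 Hz pushes away (OR < 1);
features with OR exactly 1 were dropped by the penalty.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/hicfinder.R simulate   --out subj --seed 1
Rscript inst/cli/hicfinder.R preprocess --in subj/bold.nii.gz \
        --mask subj/brain_mask.nii.gz --out pp.nii.gz
Rscript inst/cli/hicfinder.R decompose  --in pp.nii.gz \
        --mask subj/brain_mask.nii.gz --out ica --seed 1
Rscript inst/cli/hicfinder.R features   --series pp.nii.gz \
        --mask subj/brain_mask.nii.gz --maps ica/component_maps.nii.gz \
        --tcs ica/timecourses.txt --atlas subj/atlas.nii.gz \
        --venous subj/venous_mask.nii.gz --tmax subj/tmax.nii.gz \
        --out features.tsv
Rscript inst/cli/hicfinder.R qc         --motion subj/motion.par
```

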