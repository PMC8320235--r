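# epilink

Quantification of immunolabeling **linkage errors** in 3D
single-molecule localization microscopy (SMLM).

Antibody labels place the reporter — a fluorophore (STORM) or a DNA
docking strand (DNA-PAINT) — nanometers away from the epitope they
mark. Around a microtubule (a cylinder of known outer radius,
12.5 nm), immunolabels therefore form a hollow *labeling shell* whose
radius `r` and thickness `w` expose the linkage error:

```
minimum linkage error = (r − 12.5 nm) − 0.5 w
maximum linkage error = (r − 12.5 nm) + 0.5 w
```

`epilink` measures this shell from both directions:

* **Forward — Monte Carlo antibody simulation.** IgGs are modeled as
  kinked chains of rigid segments (Fab, hinge→Glu295, linker; five
  segments for primary + secondary stacks) with uniform kink angles
  within configurable bounds, steric exclusion by the microtubule and
  a minimum distance `d_min` between non-sequential segments.
  Rejection sampling yields reporter position distributions and their
  radial peak/fwhm (`simulateBatch()`, `radialDistribution()`,
  `densityMap()`, `revolveConvolve()`).
* **Inverse — convolved Gaussian-ring fit.** 3D localizations near a
  microtubule ROI are registered by a least-squares cylinder fit,
  projected into the cross-section, binned at 2 nm, and fitted by the
  ring image `exp(−(ρ−r)²/2σ²)` convolved with a compound anisotropic
  blur kernel built from binned per-localization CRLB precisions plus
  a residual-drift Gaussian; `w = 2.35 σ` (`fitShell()`, `fitRing()`,
  `linkageErrors()`).
* **Support.** A ground-truth synthetic scene generator
  (`makeScene()`), pairwise F-test comparison of fitted parameters
  (`compareParams()`), degree-of-labeling calculators from UV–vis
  absorbances (`dolAF647()`, `dolDNA()`), CSV/YAML/JSON interfaces,
  and a command-line wrapper (`inst/scripts/epilink.R`).

## Worked example

Linkage errors from measured shell dimensions — the package bundles a
reference table of fitted shell parameters for six labeling
conditions:

```r
library(epilink)
ref <- shellFitReference()
ref[3, ]
#>   cells      labeling modality scheme r_nm r_ci95 w_nm w_ci95
#> 3  U2OS aTub-647 1deg    STORM direct 20.2   0.24   10   0.48

linkageErrors(ref$r_nm[3], w = ref$w_nm[3],
              ci95R = ref$r_ci95[3], ci95W = ref$w_ci95[3])
#> $minimum
#> [1] 2.7
#> $maximum
#> [1] 12.7
#> $ci95
#> [1] 0.5366563
```

A directly labeled primary antibody in STORM leaves the fluorophore
between 2.7 and 12.7 nm from the microtubule surface. Comparing the
direct against the indirect STORM condition:

```r
compareShells(indirect = list(r = 22.5, w = 16.9),
              direct   = list(r = 20.2, w = 10.0))
#> $radiusDecrease
#> [1] 2.3
#> $thicknessReductionPct
#> [1] 40.82840
```

Direct labeling moves the shell 2.3 nm closer to the epitope and
shrinks its spread by ~40%.

Forward simulation with the bundled (reconstructed, approximate)
antibody geometry:

```r
cfg <- readModelConfig(modelConfigPath("direct"))
batch <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt,
                       nTarget = 300000, seed = 1)
batch
#> ConformationBatch: 300000 accepted / 526812 attempted (56.9%), seed 1
radialDistribution(batch)
#> RadialDistribution: 26 bins on [12.50, 25.50] nm; peak 19.75 nm, fwhm 7.42 nm
```

The simulated reporter shell of a direct-labeled primary peaks ~7 nm
outside the microtubule surface with a ~7 nm spread; the five-segment
indirect model (`modelConfigPath("indirect")`) peaks ~2.5 nm farther
out with roughly twice the spread — secondary antibodies mostly add
imprecision, not offset, because the flexible hinge randomizes the
direction in which they protrude.

End-to-end on synthetic ground truth:

```r
scene <- makeScene(sceneConfig(shellR0 = 20, shellW0 = 10), seed = 1)
res <- fitShell(scene$locs, scene$rois)
res$fit
#> RingFit: r = 20.08 +/- 0.12 nm, w = 8.90 +/- 0.51 nm (sigma 3.79), 20 sections
```

## Command line

```sh
Rscript inst/scripts/epilink.R simulate-antibody \
    --config inst/extdata/model_direct.yaml --n 300000 --seed 1 --out batch.csv
Rscript inst/scripts/epilink.R fit-shell \
    --locs locs.csv --rois rois.csv --drift 2.0,3.0 --out fit.json
Rscript inst/scripts/epilink.R dol --mode af647 --a280 0.5 --a650 0.5
```

See the methods vignette (`vignettes/linkage-errors.Rmd`) for the
model details, parameter rationale, and limitations.
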