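# hospect

Scatter correction, OSEM reconstruction and voxel dosimetry for
holmium-166 SPECT phantom studies.

## Why

¹⁶⁶Ho-loaded microspheres (half-life 26.8 h) are used in transarterial
radioembolization of liver tumours, and treatment dosimetry is computed
from quantitative SPECT of the 80.6 keV photopeak. The ¹⁶⁶Ho spectrum is
hostile to quantification: high-energy 1379 keV gamma rays scatter down in
energy (and cross the collimator septa) so that roughly *half* of the
counts in the main energy window are scatter. `hospect` implements, as a
tested R pipeline, the phantom arm of a study comparing the two practical
projection-space corrections:

* **DEW** (dual energy window): `W2 − k·W4`, with a downscatter window at
  118 keV and k = 1;
* **TEW** (triple energy window): subtraction of a trapezoidal scatter
  estimate built from two narrow 6 keV windows flanking the 12 keV main
  window — at these widths, exactly the sum of the side windows.

The pipeline simulates a six-sphere Jaszczak phantom acquisition from a
parametric model of the four spectrum components (photopeak + associated
scatter, high-energy downscatter, X rays, bremsstrahlung), corrects,
reconstructs every arm with the same OSEM protocol (10 iterations,
8 subsets, optional Butterworth 0.25/1.5 post-filter), scores image quality
with contrast recovery coefficients

CRC_i = (measured/true concentration in sphere i) / (measured/true concentration in background)

fitted by the sigmoid `S(x) = 1/(1 + e^(−b(x−c))) − d` (plateau fixed at
a = 1, x = sphere diameter/FWHM) and contrast-to-noise ratios

CNR_j = |mean(sphere j) − mean(background)| / sd(background),

and quantifies the dosimetric impact with the local-dose-deposition model,
`dose = A·κ·(counts/total)/mass`, DVH criteria (tumour fraction ≥ 150 Gy,
normal-tissue fraction 0–50 Gy), activity planning under lung-dose limits,
and paired t-tests between correction methods.

See the methods vignette (`vignettes/hospect-methods.Rmd`) for the models,
assumptions and design choices.

## Worked example

```r
library(hospect)

## the spectrum component model: a million-event draw in the main window
round(100 * sampleWindowComponents(spectrumComponentModel(), "W2", 1e6, seed = 1) / 1e6, 2)
#> photopeak_80keV_and_scatter         high_energy_scatter
#>                       48.30                       48.71
#>                   xray_peak              bremsstrahlung
#>                        0.00                        2.99

## the acquisition energy windows
defaultWindows()
#>   label center widthPercent  lower  upper  width
#> 1    W1  71.56         8.39  68.56  74.56  6.004
#> 2    W2  80.60        15.00  74.55  86.64 12.090
#> 3    W3  89.65         6.69  86.65  92.65  5.998
#> 4    W4 118.00        10.20 111.98 124.02 12.036

## the digital phantom: 18:1 sphere:background concentration, 341 MBq nominal
buildJaszczak()
#> VoxelPhantom
#> GridSpec: 128 x 128 x 128 voxels, 4 x 4 x 4 mm, origin (-254, -254, -254) mm
#>   total activity: 337.58 MBq in 8 regions

## the full study at a reduced grid (64^3, 48 projections, ~40 s)
cfg <- pipelineConfig(seed = 42L,
                      phantom  = list(gridShape = c(64L, 64L, 64L)),
                      geometry = list(nProjections = 48L),
                      metrics  = list(erosionMargin = 0L))
res <- runPipeline(cfg)
aggregate(cbind(crc, cnr) ~ method, res$metrics$table, mean)
#>         method   crc  cnr
#> 1          dew 0.123 2.15
#> 2 scatter_free 0.246 8.03
#> 3          tew 0.134 1.30
#> 4  uncorrected 0.103 2.21
```

Reading the numbers: at this coarse grid the sphere diameters are only
0.5–1.5 system FWHM, so absolute contrast recovery is low everywhere, but
the *ordering* reproduces the study's figures — the scatter-free reference
recovers the most contrast; TEW comes closest to it; DEW is barely
distinguishable from no correction; and TEW pays for its correction with
the lowest contrast-to-noise ratio (the 6 keV side windows are noisy). The
paired dosimetric comparison over the six spheres-as-tumours is also
returned:

```r
res$stats[, c("criterion", "meanA", "meanB", "t", "p", "significant")]
#>             criterion meanA meanB     t      p significant
#> 1 sphere_mean_dose_Gy  2.24  2.47 -3.47 0.0179        TRUE
```

(method A = DEW, method B = TEW: the choice of scatter correction shifts
the estimated mean tumour dose significantly, here by about 10 %.)

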