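# neurotort

Quantification of relative neurite tortuosity from Fourier transforms of
incompletely segmented neurite masks.

## The problem

The tortuosity of corneal sub-basal nerves is a clinical biomarker
(diabetic neuropathy, herpes zoster ophthalmicus, keratitis, Sjögren's
syndrome), but classical tortuosity measures — arc length over chord
length per neurite — require every neurite to be traced completely.  In
dense, dimly and unevenly labeled networks, segmentation is inevitably
discontinuous, and gap-bridging models contaminate the measurement with
their own assumptions about neurite paths.

`neurotort` measures tortuosity at the population level as **loss of
directional coherence**, which survives discontinuity.  Structures
oriented at angle θ contribute energy along the orthogonal direction of
the 2-D discrete Fourier transform, so a field of straight parallel
neurites gives a strongly anisotropic power spectrum while a tortuous
field gives an isotropic one.  The score is

τ = minor/major axis of an origin-centered ellipse fitted to the polar
profile of median spectrum amplitude over direction, restricted to an
annular bandpass (5–40 µm/cycle for corneal masks, 4–32 px/cycle for
simulations),

with τ ∈ (0, 1]: τ → 0 is perfectly coherent (straight), τ = 1 is
isotropic (maximally tortuous).  Scale dependence is measured by dividing
the mask into an n × n grid and aggregating per-cell scores with neurite
density weights:

    tau_net = sum(tau_ij * rho_ij) / sum(rho_ij)

The package provides the full pipeline: reading multi-page TIFF z-stacks,
axial Gaussian denoising, disk-median background subtraction,
skeletonization by prominence-filtered local maxima of orthogonal
reslices, spectral tortuosity measurement at any grid scale, a
scale-variant/invariant tortuous-line simulator for validation, and
two-sample Kolmogorov–Smirnov group comparison.

## Worked example

```r
library(neurotort)

# simulate a field of discontinuous lines curving about the image center
cfg  <- simulationConfig(variant = "scale_variant", alphaScale = 0, seed = 1)
mask <- simulateMask(cfg)

band <- passband(4, 32, "px")
gridTortuosity(mask, 1, band)   # global: one 1024 px window
#> GridTortuosityResult: 1 x 1 grid, tau_net = 0.8333
gridTortuosity(mask, 4, band)   # local: 16 windows of 256 px
#> GridTortuosityResult: 4 x 4 grid, tau_net = 0.1145
```

Concentric circles are continuously changing direction across the field of
view, so globally they are highly tortuous (τ_net = 0.83), yet within any
256-px window they are nearly straight arcs (τ_net = 0.11).  The same
field measured at two scales cleanly separates scale-variant from
scale-invariant tortuosity; for parallel straight lines
(`variant = "invariant"`) both numbers are small (0.006 and 0.016 with
seed 1) and rise together as the tortuosity scaling factor `alphaScale`
increases.

For a real stack:

```r
cfg <- runConfig(inputs = "cornea.tif", outputDir = "out",
                 spacingOverride = c(1.24, 1.24, 1.24))
runPipeline(cfg)   # writes skeleton mask, results.csv, manifest.yaml
```

Group comparison of tau_net values (second group is the reference):

```r
compareGroups(central_tau, peripheral_tau)
#> GroupComparison (n = 11 vs 31): delta median, percent vs reference, KS D, p
```

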