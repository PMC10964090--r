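---
title: "Measuring neurite tortuosity from Fourier power spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neurite tortuosity from Fourier power spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotort)
```

## The problem

Corneal sub-basal nerves, and dense neurite networks generally, are imaged
in vivo as incomplete, discontinuous traces: segmentation breaks at every
dim stretch, and per-neurite measures of tortuosity (arc length over chord
length) need every neurite traced end to end.  Bridging the gaps with a
tracing model begs the question, because the model's gap-filling policy
encodes an assumption about exactly the quantity being measured.

`neurotort` instead measures tortuosity as a *population-level* property
that survives discontinuity: the loss of directional coherence.  A neurite
field with no tortuosity consists of segments that share a heading; a
maximally tortuous field has segments headed every way.  Directional
coherence is read off the two-dimensional discrete Fourier transform of a
binary neurite mask: structure oriented at angle $\theta$ contributes
spectral energy along the direction orthogonal to $\theta$, so a coherent
field gives an anisotropic power spectrum and a tortuous field an isotropic
one.

## The measurement

Given a binary skeleton mask, the score is computed in three steps.

1. **Power spectrum.** The mask is embedded centered in a zero square (so
   the frequency radius is isotropic and the bandpass annulus circular) and
   the DFT magnitude is computed with the zero-frequency bin at the center.
   Real input makes the amplitude point-symmetric; the implementation
   symmetrizes explicitly so the property holds exactly in floating point.
2. **Annular-sector polar profile.** For each of $K$ directions
   $\theta_k = k\,360^\circ/K$, the *median* amplitude is taken over the
   pixels inside the bandpass annulus and within $\pm h$ degrees of
   $\theta_k$.  The annulus restricts the analysis to a chosen range of
   spatial periods — 5.0 to 40 $\mu$m per cycle for corneal masks, 4.0 to
   32 pixels per cycle for simulated ones — which targets tortuosity
   feature sizes and suppresses pixel-harmonic artefacts at the highest
   frequencies.  The median, rather than the mean, keeps the profile
   robust against the energy a hard-edged binary mask concentrates on the
   frequency axes.
3. **Ellipse aspect ratio.** An origin-centered conic $x^\top Q x = 1$ is
   fitted to the polar profile by linear least squares (the profile is
   point-symmetric by construction, so a free center would only absorb
   noise), and the tortuosity score is
   $\tau = \sqrt{\lambda_{\min}/\lambda_{\max}} \in (0, 1]$, the
   minor:major aspect ratio.  $\tau = 1$ is an isotropic (maximally
   tortuous) field; $\tau \to 0$ is perfect coherence.

### Multi-scale analysis and density weighting

Tortuosity is scale-variant: neurites spiraling about the corneal apex look
tortuous across the whole field but straight within any small window.  The
mask is therefore divided into an $n \times n$ grid and each cell measured
separately; the cell size is the length scale of the measurement.  Because
neurite density varies between cells, per-cell scores are aggregated with
density weights,

$$\tau_{net} = \frac{\sum_{i,j} \tau_{i,j}\,\rho_{i,j}}
                    {\sum_{i,j} \rho_{i,j}},$$

where $\rho_{i,j}$ is the fractional mask area of cell $(i,j)$.  Cells with
no signal, or too little for a stable profile, have undefined $\tau$ and are
excluded from both sums — coercing them to zero would cast a spurious
"perfectly coherent" vote.  Each cell is re-embedded in its own square and
the annulus radii are recomputed from the cell side, so the passband stays
fixed in physical units across scales and local and global measurements are
comparable.

## Stack preprocessing and skeletonization

The spectral score must not be biased toward bright or thick neurites, so
the image stack is normalized before analysis.

* **Axial Gaussian denoising** ($\sigma$ = 2 voxels along Z, kernel
  truncated at $\pm 4\sigma$, edges replicated).  Detector noise is
  high-frequency; because the Z step is finer than the axial optical
  resolution, filtering along Z removes it without blurring neurites.  A
  lateral median filter would also erase the finest neurites, which is why
  denoising is axial only.
* **Background subtraction** (lateral median over a discrete disk, radius 3
  pixels, per Z slice).  Neurites are thin and sparse, so the median
  excises them from the background estimate; subtracting it removes
  vignetting and mottled autofluorescence and equalizes local contrast.
  Differences are clamped at zero.
* **Skeletonization by orthogonal local maxima.**  The stack is resliced
  into XZ and YZ projections and, in every slice, regional maxima with
  topographic prominence above 0.10 of the slice maximum are marked.  The
  relative threshold makes detection contrast-based and intensity-scale
  free.  Both reslices are needed: a neurite running exactly along X is a
  translation-invariant ridge in XZ slices (its maxima degenerate to one
  plateau point) but a clean spot maximum in every YZ slice, and vice
  versa.  The marked volumes are unioned and flattened by a maximum
  projection along Z into the binary mask.  A flat plateau of tied maxima
  marks only its centroid pixel, keeping the skeleton about one pixel wide
  without morphological thinning (which could erase isolated maxima of dim
  neurites).

## The line simulator

Validation needs fields of known tortuosity.  The simulator draws
one-pixel polylines whose successive segment headings follow

$$\theta_{final} = \theta_{initial} + \alpha_{scale}\,\varphi_{random},
  \qquad \varphi_{random} \sim \mathrm{Uniform}(-\pi, \pi),$$

so $\alpha_{scale} = 0$ gives smooth paths and larger values progressively
randomize the heading.  Discontinuous segmentation is emulated by drawing
each line's segment count uniformly from a range, so lines end early.  Two
geometries share identical random draws under one seed:

* **invariant** — lines start evenly spaced on the left edge heading
  right.  At $\alpha_{scale} = 0$ the field is parallel straight lines,
  non-tortuous at every scale.
* **scale_variant** — lines start on concentric circles about the canvas
  center, heading tangentially, with a deterministic extra turn of
  (segment length)/(radius) per segment.  At $\alpha_{scale} = 0$ each path
  is a circle: tortuous globally, coherent locally.

### Geometry calibration

The canvas is 1024 px with the 4–32 px/cycle passband. Two quantities fix
the remaining constants.

*Segment length (40 px).*  Each segment perturbs the heading with standard
deviation $\alpha\pi/\sqrt{3}$, so across a feature of size $s$ the heading
spreads by roughly $\alpha (\pi/\sqrt{3}) \sqrt{s/L}$ radians for segment
length $L$.  With $L = 40$ px this spread reaches ~1 radian at the largest
analyzed feature ($s = 32$ px) only at the top of the standard sweep
($\alpha = 0.6$): the score stays responsive over the whole sweep instead
of saturating early.  Much shorter segments put a corner every few pixels,
whose near-isotropic scatter floods the passband and saturates the score by
$\alpha \approx 0.2$.

*Line count (128) and segment count (4–24 per line).*  A region containing
$n$ independently oriented segments shows a spurious spectral quadrupole —
a sampling floor on anisotropy — of order $\sqrt{\pi/(4n)}$.  The 256-px
cells of the local ($4\times4$) analysis therefore need at least on the
order of a hundred segments each; 128 lines of 160–960 px put about 7% ink
on the canvas and roughly 100–150 segments per cell.  The scale-variant
start radii are 300 px with a 1.5 px per-line increment, keeping the
outermost circle (490 px) inside the canvas.

Lines whose path leaves the canvas are clipped at the boundary and end
there.  Sweeps (`sweepAlpha()`) can average several simulated replicates
per $\alpha$ to reduce the Monte Carlo error of each point; the validation
runs use 3.

### What the simulator does not emulate

Simulated masks are ideal binary traces: there is no point-spread function,
no intensity variation, no detector noise, no neurite crossings-in-depth,
and discontinuity appears only as early line termination rather than
mid-line gaps.  Passing simulation tests therefore validates the
*measurement* — spectrum, profile, ellipse, grid weighting — and the
skeletonizer is validated separately on 3-D phantoms with known
centerlines, noise and background.  Neither establishes performance on
real corneal stacks, for which no public reference data exist.

## Numerical choices

* Processing is in floating point regardless of input bit depth; 16-bit
  values survive a write/read round trip exactly.
* Gaussian kernel truncation at $\pm 4\sigma$; recorded in the run
  manifest.
* No apodization window before the DFT by default (the binary mask is
  transformed directly); windowing is exposed as an option.  Edge energy
  concentrates on the frequency axes and is suppressed by the annulus and
  the median statistic.
* Profile defaults $K = 360$, sector half-width $1^\circ$: overlapping
  2-degree sectors stabilize the median at small radii.  If more than 10%
  of sectors are empty the geometry cannot support $K$ directions and the
  call fails with advice to widen the sector.
* The ellipse fit drops zero radii (they carry no direction information),
  normalizes by the maximum radius (aspect is scale-invariant), and falls
  back to the min/max radius ratio with a warning if the fitted conic is
  not positive definite.  An exactly flat profile returns exactly 1.
* Tied maxima plateaus mark the pixel nearest the plateau centroid;
  ties in the centroid distance resolve to the lowest pixel index, so
  skeletonization is fully deterministic.
* Grid remainders (mask side not divisible by $n$) go to the last row and
  column of cells.
* The two-sample Kolmogorov–Smirnov p-value is exact for
  $n \times m \le 10^4$ (covering typical image-group sizes) and asymptotic
  beyond.

## Validation design and problem sizes

The test suite verifies the spectrum against a brute-force $O(N^4)$ DFT on
masks up to $16\times16$; ellipse recovery to $10^{-6}$ for aspect ratios 1
to 10 at arbitrary rotation; the density-weighted aggregate against hand
evaluation; prominence-filtered maxima against a flood-based oracle;
skeleton recovery within one pixel on tube phantoms (including tubes
aligned with either reslice axis); exact KS p-values against exhaustive
enumeration at $n = m = 3$ and $4$ with a 1000-replicate null calibration;
and the two simulation sweeps ($\alpha = 0$ to $0.6$ in steps of 0.1,
grids $1\times1$ and $4\times4$, 1024-px canvas, 3 replicates per point).

## Known limitations

* The score is population-level; it cannot attribute tortuosity to
  individual neurites, and it is uninformative for fields that are
  radially symmetric by construction.
* $\tau$ compresses near its ends: once the heading distribution of a
  field is nearly uniform, further increases in path tortuosity barely
  move the score.
* Local (small-window) measurements carry two window-size effects that the
  global measurement lacks: spectral blur of narrow directional lobes by
  the cell window transform (inflating $\tau$ for strongly coherent
  cells), and the finite-sampling anisotropy floor (deflating $\tau$ for
  nearly isotropic cells by roughly $2\sqrt{\pi/(4n)}$ for $n$ segments in
  the cell).  At the validation density these opposing effects leave
  local–global differences of up to about 0.07 at intermediate and high
  $\alpha$ in the scale-invariant sweep; they shrink with denser fields
  and larger cells, and do not affect the ordering of conditions at a
  fixed scale — comparisons should be made at matched grid sizes, as in
  the central-versus-peripheral cornea design.
* TIFF metadata dialects vary; an explicit spacing override always beats
  file metadata, and runs record every resolved parameter in a manifest.
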