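---
title: "Methods: simulated visible-light OCM of amyloid pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated visible-light OCM of amyloid pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package models

Visible-light optical coherence microscopy (OCM) images *ex-vivo* brain
tissue at sub-micrometre axial resolution using the intrinsic
backscattering contrast of the tissue. In Alzheimer-model cortex,
amyloid-beta plaques (10--70 um across) appear as hyperscattering foci in
en-face projections, white-matter tracts as bright bands, and cell bodies
as hyposcattering spots. The quantitative endpoints of such a study are
the areal plaque load (plaques/mm^2 counted in a 50-um sub-surface
window, tiled into millimetre-scale mosaics), volumetric plaque
morphometry (per-plaque volume in um^3 from 3-D segmentation), plaque
contrast-to-noise ratios, and group comparisons of these quantities.

Since ex-vivo specimens cannot be redistributed, `visocm` replaces the
instrument and the tissue with a simulator whose statistical structure
matches the study conditions, and implements the complete analysis chain
on top of it: spectral-domain reconstruction, surface-referenced en-face
projection, attenuation mapping, segmentation and morphometry, synthetic
immunohistochemistry with color deconvolution, mosaic planning and
stitching, and Kolmogorov--Smirnov group statistics. Every stage is
testable against the generator's ground truth.

# The forward model

## Tissue phantom

`build_phantom()` voxelizes a cleared 200-um-class slab:

* **Plaques** are non-overlapping spheres with a thin (1 um) soft edge.
  Real deposits are distinct objects; modelling them as interpenetrating
  would make truth volumes ill-defined. Placement is dart-throwing with
  retries, so the plaque count keeps its Poisson law (mean
  `density x area` for areal fixtures, `density x volume` for volumetric
  ones). Areal fixtures place centres 10--45 um below the slab top so
  every plaque intersects the standard 0--50 um counting window;
  volumetric fixtures place spheres fully interior (5-um margins) because
  an object cut by the surface or by the end of the usable depth range
  cannot be measured and is likewise excluded by the 3-D segmentation.
* **Diameters** follow a lognormal truncated to 10--70 um, the range in
  which cortical plaques are observed. The mouse en-face fixtures use
  median 25 um (aged) and 20 um (young) with log-SDs 0.45/0.40 -- the
  shape is not constrained by any published distribution and is a
  declared stand-in; the tests therefore compare recovered distributions
  against this same configured law, not against external data. The
  volumetric fixtures are parameterized directly by per-plaque volume
  (lognormal with mean 6600 and SD 1700 um^3 for human-AD cortex, 4500
  and 1200 um^3 for aged-mouse cortex).
* **Densities**: 23 and 17 plaques/mm^2 for the aged/young mouse en-face
  fixtures (the study's printed loads). Volumetric densities are not
  printed anywhere; 1500/mm^3 (human) and 2200/mm^3 (mouse) are one-time
  choices in the range reported for late-stage AD cortex and aged APP-PS1
  mice, ordered so that the mouse load exceeds the human load.
* **Optical properties** (relative to parenchyma backscatter 1e-5 of a
  unit mirror, attenuation 4/mm before clearing): plaques scatter 2.5x
  (mouse) or 3.5x (human -- denser-core human plaques produce the higher
  CNR) with 2x attenuation; fibers 3x / 10 per mm; cell bodies 0.3x / 3
  per mm; CAA wall deposits 3.5x. Parenchyma carries a multiplicative
  lognormal texture (SD 0.25, truncated to [0.45, 2.2] and renormalized)
  so that background statistics are non-degenerate; the truncation keeps
  the hyper-/hypo-scattering contrast of labelled voxels strict.
* **Surface**: a smooth ripple (amplitude 3 um, period 400 um) on an
  8-um immersion gap. The immersion medium is modelled index-matched to
  the tissue group index (cleared tissue under water immersion), so one
  depth scale serves the whole volume.

## Interferogram synthesis

For every A-line the detected spectrum is

```
S(k) = E(k) [ DC + sum_z 2 sqrt(R_att(z)) cos(2 k n z_opt + phi(k)) ] + noise
```

with `E(k)` the source envelope (Gaussian, 555/156 nm on 425--680 nm by
default), `R_att` the backscatter after round-trip Beer--Lambert
attenuation (`exp(-2 integral mu)`, with the clearing factor dividing
`mu`), `z_opt = n (h + z)` the optical depth below the reference plane,
and `phi(k)` a quadratic-plus-cubic dispersion phase. Sensitivity
roll-off multiplies reflector amplitudes by `10^(-r z_opt / 20)` with
`r` in dB/mm -- linear in dB, so that two equal reflectors 1 mm apart
differ by exactly the rated 24 dB (a Gaussian spectrometer-response model
is not identifiable from a single rating and would only approximate it).
Detector noise is additive white Gaussian with
`sigma = sum(E) / (sqrt(N) 10^(S_dB/20))`, which makes a unit reflector
at zero depth reconstruct at exactly the configured sensitivity
(91 dB default); photon statistics are not modelled. The simulator also
records the source background `E(k) x DC` the way a real instrument
acquires a background frame.

Out of scope on purpose: speckle statistics, confocal gating,
polarization, multiple scattering, and the clearing chemistry itself
(clearing is an attenuation divisor only).

# Reconstruction

`ocm_reconstruct()` (or the four exposed stages) performs:

1. **Background subtraction**: the recorded source background is
   subtracted when available, then the per-A-line spectral mean. The
   scalar mean removal alone leaves an envelope-shaped residual whose
   transform leaks out to roughly the first ten micrometres of depth --
   exactly where a shallow surface sits -- which is why the reference
   subtraction matters.
2. **k-resampling**: cubic (Catmull--Rom) interpolation from the
   wavelength-uniform axis onto a uniform wavenumber grid spanning the
   same range, precomputed as one sparse matrix. On a k-uniform input it
   is an exact pass-through.
3. **Spectral shaping**: Hann apodization by default. On the truncated
   Gaussian source this buys >= 20 dB of side-lobe suppression over a
   rectangular window at a modest main-lobe cost.
4. **Dispersion compensation**: multiplication by `exp(-i phi(k))` about
   the centre wavenumber. In simulation the forward coefficients are
   known, mirroring the hardware-plus-postprocessing optimization a real
   system performs; an explicit zero disables it.
5. **Fourier transform** along k, normalized so Parseval's identity holds
   between the shaped spectrum and the full A-line; the positive-depth
   half is kept and the axis divided by the group index (1.36), so that
   the printed air resolution of 1.2 um reads 0.88 um in tissue.

The noise floor (median and MAD of linear intensity) is estimated from
the quietest depth planes of the volume rather than a fixed deepest
fraction: depending on geometry the quiet region may be the immersion gap
or the range beyond the slab, and a fixed fraction can land on tissue.

The axial point spread function is measured on the **amplitude envelope**
(`measure_psf_fwhm`), matching the coherence-length convention
`(2 ln 2 / pi) lambda0^2 / dlambda` (0.871 um in air for the default
source). The theoretical figure assumes an untruncated Gaussian
spectrum; the simulated, truncated source reconstructs a few percent
wider, within the 10% band the acceptance suite checks. The instrument's
own measured 1.2 um exceeds the theoretical value for reasons the source
specification cannot reproduce, so the simulator targets the theoretical
figure while the air-to-tissue conversion arithmetic targets the printed
0.88 um.

Surface detection takes, per A-line, the shallowest median-smoothed
sample above `floor + 10 sigma` (the default sits well above the
exponential tail of speckle-free intensity noise, and tens of dB below
tissue), then median-filters the height map laterally. En-face
projection averages **linear** intensity over `[surface, surface + 50 um)`
by default -- averaging in dB would weight the decaying depth profile
differently, and linear intensity is the physically additive quantity.
The attenuation map uses the depth-resolved single-scattering estimator
`mu_i = I_i / (2 delta sum_{j>i} I_j)`, with the deepest samples masked
where the estimator's closure assumption fails.

# Quantification

Manual plaque segmentation is replaced by an explicit, reproducible
surrogate: robust background statistics (median/MAD), a
`median + 3 sigma` threshold, connected components (8-connectivity in
2-D, 26 in 3-D) and a 10--70 um equivalent-diameter gate.

Two sizing conventions deserve their own explanation, because a fixed
global threshold measures systematically biased extents:

* **2-D (en-face) diameters.** The en-face footprint of a spherical
  deposit follows its chord profile, so a global threshold truncates
  small or deep plaques (whose 50-um-window contrast is diluted) far
  inside their true boundary -- deep 10--15 um plaques then fall below
  the 10-um gate and vanish from the load. The chord profile's FWHM is
  `sqrt(3)/2` of the true diameter *independently of the dilution*, so
  the default convention sizes each component at its own half-contrast
  level and applies the spherical-chord factor (4/3 on area). The raw
  supra-threshold footprint remains available (`diameter_mode =
  "threshold"`).
* **3-D volumes.** The point spread function blurs the backscattered
  *field*, so on an intensity profile the unbiased edge sits at
  `((sqrt(bg) + sqrt(core))/2)^2`, not at the intensity midpoint; each
  component's extent is refined at that level (`boundary = "halfmax"`).
  Before thresholding, volumes are masked above the detected surface,
  depth planes are normalized by their in-tissue median (compensating
  attenuation and roll-off so the threshold is depth-fair), the fine
  axial sampling is mean-binned to roughly half the lateral pitch, and
  components touching the axial limits of the tissue are excluded, as is
  standard for 3-D object counting.

CNR follows `|mu_P - mu_B| / sqrt(var_P + var_B)` with the background
taken from an annulus (1.2--3.2 plaque radii) restricted to the plaque's
own depth slab and excluding all segmented plaques; 25 plaques per volume
are sampled without replacement under a seed.

Synthetic histology renders DAB-stained plaque cross-sections and
hematoxylin nuclei through Beer--Lambert transmission with the standard
H-DAB stain vectors, at 3-um section thickness with every third section
used (pitch 9 um, so five slides span the 45 um matched to the OCM
window), plus per-slide rigid jitter. Analysis mirrors the histology
workflow: color deconvolution, chain registration of each slide to the
nearest preceding slide with immunoreactivity (rigid translation by
windowed cross-correlation; distant sections share too little structure
to register directly), Otsu thresholding of the DAB channel, OR-union of
the slide binaries (a plaque cut by several thin sections is counted
once) and size-gated component analysis.

The mosaic planner uses pitch `tile x (1 - overlap)` and
`ceil((side - tile)/pitch) + 1` tiles per side centred on the requested
area: a 2.5-mm field with 0.5-mm tiles gives 7 x 7 = 49 tiles at 1/3
overlap and 6 x 6 = 36 at 0.2 -- the two published grids, with the
overlaps back-solved from those counts since only "less overlap" is
stated for the faster scan. Stitching refines each tile against the
already-placed overlap by bounded cross-correlation and blends with
linear ramps; cropped tiles reassemble to the source image exactly.

# Statistics

`ks_two_sample` computes `D = sup |ECDF_a - ECDF_b|` with exact p-values
by lattice-path counting when both groups have at most 10 observations
and the asymptotic Kolmogorov distribution at
`sqrt(n1 n2/(n1+n2)) D` otherwise; `stats::ks.test` serves as an
independent cross-check in the test suite, never as the implementation.
Bonferroni correction takes the family size from configuration, since
the original comparison family is not stated. A numerical caveat worth
knowing: with 50 observations per group, D is confined to multiples of
1/50 and the achievable test sizes around the 5% level are 3.9% and
6.8%; no p-value method can make the finite-sample type-I rate equal
5% exactly, and the property suite documents this.

# Problem sizes and reproducibility

The acceptance-scale studies run at reduced sampling chosen once as
adequate for their endpoints: 256 spectral samples on 470--640 nm
(0.65 um axial pitch in tissue, 83 um usable depth), 5-um lateral pitch
and a 72-um slab for mosaic counting (plaques are 10--70 um; the
counting window is 50 um), and 2.5-um lateral pitch with a 70-um slab for
3-D morphometry (binned voxels about 2.5 x 2.5 x 1.3 um against plaque
diameters of 17 um and up). Plaque statistics, optical contrasts,
windows, gates and thresholds -- the study conditions -- are identical at
every scale. All randomness is seeded: phantoms and detector noise
derive their streams from the user seed, and re-running a pipeline
configuration reproduces byte-identical outputs (checksummed in the run
manifest).

# What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis
assumes: Poisson plaque counts, lognormal sizes, hyperscattering contrast
over textured parenchyma, attenuation, roll-off, dispersion, detector
noise, matched histology. It deliberately omits speckle statistics,
focus/confocal effects, real stain variability, rater behaviour and
scanner color response. Recovery of the configured densities and volume
scales therefore validates the pipeline's internal consistency and its
robustness to the modelled physics -- not its performance on real
specimens. Where the original endpoints depend on the specimens
themselves (specific p-values, CNR magnitudes), the package reproduces
the procedures and the generator-imposed orderings, not the numbers.
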