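---
title: "Signed degree-of-polarization imaging and tumor contrast statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed degree-of-polarization imaging and tumor contrast statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polcontrast)
```

## The measurement and the model

Reflection-mode (backscatter) polarimetry probes tissue by illuminating it
with a known polarization state and analyzing the polarization of the
returned light. Depolarization — the fraction of returned intensity that has
lost its polarization — differs between tumor and healthy tissue in many
organ systems, with tumors typically depolarizing *less*. `polcontrast`
implements the image-analysis side of that experiment: computing
degree-of-polarization (DOP) images from polarization-resolved intensity
frames, delineating a tumor region from a co-acquired fluorescence image,
and quantifying how well the DOP values separate tumor from non-tumor
pixels.

The central quantities are *signed* DOP metrics. The conventional circular
DOP is $S_{3,\mathrm{out}}/S_{0,\mathrm{out}} = (I_R - I_L)/(I_R + I_L)$,
always non-negative in magnitude terms. Here it is multiplied by the sign of
the incident circular component, so

$$\mathrm{DOCP} \;=\; \operatorname{sign}(S_{3,\mathrm{in}})
  \cdot \frac{I_R - I_L}{I_R + I_L} \;\in\; [-1, +1],$$

and a *negative* value means the returned handedness opposes the incident
one (helicity flipping, characteristic of direct backscatter from small
Rayleigh-regime scatterers), while a positive value means helicity
preservation. The magnitude is unchanged from the conventional definition —
a property the test suite asserts pixel-wise.

The signed linear DOP combines two separate experiments, one in the H/V
basis under a pure horizontal (or vertical) incident state and one in the
±45° basis under a pure diagonal state:

$$\mathrm{DOLP} \;=\;
  -\operatorname{sign}(S_{1,\mathrm{in}})\,
   \frac{I_H - I_V}{I_H + I_V}
  \;-\;\operatorname{sign}(S_{2,\mathrm{in}})\,
   \frac{I_{+45} - I_{-45}}{I_{+45} + I_{-45}}.$$

Each term is negative when the *co-linear* detected intensity dominates the
cross-linear one, mirroring the sign convention of the circular metric under
direct backscatter. Two conventions deserve comment, because the printed
form of this equation in the polarimetry literature is ambiguous:

* **Sign of the diagonal term.** We apply $-\operatorname{sign}(S_\mathrm{in})$
  to *both* terms, so that co-linear dominance is negative in each basis.
  The alternative (a positive sign on the ±45 term) makes an ideal mirror
  score $-2$; under our convention the mirror's H/V term is $-1$ and the two
  terms are interpreted identically. Consistency between the Mueller and DOP
  pathways is asserted on the H/V and circular terms.
* **Pure incident states only.** The sign factors are undefined when the
  relevant incident Stokes component is zero, and the printed denominators
  of the intensity form only equal the Stokes form for pure states. The
  functions therefore *reject* impure incident-state labels rather than
  adopting a sign(0) convention.

Because the two linear experiments are acquired separately, their sum can
mathematically leave $[-1, +1]$ when they disagree. Such pixels are
**flagged, never clamped** (`out_of_range` attribute) and excluded from the
contrast statistics.

A per-pixel total-DOP magnitude is defined as
$(|\mathrm{DOLP}| + |\mathrm{DOCP}|)/2$.

### Stokes convention

Fixed throughout and recorded in every output sidecar:
$S_1 = I_H - I_V$, $S_2 = I_{+45} - I_{-45}$, $S_3 = I_R - I_L$ with
right-circular positive. The source experiment never states handedness; one
convention had to be chosen, and all signs in the package are consistent
with it.

### Mueller imaging

The full 4×4 Mueller matrix is reconstructed per pixel from 16
generator/analyzer intensity measurements by exact inversion of the linear
forward model $I(g,a) = \mathbf{a}\,M\,\mathbf{s}_g$, with
$\mathbf{a}$ the ideal-analyzer row vector (including the factor ½) and
$\mathbf{s}_g$ the generator Stokes vector. The default scheme
$\{H,V,+45,R\}\times\{H,V,+45,R\}$ is the minimal invertible 16-state
design; the real apparatus's scheme and measured beam-splitter matrices live
in hardware-specific calibration files which are not reproduced, so
`correct_beam_splitter()` defaults to identity factors and accepts measured
ones ($M_\mathrm{sample} = M_\mathrm{det}^{-1} M_\mathrm{raw}
M_\mathrm{ill}^{-1}$). Indexing is `M11`…`M44`, first index the row; a
normalized image divides by `M11`, after which `M44` of a physical sample
lies in $[-1, +1]$ (−1 = helicity-flipped, +1 = helicity-preserved).

## Tumor masking and registration

The tumor region is delineated from a fluorescence image of the labelled
tumor line: every pixel with intensity at least `fraction` × the image
maximum (default 0.95, boundary-inclusive `>=`) is tumor. Whether "95%
intensity" means this rule or a top-5% percentile rule is not decidable from
the source description; the fraction-of-max rule is implemented and the
fraction is configurable. No connected-component filtering is applied by
default (an optional `keep_largest` flag exists for speckled images). The
margin outline keeps mask pixels within `thickness` (default 5) Chebyshev
pixels of a non-mask pixel — a square structuring element, which makes the
thickness exact along axes and diagonals alike.

Fluorescence and polarimetry frames are related by a rigid or similarity
transform estimated from fiducial point correspondences (window-chamber rim
elements in the real experiment; supplied as a CSV here — automatic fiducial
detection is out of scope) via the closed-form Procrustes/Umeyama solution,
reflections excluded. Masks are inverse-warped with nearest-neighbour
sampling (binary data; out-of-frame pixels become background). Coordinates
are 0-based (row, col), origin top-left.

## Contrast statistics

* **Histograms and overlap.** Tumor and non-tumor pixels are binned on one
  fixed grid of 80 bins (width 0.025) spanning $[-1-\varepsilon,
  1+\varepsilon]$ and normalized to unit area. The overlapping coefficient
  $\sum_b \min(f_T, f_N)\,\Delta$ ranges from 0 (total separation) to 1 (no
  separation). It is binning-dependent, so the bin width is always reported
  with it.
* **ROC/AUC.** The classification threshold sweeps the 39 interior grid
  points $-0.95, -0.90, \dots, +0.95$; pixels strictly above the threshold
  are positives (ties count negative — "above" is read strictly, and
  boundary handling matters at a 0.05-step grid). The curve is anchored at
  (0,0) and (1,1) and integrated trapezoidally — deliberately *not* a
  rank-based AUC, which serves instead as an independent property-check
  oracle (agreement within the discretization error). AUC below 0.5 is
  reported as-is; the source experiment itself reports a 0.40.
* **Orientation.** With helicity-flipping tumors the tumor class is *more
  negative*, so the literal signed-value sweep yields AUC < 0.5 even for
  well-separated classes. Whether published figures used signed values,
  magnitudes, or an implicit inversion cannot be determined; the pipeline
  computes both the literal signed sweep and a |value| variant and reports
  both.
* **Confidence intervals.** 95% percentile bootstrap, stratified by class,
  seeded. The swept AUC depends on the data only through per-class counts on
  the 40 threshold bins, so pixel resampling is realized exactly as a
  multinomial draw over those bins — distributionally identical to literal
  pixel resampling (verified against one in the tests) and O(bins) per
  replicate, which keeps the paper-scale setting (>5×10⁵ pixels per class,
  1000 replicates) in seconds.

## The synthetic scene: a stated world

The real mouse images are not public, so the pipeline is exercised on a
generator whose structure mirrors the reported findings. Its defaults are
fixed once:

| parameter | default | rationale |
|---|---|---|
| frame | 256 × 256 px | typical intensified-CCD region of interest |
| tumor | ellipse, axes (60, 40) px | few-mm xenograft at ~20 px/mm |
| DOCP tumor | N(−0.40, 0.12) trunc. | markedly negative, high magnitude |
| DOCP non-tumor | N(−0.10, 0.12) trunc. | weakly negative background |
| DOLP tumor | N(−0.55, 0.10) trunc. | linear magnitude exceeds circular |
| DOLP non-tumor | N(−0.45, 0.10) trunc. | slight tumor shift only |
| S0 | 1000 counts | comfortably above the 10⁻⁶ intensity floor |
| noise | additive Gaussian SD 2 (0.2%) | low-noise cooled detector; Poisson optional |
| fluorescence | contrast 200 over background 20, blur SD 2 px, noise SD 2 | bright labelled line, mild optics blur |
| transform | rigid, 0.02 rad, (+4, −6) px | small manual repositioning between microscopes |

Pixels are sampled i.i.d. from class-conditional truncated normals
(rejection sampling; one seeded RNG stream, saved and restored so library
calls never disturb the caller's RNG). Real tissue is spatially smooth; an
optional Gaussian correlation length exists but defaults to 0 because no
spatial statistics are reported to emulate. The intensity frames *realize*
the sampled DOP fields exactly before noise (inverse-then-forward identity),
with the signed linear value carried entirely by the H/V term by default
(`linear_split = 1`) — the two-term structure is under-determined by a
single target value, so the split is exposed. Fiducial disks are stamped
bright in both frames; in the polarimetry frames they scale intensity
without altering local DOP, so they do not perturb the statistics.

A green end-to-end test therefore establishes that the *pipeline* recovers
the statistical structure it was pointed at — class means/SDs within
sampling error, AUC and overlap at their closed-form binormal values
$\Phi\!\big((\mu_T-\mu_N)/\sqrt{\sigma_T^2+\sigma_N^2}\big)$ and
$2\Phi(-|\Delta\mu|/2\sigma)$ — not that real tumors look like truncated
Gaussians. No scattering physics is simulated: the generator matches
observed DOP distributions, not their physical origin, and heavy-tailed
artifacts of fur/scar imaging are available only as an unvalidated option.

## Numerical choices

* Intensity floor: pixels with pair-total intensity ≤ 10⁻⁶ × the image
  maximum are invalid (`NA`, masked) — dark-pixel handling is unstated in
  the source, and silent division blowups are worse than a mask.
* Physical-realizability ($S_1^2+S_2^2+S_3^2 \le S_0^2$) violations from
  noise are flagged, never clipped; the S0 consistency cross-check
  (H+V vs ±45 vs R+L) warns and flags beyond 10⁻⁶ relative.
* Round-trip assertions use 10⁻⁹–10⁻¹⁰ absolute tolerances on order-1
  quantities; the 16×16 design inversion is exact linear algebra (`solve`),
  with a singular-scheme error naming the offending states.
* Thresholds are generated as `-1 + 0.05 * (1:39)`; tests that probe tie
  behaviour reproduce that exact floating-point expression rather than
  assuming 0.5 is on the grid.
* File formats: no TIFF codec is available in the supported installation,
  so images travel as plain CSV grids with JSON sidecars (metric,
  convention, valid-pixel counts), masks as PNG. The container types, not
  the codecs, carry the scientific contracts.

## Known limitations

* The mask is fluorescence-derived and unvalidated against histology; the
  statistics quantify *contrast*, not margin-delineation accuracy.
* The generator's i.i.d. pixels make bootstrap CIs honest but understate
  spatial correlation in real tissue, where effective sample sizes are
  smaller and CIs optimistic.
* The 16-state scheme and beam-splitter matrices of any real apparatus must
  be supplied by the user; defaults are the minimal scheme and identity
  correction.
* `estimate_transform` fits rigid/similarity models only; affine or
  projective distortion between modalities is not modelled.
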