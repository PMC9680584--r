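---
title: "Methods: non-iterative EPID dose calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-iterative EPID dose calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

An amorphous-silicon portal imager (EPID) mounted opposite the treatment
head sees every beam that traverses the patient, which makes it an
attractive transit dosimeter — except that its image is not dose. The panel
over-responds in small fields and under-responds in large ones, its
energy-dependent response changes with the amount of patient or phantom
material in the beam, and the vendor acquisition software flattens the
lateral image profile so that the true beam shape (including the "horns"
of a flattened clinical beam) is no longer visible in the gray values.

`epidcal` implements a non-iterative, purely measurement-based correction
chain that converts a raw portal image $I(x,y)$ with vendor pixel scaling
factor $s$ into absolute dose to water at the detector plane:

$$D_w^{f,d}(x,y) \;=\; N \,\frac{I^{f,d}(x,y)}{s}\; k_f \; k_d \;
k_{\mathrm{profile}}(x,y,d),$$

with

* $N$ — cross-calibration factor against an ionization chamber under
  reference conditions (field $f_{\mathrm{ref}} = 10\times10$ cm$^2$
  defined at the isocenter, no phantom, $d_{\mathrm{ref}} = 0$),
  $N = s_{\mathrm{ref}} D_w^{\mathrm{ref}}(0,0) / \bar I_{\mathrm{ref}}$,
  where $\bar I$ is the mean gray value in a 1 cm $\times$ 1 cm window at
  the beam axis;
* $k_f$ — field-size response correction, the ratio of dose-per-signal at
  the clinical field size to that at the reference field, measured at
  square fields of 4–26 cm side in 2 cm steps and interpolated linearly;
* $k_d$ — thickness response correction measured on a grid of four field
  sizes (5, 10, 15, 20 cm) times six RW3 thicknesses (0–20 cm in 4 cm
  steps); per field side a third-degree polynomial in $d$, constrained
  through $(0, 1)$, is fitted by least squares and field sizes in between
  are interpolated linearly;
* $k_{\mathrm{profile}}(x,y,d)$ — the pointwise ratio of the
  center-normalized relative dose profile (measured with a 2D
  ionization-chamber array at $f_{\max} = 15\times15$ cm$^2$) to the
  center-normalized portal image, stored per calibration thickness. For
  other field sizes the map is compressed or expanded laterally about the
  beam axis by $f_{\max}/f$; for other thicknesses it is interpolated
  linearly between the stored maps.

The clinical field size is estimated from the image itself: Otsu's
threshold on the gray-value histogram (256 bins after min–max
normalization, no smoothing), the axis-aligned bounding box of the mask,
and assignment of the *enclosing square* — the larger of the box width and
height — converted from detector to isocenter scale by the geometric
magnification SDD/SAD = 160/100 = 1.6. When an image carries its nominal
field size as metadata (the synthetic simulator records it), that value
takes precedence.

Both normalizations in the profile correction are deliberate: a literal
ratio of an absolute relative-dose profile to a raw image would carry the
absolute scale a second time. Here the beam-axis value of every stored map
is exactly 1 and the absolute scale lives solely in $N\,k_f\,k_d$.

# Two readings the measurement prescription leaves open

**Averaging window.** The averaging area for $\bar I$ is read as a
1 cm $\times$ 1 cm square at the detector plane (25 × 25 pixels at the
0.4 mm pitch); a window of 1 cm$^2$ side is dimensionally impossible. When
the rounded window parity cannot be centered exactly on the grid, the
window shifts half a pixel toward the origin — a fixed, documented
tie-break (`central_roi_mean()`).

**Forming the profile ratio.** The detector array delivers its profile on
a coarse grid (7 mm spacing by default); the portal image lives on the
fine pixel lattice. Upsampling the coarse profile bilinearly *before*
dividing injects large interpolation artifacts exactly at the field edge,
where the penumbra is steep relative to 7 mm — rings of several percent
to tens of percent that a correction claiming sub-percent edge accuracy
cannot carry. `build_profile_set()` therefore samples the portal image at
the coarse array positions, forms the ratio *there* (numerator and
denominator share the penumbra, which cancels), and interpolates the
smooth ratio to the full grid. The contract is unchanged: same inputs,
maps on the detector grid with beam-axis value 1. Where the normalized
portal signal is below `profile_floor` (default $10^{-3}$) the ratio is
undefined and set to 1 — no correction where there is no signal.

# Interpolation, tie-breaks and degenerate inputs

* Beam axis at the grid center, continuous index $(n+1)/2$ per axis
  (between the two central pixels on the even-sized panel). The "beam-axis
  sample" of any map is the bilinear value there; the "central lateral
  profile" is the bilinear profile at $y = 0$, i.e. the mean of the two
  central rows on an even grid.
* All grid resampling (coarse array → panel, lateral rescale, gamma
  subsampling) is bilinear with clamping to the boundary — monotone and
  artifact-free for ratio maps; constants are preserved exactly and
  support points reproduce exactly.
* Out-of-support lookups ($f < 4$ or $> 26$ cm for $k_f$, $f < 5$ or
  $> 20$ cm and $d > 20$ cm for $k_d$/$k_{\mathrm{profile}}$): clamp to
  the nearest support value with a warning by default; `out_of_range =
  "error"` raises instead.
* The $k_f$ entry at $f_{\mathrm{ref}}$ is forced to exactly 1 (it is 1
  by definition; measured values carry rounding noise), and the
  constrained cubic makes $k_d(\cdot, 0) = 1$ exact.
* Degenerate inputs error out explicitly: zero central ROI, zero beam-axis
  value in a profile pair, a constant image offered for field-size
  estimation, fewer than four thickness points per field side.
* Per-pixel thickness maps (e.g. projected from a 2D water-equivalent
  phantom through the divergent source geometry) evaluate $k_d$ and the
  thickness interpolation of $k_{\mathrm{profile}}$ pixelwise; the lateral
  rescale keeps the single enclosing-square field size. Projection uses
  nearest-neighbour sampling at the isocenter plane so that sharp
  material boundaries stay sharp and land at magnified positions.

# Gamma analysis

`compute_gamma()` implements the 2D global-normalization gamma index. For
each reference point above the low-dose threshold (10% of the global
reference maximum by default) it searches evaluated positions within
3 × DTA, sampling the evaluated map bilinearly at 1/3-pixel steps, and
minimizes $\sqrt{(\Delta D / (dd\% \cdot D_{\max}))^2 + (r/\mathrm{DTA})^2}$.
Offsets are visited in order of increasing distance with early
termination once the spatial term alone exceeds the worst current
minimum. Ties at the pass threshold are decided with a relative
$10^{-12}$ guard, so a uniform offset of exactly $dd\%$ counts as passing
(its gamma is exactly 1 up to round-off). The test suite pins the search
against an exhaustive brute-force oracle with independent interpolation
code. The commercial software used for the original validation is not
re-implemented and equivalence with it is not claimed; normalization,
threshold, search radius and subsampling are exposed parameters.

# The synthetic test bed

No measured data ship with the package. `generate_system()` builds a
seeded forward model of linac + phantom + EPID whose only contracts are
(a) qualitative agreement with the clinically observed behaviours and
(b) *exact invertibility* by the calibration it feeds:

$$D = D_0\, \mathrm{OF}(f)\, e^{-\mu_{\mathrm{eff}} d}\, P(u,v,d)\,
A_{\mathrm{pen}},\qquad
I = s\, \frac{D\, R_f(f)\, R_d(f,d)}{N_{\mathrm{sys}}\, F(u,v,d)}
(1+\varepsilon).$$

Choices, with units and defaults:

* $D_0 = 0.4$ Gy (≈1 cGy/MU at the isocenter scaled to the 160 cm
  detector distance), $\mu_{\mathrm{eff}} = 0.045$ cm$^{-1}$ (6 MV broad
  beam), $N_{\mathrm{sys}} = 8\times10^{-5}$ Gy per gray value (reference
  center gray value ≈ 5000).
* $1/R_f$ — the correction the calibration must find — is piecewise
  linear through the 2 cm calibration knots, the knots sampling
  $(f/10)^{0.05}$: over-response below 10 cm, under-response above, and a
  table measured at those knots recovers it exactly at *any* field size.
* $R_d = 1/k_d^{\mathrm{true}}$ with $k_d^{\mathrm{true}}$ an exact cubic
  in $d$ per field side (coefficients interpolated linearly in $f$), so
  the constrained cubic fit can recover it identically off-grid. The
  large-field values lie in the clinically reported 1.1–1.25 band over
  4–20 cm, small fields drift toward over-response with thickness.
* Horns $P = 1 + h(d) g(\rho)$ and flattening $F = 1 + \varphi(d)
  g(\rho)$ share field-normalized coordinates $u = x/(f_{\mathrm{det}}/2)$
  and a radial shape $g$ that is zero inside a flat core
  ($\rho \le 0.35$) and rises quadratically to the field edge. Sharing
  the normalized coordinates makes the lateral-rescale approximation of
  the profile correction *exact* for this generator (the resampling error
  is all that remains); the flat core keeps central ROI means equal to
  beam-axis values at the $10^{-12}$ level, so the table-recovery
  contract is clean. $h(0) = 0.06$, $\varphi(0) = 0.10$ (≈10% maximum
  EPID-vs-array profile deviation at $d=0$, matching the observed
  magnitude), both decaying with thickness.
* Penumbra: a compact-support smoothstep edge of 15 mm half-width at the
  detector plane (80–20% distance ≈ 9.7 mm, comparable to a magnified
  6 MV penumbra at 160 cm). Compact support keeps the field interior at
  exactly 1, so reference normalizations are not polluted by edge tails;
  aperture fields are convolved with the matching smoothstep-derivative
  kernel. A 0.2% transmission floor stands in for jaw/leaf leakage and
  keeps profile ratios well-defined off-field.
* Multiplicative Gaussian noise, sd 0.3% by default, one seeded stream
  per image. Calibration acquisitions average 4 frames
  (`generate_calibration_dataset(n_frames = 4)`) — the standard practice
  of averaging repeated calibration readings — while validation images
  are single-frame.

`generate_calibration_dataset()` reproduces the full calibration design
(reference pair; 12 field sizes; 4 × 6 thickness grid; 6 profile pairs at
$f_{\max}$ with the array profile on a 7 mm grid), and
`generate_imrt_aperture()` draws seeded unions of leaf-quantized
rectangular segments as IMRT stand-ins.

What the generator does *not* emulate: scatter kernels and off-axis
spectral shifts that break multiplicative separability, ghosting,
dose-rate dependence, memory effects, gantry-angle sag, and detector
aging. Passing tests on this bed therefore demonstrate that the
calibration chain inverts a system with exactly the modelled response
structure — not that it captures every non-separable effect of a physical
panel.

# Problem sizes and numerical tolerances in the tests

The unit and property tests run the full chain on a 128 × 128 panel
covering the same 41 cm side; the end-to-end validation suites (nine-field
IMRT gamma, three-density phantom, profile rescale) use 256 × 256, and the
gamma oracle comparison uses 32 × 32 maps at 2 mm spacing — sizes chosen
so the whole suite completes in about a minute on one core while keeping
every interpolation path (pixel pitch vs. 7 mm array spacing vs. penumbra
width) in a realistic ratio. Noise-free table recovery is asserted at
$10^{-6}$ relative; resampling-limited map comparisons at $10^{-3}$;
bit-exactness is asserted for archive round trips (JSON scalars are
written with 17 significant digits for that reason).

# Known limitations

* The profile correction for field sizes far from $f_{\max}$ relies
  entirely on the lateral-rescale approximation; on real data its error
  grows for small fields (the original validation reports 1.6% at
  5 × 5 cm$^2$). Additional profile sets at small/medium/large fields
  would reduce it, at the cost of more calibration measurements.
* Outside the calibrated field the stored profile ratio carries
  sub-coarse-grid structure from the penumbra of the calibration field;
  it is meaningless there and clamped to the low-signal floor behaviour.
* DICOM RTIMAGE input is not supported in this build (no DICOM reader in
  the R dependency stack); 16-bit TIFF with a JSON sidecar and plain-text
  grids are the canonical formats.
* The gamma module is 2D, global normalization only.
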