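# epidcal — non-iterative dose calibration for electronic portal imagers

Electronic portal imaging devices (EPIDs) sit opposite the treatment head
of a linac and image every beam that has traversed the patient, which
makes them attractive transit dosimeters for in-vivo verification and
patient-specific QA. Their raw images are not dose, though: the panel
over-responds in small fields and under-responds in large ones, its
energy-dependent response shifts with the irradiated patient/phantom
thickness (beam hardening), and the vendor software flattens the lateral
profile so the true beam shape is lost.

`epidcal` implements a non-iterative, measurement-based calibration that
converts a portal image `I(x, y)` with vendor pixel scaling factor `s`
into absolute dose to water at the detector plane:

```
D_w(x, y) = N · I(x, y)/s · k_f(f) · k_d(f, d) · k_profile(x, y, d)
```

* `N` — cross-calibration factor against an ionization chamber at the
  reference conditions (10 × 10 cm² field, no phantom), from the mean
  gray value in a 1 cm × 1 cm central window;
* `k_f` — field-size response correction, measured at square fields of
  4–26 cm (2 cm steps), linearly interpolated; the field size is
  estimated from the image with Otsu's method and the enclosing-square
  rule, or taken from image metadata;
* `k_d` — phantom-thickness response correction on a grid of 4 field
  sizes × 6 RW3 thicknesses (0–20 cm), fitted per field side with a
  third-degree polynomial constrained through (0, 1);
* `k_profile` — ratio of the center-normalized detector-array profile to
  the center-normalized portal image at `f_max` = 15 × 15 cm², per
  thickness; laterally compressed/expanded to other field sizes and
  interpolated in thickness, including a per-pixel thickness mode for
  inhomogeneous phantoms.

A 2D gamma-index module (global normalization, e.g. 3%/3 mm) validates
converted dose maps, and a seeded synthetic linac+EPID forward model
generates the complete calibration fixture set so the whole chain is
testable without measured data. Geometry defaults follow a fixed-SDD
a-Si panel: SDD 160 cm, SAD 100 cm (magnification 1.6), 1024 × 1024
elements over 41 × 41 cm² (0.4 mm pitch).

See the methods vignette (`vignettes/epid-dose-calibration.Rmd`) for the
model, its assumptions and the design decisions.

## Worked example

Calibrate a synthetic system from its fixture set, convert a portal image
taken through 8 cm of water-equivalent slab at a 12 × 12 cm² field, and
compare against the ground-truth dose:

```r
library(epidcal)

det    <- detector_spec(256, 256, 410 / 256, 41)   # desk-scale panel
linac  <- generate_system(seed = 42, detector = det)
model  <- build_calibration_model(generate_calibration_dataset(linac))
model
#> EPID dose calibration model
#>   N = 8.00234e-05 Gy per gray-value unit (f_ref 10 cm, d_ref 0 cm, s_ref 1)
#>   k_f support: 4 - 26 cm (12 points)
#>   k_d support: fields {5, 10, 15, 20} cm, thickness 0 - 20 cm
#>   k_profile: f_max 15 cm, 6 thickness maps on 256 x 256 grid

img  <- simulate_epid_image(linac, field = 12, phantom = slab_stack(8, 1),
                            noise_seed = 7)
dose <- convert_image_to_dose(model, img)
dose
#> Dose map 256 x 256 Gy, range [0.0004993, 0.3014], axis 0.283186

truth <- simulate_true_dose(linac, field = 12, phantom = slab_stack(8, 1))
compute_gamma(truth, dose, gamma_params(3, 3))
#> Gamma analysis (3%, 3 mm, global, 10% threshold)
#>   evaluated points: 17272; pass rate: 100.00%; mean gamma: 0.084
```

The beam-axis dose 0.283 Gy is the reference dose 0.4 Gy scaled by the
12 cm output factor and the 8 cm attenuation (`0.4 · 1.015 · e^(-0.045·8)`);
the gamma analysis says every evaluated pixel of the converted image
agrees with the ground truth within 3% of the dose maximum or 3 mm.

## Command line

A thin launcher (`inst/exec/epidcal`, or `epid_cli()` from R) covers the
shell workflow:

```sh
epidcal simulate  --seed 42 --out bundle/ --n 256
epidcal calibrate --bundle bundle/ --out model/
epidcal convert   --model model/ --image bundle/validation/imrt.tif --out dose.txt
epidcal gamma     --ref bundle/validation/imrt_true_dose.txt --eval dose.txt \
                  --dd 3 --dta 3 --out gamma.json
```

Portal images travel as 16-bit TIFF with a JSON sidecar (pixel scaling
factor, geometry, metadata) or as plain-text grids; chamber readings as
CSV; models as a JSON manifest plus full-precision text grids
(round-trip exact).

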