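---
title: "Methods: regression-based vein visualization from RGB skin images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression-based vein visualization from RGB skin images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Subsurface veins are nearly invisible in an RGB photograph of skin: vein
and non-vein pixels differ by only a few digital numbers. They differ
strongly, however, in one biophysical parameter — the volume fraction of
blood in the dermis. `veinviz` inverts the color-formation process to
map each pixel of an ordinary RGB image to estimates of melanin
concentration $C_m$ (epidermis) and blood concentration $C_b$ (dermis);
the spatial distribution of $C_b$ renders the vein pattern. The chain
is:

1. **Light correction** — an entropy-optimal gamma exponent removes
   global exposure distortion.
2. **Shading removal** — iterated bilateral filtering in the log domain
   splits each channel into a smooth illumination-and-geometry layer and
   a high-frequency pigment-detail layer; the detail layer is kept and a
   flat base color restored.
3. **Wiener spectral reconstruction** — the 3-vector RGB observation is
   expanded to a 31-band diffuse reflectance spectrum (400–700 nm at
   10 nm) using a second-moment reflectance prior.
4. **Two-stage inverse model** — per pixel, absorbance
   $A(\lambda) = -\log_{10} r(\lambda)$ is regressed on chromophore
   extinction spectra (modified Beer–Lambert), and the regression
   coefficients are mapped to $(C_m, C_b)$ through a trained cubic
   polynomial.
5. **Vein extraction** — a 16-filter Gabor bank, contrast stretch, Otsu
   binarization and small-component removal produce a binary vein mask,
   scored by accuracy/precision/recall/F1 against ground truth.

A Monte Carlo photon-transport model of three-layer skin supplies both
the reflectance prior of step 3 and the training pairs of step 4, so
the package is self-contained: no measured spectra or camera data are
required.

## Color formation and its inverse

A camera pixel integrates illuminant, sensor response and tissue
reflectance. Under the narrow-band (Dirac) sensor assumption the
observation is linear in the reflectance spectrum,
$$ I = S\,E\,r = F r, $$
with $S$ the $3\times 31$ stacked response curves, $E$ the diagonal
illuminant and $r$ the per-pixel diffuse reflectance. Inverting
$3 \to 31$ dimensions is ill-posed; the linear minimum-mean-squared-
error solution given a second-moment prior
$\langle r r^\top \rangle$ is the Wiener estimator
$$ W = \langle rr^\top\rangle F^\top
       \left(F \langle rr^\top\rangle F^\top\right)^{-1},
  \qquad \tilde r = W I. $$
$W F$ acts as the identity on the span of the prior's top three
eigenvectors, so reconstruction is exact for spectra inside the
dominant prior subspace and shrinks toward it elsewhere. Reconstructed
reflectance is clipped to $[10^{-4}, 1]$ (the inverse model takes
logarithms); the clip count is reported in the cube's provenance.

The prior defaults to the Monte Carlo training spectra. A measured
reflectance database can be substituted through `build_prior()` on any
spectra collection.

**Exposure convention.** `system_matrix(normalize_to = spectra)` scales
$F$ so the brightest prior spectrum maps to a maximum channel value of
1. A residual per-image scalar gain (unknown irradiance and the mean
shading constant) is fitted as the ratio of the masked gray median to
the rendered-prior gray median. This convention deliberately cannot
distinguish a uniformly dark subject from underexposure — a genuine
ambiguity of single-image radiometry — so absolute concentration maps
carry a subject-dependent scale bias while rank ordering, and therefore
vein contrast, is preserved.

## The Monte Carlo forward model

Skin is modeled as three homogeneous plane-parallel layers:

| layer      | n    | d (cm) | absorption                               |
|------------|------|--------|------------------------------------------|
| epidermis  | 1.37 | 0.006  | $C_m\,\mu_{a,\mathrm{mel}} + (1-C_m)\,\mu_{a,\mathrm{base}}$ |
| dermis     | 1.37 | 0.09   | $C_b\,\mu_{a,\mathrm{blood}} + (1-C_b)\,\mu_{a,\mathrm{base}}$ |
| hypodermis | 1.44 | 0.03   | fixed fixture curve                      |

Scattering coefficients, anisotropy ($g = 0.62 + 2.9\times10^{-4}
\lambda$ for epidermis/dermis) and the baseline absorption follow
standard literature curves bundled as CSV fixtures
(`inst/extdata/manifest.json` documents each file). Whole-blood
absorption mixes oxy- and deoxyhemoglobin extinction at a configurable
oxygen saturation, default 75% (venous-dominant), at 150 g/L hemoglobin.
Melanin absorption uses the $\lambda^{-3.33}$ interior-melanosome power
law. The bundled camera model is three Gaussian responses
(peaks 610/540/460 nm, FWHM 60 nm); under the narrow-band assumption
above, results depend mainly on the peak positions, and measured curves
can be substituted via the fixture directory hook.

Transport is the standard hop–drop–spin walk: free path
$-\ln\xi/(\mu_a+\mu_s)$, Henyey–Greenstein scattering, Fresnel
reflection/refraction at index mismatches, absorption by fractional
weight drop, Russian roulette below weight $10^{-4}$ with survival
probability 0.1. Two numerical choices are worth noting:

* **Exact weight accounting.** The roulette survivor boost is recorded
  as *negative* absorption, so specular + diffuse + transmitted +
  absorbed equals the launched weight to floating-point precision on
  every run, not merely in expectation.
* **Order-independent streams.** Each photon's RNG stream is seeded by
  hashing (seed, band, photon index), so a run is bit-reproducible
  regardless of how work is chunked.

The simulator reproduces the published benchmark slab
($\mu_a = 10\,\mathrm{cm}^{-1}$, $\mu_s = 90\,\mathrm{cm}^{-1}$,
$g = 0.75$, matched index, $d = 0.02$ cm: total diffuse reflectance
0.0974) within Monte Carlo error.

The training dataset covers $C_m \in [1.3\%, 43\%]$ and
$C_b \in [0.1\%, 7\%]$ on a uniform lattice; the full design is
$50\times50 = 2500$ pairs. For desk-scale work the package defaults to
$10^5$ photons per band; the validation suite trains on a reduced
$10\times10$ lattice at $10^5$ photons per band and uses an $8\times8$
lattice at $5\times10^3$ photons for cheap behavioural tests. These
sizes are the package's chosen operating points; the simulation scales
to the full design via `build_training_grid(50, 50, ...)`, which also
supports checkpoint files for resumable runs.

## The two-stage inverse model

Stage one fits, per spectrum, the modified Beer–Lambert regression
$$ A(\lambda) = a_m\,\varepsilon_m(\lambda) + a_{ob}\,\varepsilon_{ob}(\lambda)
   + a_{db}\,\varepsilon_{db}(\lambda) + a_0 $$
by ordinary least squares. The coefficients absorb the unknown mean
path lengths in each layer; the intercept absorbs scattering loss. The
fit is restricted to 500–600 nm, where the oxy/deoxy extinction spectra
differ most and where the single-path-length approximation holds best;
the same spectra fitted over the full 400–700 nm range give a visibly
lower $R^2$ (the Soret-band absorbance saturates and the effective path
length collapses, breaking linearity). `scripts/acceptance.R`
recomputes both means from a fresh simulation.

Stage two expands $(a_m, a_{tb} = a_{ob}+a_{db}, a_0)$ into the fixed
14-term cubic feature vector and solves two linear least-squares
problems for the weight vectors mapping features to $C_m$ and $C_b$.
Because the raw cubic features span roughly fifteen decades, the design
matrix is column-equilibrated before a QR solve — an exact
reparametrization that avoids the accuracy loss of normal equations at
this conditioning. Oxygen saturation is not an output: only the total
blood coefficient enters the feature vector. Concentrations are kept in
volume fractions internally (0.10 means 10%). Predictions are not
clipped to the training range by default, since out-of-range values
carry vein contrast; a display clip is available.

Per-pixel application uses the same 500–600 nm band at 10 nm by
default; `pipeline_config(subgrid_step_nm = 20)` switches to 20 nm
spacing for faster application at slightly reduced stability.

## Preprocessing details

**Gamma.** $\gamma^\* = -1/\operatorname{mean}(\ln u)$ over masked
gray pixels maximizes the differential entropy of the transformed
image. Zero pixels are clamped to 1/255 before the log. The histogram
version of the entropy criterion is extremely flat near its maximum,
so a brute-force 256-bin scan lands within a few thousandths of
$\gamma^\*$ — equal criterion value, slightly different argmax; the
test suite asserts both notions of agreement. The same exponent is
applied to all three channels to avoid hue distortion.

**Shading.** Channels are scaled to [0, 255], floored at 1 and
log-transformed. The bilateral filter (spatial sigma 5% of the shorter
image side; range sigma 5% of the current input's masked maximum,
recomputed each pass; window truncated at $3\sigma_1$) is applied
`n_iter = 5` times — the decomposition stabilizes within a few passes
at these sigmas. Small-amplitude high-frequency pigment detail is
averaged out of the base layer while smooth shading gradients remain
in it; the corrected image is the detail layer plus the masked mean of
the base layer. Masked-out pixels pass through untouched, and the two
log layers sum to the scaled input exactly by construction.

## Vein extraction

Sixteen even-symmetric Gabor kernels (2 scales, $\sigma = 2, 4$ px,
carrier wavelength $4\sigma$, aspect 0.5; 8 orientations over
$[0,\pi)$) are applied to the inverted blood map (veins dark); the
maximum response over the bank is contrast-stretched inside the skin
region, thresholded by Otsu's method computed over masked values only,
and components below 50 px are discarded. The 2×8 factorization and
the binarization recipe are package choices — the extraction literature
this follows states "enhanced and binarized" without parameters — and
all are exposed as arguments. Ground-truth masks from NIR-like images
are produced by the identical extractor so comparisons are
apples-to-apples.

## The phantom generator

`phantom_spec()` / `render_phantom()` synthesize skin images with known
ground truth: smooth background $(C_m, C_b)$ fields, tube-shaped veins
(smooth random-walk centerlines, width 4–10 px, elevated $C_b$),
multiplicative shading (ramp or spotlight), acquisition gamma, 8-bit
quantization and additive sensor noise (default 1.5 DN). Reflectance
comes from bilinear interpolation on the Monte Carlo lattice — running
the full MC per pixel is not desk-scale — and RGB from the same system
matrix the pipeline inverts.

Two generator choices deserve justification:

* **Auto-exposure.** Before gamma distortion the linear image is scaled
  so the geometric mean of its gray values is $e^{-1}$ — exactly the
  exposure at which the entropy-optimal exponent is 1. This emulates
  camera auto-exposure and makes the phantom family consistent with the
  correction criterion: a distortion-free phantom needs no correction,
  and a gamma-distorted one is restored by $\gamma^\* \approx
  \gamma_\mathrm{true}$.
* **The evaluation batch.** `phantom_batch(10)` treats illumination
  quality as a single latent factor: the worst-lit subject is both dim
  (gamma 0.5; median skin brightness ≈ 1/8 of full scale) and strongly
  shaded (ramp depth 0.5), the best is well exposed (gamma 1.0, depth
  0.2). Captures dimmer than gamma 0.5 were excluded as
  quantization-ruined: at gamma 0.45, correction with the *true*
  exponent still recovers only ~0.19 recall, because the vein contrast
  no longer survives 8-bit quantization. Within the batch, light
  correction is roughly neutral on well-exposed members and decisive on
  dim ones — the uncorrected inverse model's cubic map is evaluated far
  outside its training coefficient range and folds over.

What the phantoms do **not** emulate: hair, skin texture, specular
highlights (the optical model assumes a Lambertian surface), spatially
varying illuminant color, 3-D vessel depth, or camera noise beyond
additive Gaussian. Passing the synthetic suite therefore demonstrates
internal consistency of the optical chain and robustness to exposure,
shading, quantization and mild noise — not performance on real skin.

## Known limitations

* Absolute $(C_m, C_b)$ values inherit the exposure-convention bias
  described above; treat maps as relative within an image.
* The forward model is a homogeneous-layer stack: a "vein" is emulated
  as locally elevated dermal blood fraction, not a discrete cylindrical
  vessel at depth.
* The Gaussian camera model is a stand-in; for quantitative work with
  a real camera, substitute measured response curves.
* Hemoglobin extinction fixtures are transcribed literature
  compilations at 10 nm resolution; small digitization differences
  shift the absolute $R^2$ statistics by a few thousandths.
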