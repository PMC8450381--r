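# veinviz

Vein visualization from ordinary RGB skin images, for venipuncture
assistance and the study of subsurface ("feeder") veins — no infrared
hardware required.

Veins are nearly invisible in a photograph: vein and skin pixels differ
by a few digital numbers. They differ strongly in one biophysical
parameter, the dermal blood volume fraction *C<sub>b</sub>*. `veinviz`
inverts the color-formation process per pixel:

1. **Preprocess** — entropy-optimal gamma correction
   (γ\* = −1 / mean ln *u*) and shading removal by iterated bilateral
   decomposition in the log domain.
2. **Wiener spectral reconstruction** — the RGB triplet *I* = *F r*
   (with *F* = *S E* the camera–illuminant system matrix) is expanded to
   a 31-band reflectance spectrum via
   *W* = ⟨*rr*ᵀ⟩*F*ᵀ(*F*⟨*rr*ᵀ⟩*F*ᵀ)⁻¹.
3. **Inverse model** — absorbance *A*(λ) = −log₁₀ *r*(λ) over
   500–600 nm is regressed on melanin / oxy- / deoxyhemoglobin
   extinction spectra (modified Beer–Lambert law); a trained cubic map
   takes the regression coefficients to melanin and blood volume
   fractions (*C<sub>m</sub>*, *C<sub>b</sub>*).
4. **Vein extraction** — a 16-filter Gabor bank, Otsu binarization and
   small-component removal turn the blood map into a binary vein
   pattern, scored by accuracy / precision / recall / F1.

The reflectance prior of step 2 and the training pairs of step 3 come
from a built-in MCML-style Monte Carlo simulation of three-layer skin
(epidermis / dermis / hypodermis; Henyey–Greenstein scattering, Fresnel
boundaries, Russian roulette), so the package is fully self-contained.
A phantom generator synthesizes RGB skin images with known ground truth
for end-to-end validation. See the methods vignette
(`vignettes/veinviz-methods.Rmd`) for the model, parameter defaults and
design rationale.

## Worked example

Simulate a small training lattice, build the model assets, render a
shaded and gamma-distorted phantom, and run the full chain:

```r
library(veinviz)

tg     <- build_training_grid(8, 8, photon_config(5e3, seed = 11))
assets <- pipeline_assets(tg)

ph <- render_phantom(phantom_spec(gamma_true = 0.7, seed = 3),
                     assets$F, assets$lookup)
bundle <- run_pipeline(ph$rgb, assets)

bundle$provenance$gamma_star
#> [1] 0.7012492
score_veins(bundle$vein_mask, ph$truth_mask, ph$rgb$mask)
#> <vein_score TP=679 FP=20 FN=89 TN=11500 acc=0.9911 P=0.9714 R=0.8841 F1=0.9257>
```

The estimated restoration exponent (0.701) recovers the phantom's
acquisition gamma (0.7), and the extracted vein mask overlaps the
ground-truth vein with F1 ≈ 0.93. `bundle$cb_map` holds the blood map,
`bundle$visualization` the NIR-style rendering (high blood = dark), and
`write_bundle(bundle, dir)` persists all artifacts with provenance.

A command-line interface wraps the same functions (the script is
installed at `system.file("exec", "veinviz", package = "veinviz")`;
put it on your PATH or call it via Rscript):

```sh
veinviz simulate-grid --out grid.csv --nm 10 --nb 10 --photons 1e5
veinviz run --image arm.png --grid grid.csv --out-dir out/
veinviz evaluate --images imgs/ --truths nir/ --grid grid.csv --out metrics.csv
```

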