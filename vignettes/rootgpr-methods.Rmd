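---
title: "Methods: simulating and inverting GPR scans of roots in layered heterogeneous soil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inverting GPR scans of roots in layered heterogeneous soil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ground-penetrating radar (GPR) images the shallow subsurface by emitting
electromagnetic pulses and recording their reflections.  For root
phenotyping the quantity of interest is the map of relative permittivity
$\epsilon'(x, z)$: roots (water-rich) contrast with soil, and the soil's
own permittivity tracks moisture.  Recovering $\epsilon'$ from a B-scan
is a nonlinear inverse problem; `rootgpr` attacks it with a learned
image-to-image inversion network trained entirely on synthetic data that
the package itself manufactures.  The pipeline is:

1. **Scene generation** — randomized three-layer heterogeneous soil with
   buried root-like scatterers.
2. **Dielectric modelling** — per-cell complex permittivity from the
   Peplinski soil mixing model.
3. **Forward simulation** — a 2-D FDTD Maxwell solver produces the
   B-scan a surface survey would record.
4. **Preprocessing** — background removal, time gain, normalization,
   resizing, and construction of the two training labels.
5. **Inversion network** — a dual-branch pyramidal-convolution /
   vision-transformer network with an edge-inversion auxiliary task.
6. **Training and transfer** — AdamW with cosine annealing, an 8:1:1
   split, and a staged transfer-learning protocol.

# Soil dielectrics

A soil's complex relative permittivity is written
$\epsilon = \epsilon' - j\epsilon''$, and its conductivity follows from
the loss factor as $\sigma = 0.05563\, f_{\mathrm{GHz}}\, \epsilon''$
(S/m).  The mixing model combines four ingredients:

* the solid-grain permittivity
  $\epsilon_s = (1.01 + 0.44\rho_s)^2 - 0.062$ with particle density
  $\rho_s$ (g/cm^3^);
* single-relaxation Debye water,
  $\epsilon_w = \epsilon_{w,\infty} +
  (\epsilon_{w,s} - \epsilon_{w,\infty}) / (1 + j\omega t_{0,w})$, with
  $\epsilon_{w,\infty} = 4.9$ and temperature-dependent
  $\epsilon_{w,s}(T)$ and $t_{0,w}(T)$ from the standard polynomial
  fits (giving $t_{0,w} \approx 9.3$ ps at 20 °C);
* the texture-dependent exponents
  $\beta' = 1.2748 - 0.519 S - 0.152 C$ and
  $\beta'' = 1.33797 - 0.603 S - 0.166 C$, where $S$ and $C$ are the
  sand and clay **mass fractions in [0, 1]** — using 0–100 percentages
  would drive $\beta'$ negative and nonphysical, so the fraction
  convention of the original Peplinski formulation is used;
* the effective conductivity
  $\sigma_f = 0.0467 + 0.2204\rho_b - 0.411 S + 0.6614 C$ in the
  0.3–1.3 GHz band (a different fit applies above 1.4 GHz).

The real part uses the power-law mixing form with exponent $a = 0.65$
and, below 1.3 GHz, the linear correction
$\epsilon' \mapsto 1.15\epsilon' - 0.68$.  The imaginary part combines
the Debye loss with the conductive term scaled by
$(\rho_s - \rho_b)/(\rho_s f_w)$; at $f_w = 0$ it vanishes.  Defaults
$\rho_b = 1.5$ and $\rho_s = 2.66$ g/cm^3^ are the customary field
values; both are configurable in `soil_state()`.

Soil texture classes follow the 12-class international (ISSS) triangle.
The class boundaries are not tabulated in a single canonical source at
full precision, so the package ships them as a versioned JSON rule table
(`inst/extdata/isss_texture_classes.json`): clay bands at 15/25/45/65 %,
a silt threshold at 45 % and sand thresholds at 55/85/90 %.  Rules are
evaluated in a fixed order and the first match wins, which is the
documented tie-break for boundary compositions.  On a dense 1 % grid the
rules partition the simplex completely into exactly 12 classes.

# Scene generation

Scenes emulate a 1.54 m wide, 0.6 m deep survey cell at `dx = 2.5` mm.
Three layers with fixed conditions (moisture 5–10 % at 20 °C, 10–13 % at
17 °C, 13–15 % at 15 °C, shallow to deep) each receive a random ISSS
texture class and five random composition variants inside that class.
The variants are arranged spatially as a smoothed Gaussian random field
thresholded at its quantiles into five contiguous-patch regions
(default correlation length 0.05 m) — the within-layer arrangement is a
modelling choice, as only the existence of five variants per layer is
prescribed; the thresholded-field construction mimics the fractal soil
boxes of standard GPR simulators.  Nominal layer boundaries sit at
0.20 m and 0.40 m and are jittered by ±0.03 m per scene; these depths
are likewise package defaults (chosen so that the scatterer depth band
0.20–0.30 m falls in layer 2), not measured values.

Scatterers take one of four shapes — circle, semicircle, rectangle,
triangle — with circumradius 5–10 cm (rectangles 10–15 cm × 4–6 cm),
uniform rotation, center depth 0.20–0.30 m and relative permittivity
uniform in 2–32.  The shape list is reconciled as *rectangles* because
side-length ranges are only given for rectangles.  Scatterer
conductivity defaults to 0.001 S/m (configurable).  Scenes come in three
modes (`single`, `two_separate`, `two_overlap`); the two-scatterer modes
enforce disjoint or intersecting rasterized footprints by bounded
rejection.

Rasterization is cell-centered (x rightward, z downward, half-open cell
intervals); the later scatterer wins where footprints overlap, and the
permittivity map is the $\epsilon'$ channel of the material grid.

# Forward FDTD simulation

The solver is a 2-D TM-mode (E~z~, H~x~, H~y~) Yee scheme with
split-field PML absorbing boundaries (10 cells, quartic grading,
PML strength scaled by $\sqrt{\epsilon_r}$ of the local medium) and a
0.10 m air layer above the soil.  A 2-D solve is chosen for desk-scale
tractability; the `write_gprmax()` exporter provides a 3-D
cross-validation path through an external simulator.  The time step
sits exactly at the 2-D Courant limit $\Delta t = dx/(c\sqrt{2})$,
which at `dx = 2.5` mm reproduces the survey sampling interval
$5.89664 \times 10^{-12}$ s; the energy-conservation test shows the
scheme is stable there (the staggered-time energy oscillates within a
step but its envelope does not grow).

The source is a Ricker wavelet (center frequency 900 MHz, amplitude 1,
delay $t_0 = 1.5/f_c$ so the waveform starts near zero), injected as an
*additive* (soft) point source rather than a clamped hard source: a
clamped node acts as a point scatterer after switch-off and would
pollute the record that the PML-quality check requires to be clean.
The receiver is a point E~z~ probe.  Both sit 0.005 m above the surface,
0.14 m apart, and slide together: emissions at
$x_k = 0.025 + 0.015k$ m for $x_k < 1.375$ m give exactly 90 traces
(the 1.375 m end position is read as the final arrival, not an
emission).  The time window is 20 ns.  Antenna geometry is modelled at
this point-source level of fidelity only; no bow-tie model is included.

Materials are evaluated at the 900 MHz center frequency and held
non-dispersive during stepping (no Debye-pole FDTD); soil loss enters
through the static conductivity term.

# Preprocessing and labels

Raw B-scans pass through exactly four stages, in order: (1) per-row
mean-trace subtraction (background removal), (2) exponential time gain
$\exp(10^8\, i\, \Delta t)$ at the record's **native** sampling interval
(the synthetic $5.89664\times 10^{-12}$ s, or 10 ns/512 for emulated
measured records), (3) min–max normalization to [0, 1], (4)
nearest-neighbour resize to 128 × 128 (half-open cell mapping, boundary
ties toward the smaller index, for bit-exact reproducibility).  A
regression test pins this order: swapping gain and background removal
changes the output.

The permittivity label uses a **global** fixed scale
$(\epsilon' - 1)/(32 - 1)$ clipped to [0, 1], not per-image min–max:
per-image scaling would destroy comparability of predicted permittivity
across samples, and the normalization constants are stored with each
sample so labels invert back to $\epsilon'$.  The edge label marks cells
whose forward difference to the right or lower neighbour of the resized
normalized map exceeds 0.02, giving single-cell-wide closed contours;
the operator and threshold are configurable because only "edges labelled
1" is prescribed.

# The inversion network

Both branches are encoder → feature extractor → decoder chains over
128 × 128 single-channel images.  The encoder is a 3 × 3 convolution +
batch-norm + ReLU; decoders are a 3 × 3 convolution + sigmoid (range
(0, 1), one channel).

**PyConvFEB** runs three parallel convolutions — 3 × 3 with 1 group,
5 × 5 with 4 groups, 7 × 7 with 8 groups — concatenates them, fuses with
a 3 × 3 convolution + BN + ReLU to the stage width, and adds a CBAM
attention output residually.  Each parallel branch emits half the stage
width (so the concatenation is 1.5 × the width before fusion); this
split is a design choice, as only the kernel/group plan is fixed.  CBAM
follows its standard form: channel attention from average- and
max-pooled descriptors through a shared bottleneck MLP (reduction 16),
then spatial attention through a 7 × 7 convolution.

**ViTFEB** downsamples 256 × 128 × 128 features to 256 × 32 × 32 with a
serial 7 × 7 (stride 2), two 3 × 3, 5 × 5 (stride 2), three 3 × 3
convolution chain, tokenizes the 32 × 32 map as 1024 one-pixel patches
of dimension 256, adds a learned positional embedding (the embedding
type is unstated; learned is the common ViT choice), runs two ViT
blocks of two transformer encoder layers each (pre-LN, 16 heads,
MLP width 512) — the "two blocks of two encoders" reading, i.e. four
encoder layers total — adds the transformer output back to the 32 × 32
map, and restores 128 × 128 with a 6 × 6 deconvolution, three 3 × 3
convolutions and a 4 × 4 deconvolution, finishing with a CBAM residual.

The auxiliary branch uses five PyConvFEBs with widths
(64, 128, 128, 64, 32); its stages 1, 2, 4 and 5 are channel-
concatenated into main stages 1, 2, 4 and 5.  The ViTFEB therefore sits
third in the main branch — the one stage without a skip.  Main widths
are encoder 64, then 64, 256, (ViTFEB 256), 128, 96: the first three are
forced by the 256-channel ViTFEB interface, while the last two are
calibrated so the total trainable parameter count rounds to the
published 18.9 million.  `pyvitenet_config(edge_branch = FALSE)` builds
the main-branch-only ablation.

Because no deep-learning backend is available to R in this toolchain,
the package includes a compact reverse-mode engine (conv/deconv via
C++ im2col + BLAS, batch-norm, CBAM, multi-head self-attention,
LayerNorm, GELU, AdamW); every layer's backward pass is verified against
central-difference numerical gradients at about 1e-10 relative error.

# Training, metrics, transfer

The loss is $\alpha\,\mathrm{MSE}(\text{perm}) +
\beta\,\mathrm{MSE}(\text{edge})$ with $\alpha = 1$, $\beta = 0.01$;
a near-unity $\beta$ lets the easier auxiliary task dominate.  Training
uses AdamW (decoupled weight decay 0.01 on weight matrices only),
initial learning rate 5e-4, cosine annealing to zero over the run with
no restarts, batch size 64, 150 epochs ("iterations" is read as epochs —
150 optimizer steps could not traverse a 16,000-sample training set at
batch 64), no early stopping, best-validation checkpointing, and a
seed-deterministic 8:1:1 scene-level split.

Metrics are computed in the normalized [0, 1] label space and rescaled
only for display (MSE × 10^−4^, MAE × 10^−2^).  SSIM uses **global**
per-image statistics with $c_1 = 0.01$, $c_2 = 0.03$ — the printed form
has no sliding window — so identical images score exactly 1; an 11 × 11
windowed variant is available behind the `window` argument.  Lower
MSE/MAE and higher SSIM are better.

`transfer_pipeline()` chains fine-tuning stages with weight carry-over
(broad synthetic → site-matched synthetic → measured data in the
reference protocol, sizes 20,000 → 2,000 → measured); any number of
stages ≥ 1 is valid, so skipping the matched stage is a two-stage
configuration.  Checkpoints embed the architecture configuration and
refuse to load into a different architecture.

# Numerical choices and problem sizes

* Grid: cell-centered, 0-based half-open cells; `dx = 2.5` mm default.
* FDTD: split-field PML, 10 cells, quartic grading, reflection target
  1e-7; instability (non-finite fields) aborts with the offending step.
* Nearest-neighbour ties go to the smaller index; min–max normalization
  errors on constant input; background removal requires ≥ 2 traces.
* The test suite and examples run the pipeline at a reduced scale
  (`reduced_sim_config()`: 0.60 × 0.50 m domain at 10 mm, 16 traces,
  12 ns window, 32 × 32 images, width-16 network): every code path is
  identical to the full-scale configuration, only sizes differ.  The
  package's own choice of desk-scale problem sizes keeps a complete
  generate–simulate–train cycle in minutes on one CPU.
* The desk-scale learning demonstration (64 scenes, 20 epochs) trains
  with learning rate 2e-3, batch size 4 and edge weight β = 1: within a
  20-epoch budget the auxiliary head receives too little gradient at the
  full-scale β = 0.01 to move off its initialization, so the
  demonstration weights the two tasks equally.  β = 0.01 remains the
  recommended full-scale training weight.
* Datasets persist via RDS; scenes serialize losslessly to JSON.

# What the synthetic data does and does not show

The generator reproduces the stated survey geometry, layered moisture /
temperature structure, ISSS texture diversity, intra-layer
heterogeneity and scatterer statistics.  It does not model antenna
radiation patterns, 3-D scattering, dispersive (frequency-dependent)
soil response, surface roughness or vegetation clutter, measurement
noise, or realistic branching root morphologies.  Tests passing on this
data demonstrate that the pipeline and network behave as specified —
not that a model trained here transfers to field records; that is what
the staged transfer protocol is for, and it requires measured data.

# Known limitations

* The 2-D TM solve approximates a 3-D survey; amplitudes (and thus any
  amplitude-sensitive inversion detail) differ from 3-D reality more
  than travel times do.
* Full-scale training (20,000 simulations, 150 epochs at 128 × 128)
  is far beyond a single-CPU R session; the package demonstrates
  learning at reduced scale and provides the full-scale configuration
  as defaults.
* The water Debye fits give 9.28 ps at 20 °C against the commonly
  quoted ≈ 9.23 ps; the published polynomial fits are used unmodified.
* ISSS class boundaries at 0.1 % precision vary slightly between
  published renderings of the triangle; the shipped table is versioned
  so alternative boundary sets can be swapped in.
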