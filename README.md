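# rootgpr

Synthetic ground-penetrating radar (GPR) imaging of tree roots in layered
heterogeneous soil: an end-to-end R pipeline that manufactures physically
simulated training data and learns to invert B-scans into subsurface
permittivity maps.

GPR surveys detect roots non-destructively, but turning a recorded B-scan
(time sample × antenna position) into the permittivity map
ε′(x, z) that reveals root position, shape and water status is a hard
nonlinear inverse problem.  `rootgpr` is for researchers in root
phenotyping, precision agriculture and near-surface geophysics who want a
fully self-contained, scriptable version of the learned-inversion
approach: every stage from soil physics to network training is in the
package, so the whole chain is reproducible from a seed.

## What is inside

* **Soil dielectrics** — the Peplinski mixing model: complex relative
  permittivity ε = ε′ − jε″ and conductivity
  σ = 0.05563 f_GHz ε″ of moist soil from texture (sand/clay mass
  fractions), densities, volumetric moisture and temperature, with
  single-relaxation Debye water and the 12-class international (ISSS)
  texture triangle (`peplinski()`, `classify_texture()`,
  `sample_compositions()`).
* **Scene generation** — randomized three-layer heterogeneous soil
  (ordered moisture 5–10 %, 10–13 %, 13–15 % with temperatures 20, 17,
  15 °C), five composition variants per layer arranged in smooth patches,
  and one or two buried root-like scatterers (circle, semicircle,
  rectangle, triangle; ε_r ∈ [2, 32]; depth 0.20–0.30 m), rasterized to
  material grids (`sample_scene()`, `rasterize_scene()`).
* **Forward simulation** — a 2-D TM-mode FDTD Maxwell solver with
  split-field PML boundaries, Ricker excitation at 900 MHz, and the
  90-trace survey geometry; the time step sits at the 2-D Courant limit,
  `5.89664e-12 s` at the default 2.5 mm grid (`run_bscan()`,
  `courant_dt()`, `write_gprmax()` for external cross-validation).
* **Preprocessing** — mean-trace background removal, exponential time
  gain `exp(1e8 · i · Δt)`, min–max normalization, nearest-neighbour
  resize to 128 × 128, and construction of the two training labels: the
  globally normalized permittivity map and its binary edge map
  (`process_sample()`, `make_labels()`).
* **Inversion network** — a dual-branch architecture: a main branch of
  four pyramidal-convolution blocks (3×3/5×5/7×7 kernels with 1/4/8
  groups + CBAM attention) around a vision-transformer block (1024
  one-pixel tokens, 16 heads, MLP 512), plus an edge-inversion auxiliary
  branch of five pyramidal blocks whose features feed the main branch;
  18.9 million trainable parameters at the default configuration
  (`build_pyvitenet()`, `count_parameters()`).  The network runs on the
  package's own compact reverse-mode engine (C++ im2col + BLAS), with
  every layer's backward pass verified against numerical gradients.
* **Training / evaluation / transfer** — composite loss
  α·MSE(perm) + β·MSE(edge) with defaults α = 1, β = 0.01; AdamW with
  cosine annealing; 8:1:1 splits; MSE, MAE and global-statistics SSIM
  metrics; and a staged transfer-learning pipeline with weight carry-over
  (`train_model()`, `evaluate_model()`, `transfer_pipeline()`).

## A worked example

Generate a scene, simulate its B-scan at reduced desk scale, preprocess,
and inspect:

```r
library(rootgpr)

rc <- reduced_sim_config()          # 0.6 x 0.5 m domain, 16 traces
scene <- sample_scene("single", rc$config, seed = 7)
scene
#> GPR scene (single): 0.60 x 0.50 m @ dx = 0.01 m
#>   layer boundaries: 0.191, 0.361 m
#>   layer 1: loamy sand, moisture 0.070, 20 degC
#>   layer 2: sandy clay, moisture 0.121, 17 degC
#>   layer 3: loamy sand, moisture 0.141, 15 degC
#>   scatterer: semicircle at (0.46, 0.25) m, eps_r = 27.51

ras <- rasterize_scene(scene)
range(ras$eps_real)                 # soil background up to the scatterer
#> [1]  8.319111 27.507807

bs <- run_bscan(ras, rc$geometry, dx = rc$config$dx)
dim(bs)                             # time samples x traces
#> [1] 509  16

sample <- process_sample(bs, ras$map, size = rc$size)
str(sample$input)                   # 32 x 32 network input in [0, 1]
#>  num [1:32, 1:32] 0.486 0.486 0.486 0.486 0.491 ...
```

The scene printout lists what was drawn for each soil layer (ISSS texture
class, moisture within the layer's fixed range, temperature) and for the
scatterer; `ras$eps_real` holds the per-cell Peplinski permittivities the
solver propagates through; the processed sample pairs the normalized
B-scan image with its permittivity and edge labels, ready for
`train_model()`.  `autoplot(bs)` and `autoplot(ras$map)` draw the radar
record and the ground truth.

At full scale the same calls with the default `scene_config()` and
`scan_geometry()` produce the 1.54 m, 90-trace, 20 ns records the
training recipe assumes.

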