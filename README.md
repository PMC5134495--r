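# lenslessSR

Single-frame super-resolution and cell counting for lensless (shadow)
microfluidic cytometry, in R.

## The problem

A lensless cytometer bonds a microfluidic channel directly onto a CMOS
image sensor; flowing cells cast diffracted shadows recorded with no
optics. Cell diameters and pixel pitches are both a few micrometres, so a
single cell covers only a handful of pixels, and shadow contrast decays
with object distance $d_{obj}$ as
$C_{im} = \alpha / (1 + (d_{obj}/D)^{\varphi})$. The resulting images are
too pixelated for reliable recognition. This package implements the
computational pipeline for such systems — aimed at researchers building
point-of-care cell counters or studying learned single-frame
super-resolution (SR) on small images:

* **ELMSR** — an extreme learning machine that regresses the
  high-frequency residual $\mathrm{HF} = \mathrm{HR} - \mathrm{LR_{Int}}$
  from 14-dimensional patch descriptors (nine 3×3 intensities + five
  finite-difference derivatives) of the bicubically interpolated LR
  image. Input weights are random and fixed; output weights come from one
  closed-form ridge solve,
  $\beta = T H^\top (I/C + H H^\top)^{-1}$ with
  $H = \sigma(AX + B)$ ($d = 14$, $L = 20$, $C = 512$ by default).
* **CNNSR** — a three-layer convolutional network (64 filters of 5×5 →
  32 of 1×1 → one 3×3 reconstruction bank, ReLU between layers; each HR
  pixel depends on a 49-pixel LR neighbourhood) trained end-to-end on MSE
  by momentum SGD ($\Delta_{i+1} = 0.9\Delta_i - \eta\,\partial L/\partial W$)
  with hand-derived backpropagation (convolutions in compiled code).
* **Pipeline** — Catmull–Rom bicubic resampling (4× by default, 12×12 →
  48×48), MSSIM-based strongest-similarity cell-type classification,
  temporal-difference detection with 8-connected labelling, increment
  counting over frame sequences, and group summary statistics
  (ratio mean/SD/CV).
* **Synthetic phantoms** — seeded generators for RBC / WBC / HepG2
  morphology, the contrast–distance degradation chain (blur, 4×
  pixelation, sensor noise), and ground-truthed flow sequences, so every
  stage is testable without captured data.

## Worked example

```r
library(lenslessSR)

# HR training library: 30 phantoms per type, 48x48 px
lib   <- make_phantom_library(per_type = 30, size = 48, seed = 3)
pairs <- lapply(lib$entries, function(e)
  hf_decompose(e$image, resample_config(4), e$cell_type))
model <- train_elm(pairs, elm_config(seed = 1))

# a held-out white blood cell, imaged lenslessly at d_obj = 10 um
hr_true <- make_phantom("wbc", 48, seed = 999)$image
lr      <- degrade_lensless(hr_true, d_obj = 10, seed = 1000)   # 12x12 px

hr_bic <- super_resolve(lr, engine = "none")        # plain bicubic
hr_sr  <- apply_elmsr(lr, model)                    # ELM engine
mssim(hr_bic, hr_true); mssim(hr_sr, hr_true)
classify_cell(hr_sr, lib)
```

Output:

```
MSSIM vs ground truth: bicubic 0.8543, ELMSR 0.8626
classified as: wbc (best MSSIM 0.8242, matched wbc_026)
    hepg2       rbc       wbc
0.5052837 0.6330267 0.8242205
```

The engine recovers detail that interpolation cannot (higher MSSIM
against the true HR image), and the recovered cell is assigned the type
whose library entries it most structurally resembles — here the WBC score
0.82 clearly separates from HepG2 (0.51) and RBC (0.63). `train_cnn()` /
`apply_cnnsr()` give the convolutional engine the same way, and
`count_sequence()` runs detection → SR → classification → increment
counting over a frame sequence.

A command-line wrapper is installed as `exec/lensless-sr` with
subcommands `synth`, `train-elm`, `train-cnn`, `sr`, `classify`, `count`:

```sh
lensless-sr synth library --out lib/ --per-type 30 --size 48 --seed 1
lensless-sr train-elm --library lib/ --out elm.rds
lensless-sr sr --engine elm --model elm.rds --in lr.png --out hr.png
```

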