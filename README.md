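# mkunet

Growth-aware lung tumor segmentation and immune-evasion scoring for
longitudinal CT, in R.

Lung tumors that grow fast under immune surveillance tend to look different
— irregular, spiculated margins, necrotic cores — and tend to behave
differently under immunotherapy. `mkunet` implements an analysis chain that
treats growth kinetics as a first-class signal alongside the images:

* **I/O and cohorts** — NIfTI volumes/masks in calibrated Hounsfield units,
  cohort CSVs, deterministic train/validation/test splits
  (420 cases at 71.4/14.3/14.3% → exactly 300/60/60).
* **Multi-modal preprocessing** — a 4-channel stack per volume: raw HU,
  slice-wise Canny edge map (σ = 1.5, hysteresis 0.1/0.2), 3-D Gaussian
  denoising (kernel 3, σ = 0.8), and sliding-window (5×5×5) gray-level
  co-occurrence contrast; plus adaptive intensity windowing parameterized by
  tumor-voxel statistics (μ, σ) and seeded geometric/noise augmentation.
* **Growth kinetics** — the log volume change rate (LVCR): the weighted
  least-squares slope of ln(tumor volume) on time, in 1/day, with uniform,
  time-interval, and inverse-variance weighting; tumors above 0.15/day are
  stratified as high-growth.
* **Segmentation network** — a 4-level 3-D encoder–decoder
  (32→64→128→256 channels, 256-channel bottleneck, ≈20.6 M parameters)
  with attention-gated skips, a 6-D clinical vector (age, gender, smoking,
  grade, stage, LVCR) fused at the bottleneck, and immune-aware attention
  gates α = σ(Wθ[f_enc, f_dec, LVCR] + bθ) that condition spatial attention
  on growth rate. Built from first principles (C++ im2col + BLAS, exact
  hand-written backprop) — no deep-learning framework required.
* **Objective and metrics** — hybrid loss 0.6·DiceLoss + 0.4·BCE; Dice,
  IoU, and HD95 (pooled bidirectional surface distances, physical mm) with
  LVCR-stratified reporting.
* **Radiomics and IES** — mesh-based sphericity π^(1/3)(6V)^(2/3)/A and the
  Immune Evasion Score
  `IES = 0.6·LVCR + 0.3·(1 − Sphericity) + 0.1·PD-L1⁺AreaRatio`.
* **Phantoms** — a synthetic longitudinal CT generator (balls with optional
  spiculations and necrotic cores, exact masks, exponential volume growth at
  a known true slope) so the whole chain is testable with no clinical data.

## Worked example

Generate a small synthetic cohort, estimate growth rates from the masks,
and score each patient:

```r
library(mkunet)

dir <- tempfile()
make_cohort(3, dir, growth_rates = c(0.2, 0.05, 0.0), seed = 2)
cohort <- read_cohort(file.path(dir, "cohort.csv"))

# per-patient LVCR from segmented volumes
rows <- split(cohort, cohort$patient_id)
for (pid in names(rows)) {
  r <- rows[[pid]][order(rows[[pid]]$time_days), ]
  vols <- sapply(r$mask_path, function(p) mask_volume(read_mask(p)))
  s <- longitudinal_series(pid, r$time_days, vols)
  res <- ies_pipeline(s, read_mask(r$mask_path[nrow(r)]))
  print(res)
}
```

```
<ies_result> P001  LVCR 0.1958/day (high, score 0.702)  sphericity 1.018  PD-L1+ ratio 0.000 (missing)  IES 0.4160
<ies_result> P002  LVCR 0.0502/day (low, score 0.286)  sphericity 1.062  PD-L1+ ratio 0.000 (missing)  IES 0.1533
<ies_result> P003  LVCR 0.0000/day (low, score 0.143)  sphericity 1.092  PD-L1+ ratio 0.000 (missing)  IES 0.0582
```

Reading the first line: patient P001's tumor volume grew at 0.196 log units
per day (the generator's true slope was 0.2/day; the difference is mask
voxelization), which is above the 0.15/day threshold, so the tumor is
stratified high-growth. Its mask is essentially spherical (sphericity ≈ 1,
so the shape term contributes ≈ 0), no PD-L1 mask was supplied (ratio 0,
flagged missing), and the composite IES 0.42 is dominated by the normalized
growth term 0.6 × 0.702.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/mkunet.R phantom --out cohort_dir --n 6 --seed 1
Rscript inst/cli/mkunet.R lvcr --cohort cohort_dir/cohort.csv --out lvcr.csv
Rscript inst/cli/mkunet.R ies  --cohort cohort_dir/cohort.csv --out ies.csv
```

Training and segmentation work the same way at desk scale
(`train`, `segment` subcommands, or `build_model()` / `train_model()` /
`predict_mask()` from R); see the methods vignette
(`vignettes/methods.Rmd`) for the model, parameters, and design decisions.

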