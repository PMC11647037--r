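# pulsarformer

Attention-based analysis of the synergy between pulsed radiotherapy
(PULSAR: personalized, ultra-fractionated stereotactic adaptive
radiotherapy) and PD-L1 checkpoint blockade in murine tumor models.

Widely spaced tumoricidal radiation pulses leave time for the adaptive
immune response to build between pulses; combined with an immune
checkpoint inhibitor such as α-PD-L1, the net effect on tumor growth — the
*PULSAR effect* — depends on pulse dose, spacing, and drug timing.
`pulsarformer` studies this interaction with a deliberately small
sequence-to-sequence model:

* **Simulator** — group-mean tumor-volume trajectories on a 28-day axis
  from exponential growth, linear-quadratic (LQ) pulse kill
  `S(D) = exp(-(αD + βD²))`, lagged exponential repopulation, a delayed
  radiation→immunotherapy synergy kill, survival-endpoint censoring
  (dimension > 2 cm or volume > 1500 mm³), and uniform augmentation around
  group means (24 groups × 50 replicates = 1200 samples).
* **Encoding** — each course becomes two 28 × 5 token matrices (1 signal
  channel + 4 sinusoidal positional channels); targets are the volume
  changes between adjacent measurements, `VC_i = V(d_{i+1}) − V(d_i)`,
  zero-padded and masked at unmeasured steps (6 measurements → 5 targets).
* **Model** — a 536-parameter encoder–decoder transformer
  (d_model = 5, one head, d_ff = 5, one layer each side) with the causal
  mask applied to encoder self-, decoder self-, and cross-attention
  (`softmax(QKᵀ/√d_k)·V`), trained with AdamW (lr 1e-4, weight decay
  1e-4, batch 32, 5000 epochs) on the masked L2 loss over measured steps.
* **Attention analysis** — per-group mean self-/cross-attention maps and
  difference maps `D = A_a − A_b`: when two groups differ in exactly one
  treatment factor, every nonzero entry of `D` is attributable to that
  factor.

## Worked example

Simulate two arms that differ only in checkpoint blockade, train a small
model, and attribute the cross-attention difference to the drug:

```r
library(pulsarformer)

groups <- build_default_groups()
length(groups)
#> [1] 24

kin <- tumor_kinetics_params()
print(simulate_mean_trajectory(groups[["g04_20Gyd1_aPDL1"]], kin))
#> <trajectory> g04_20Gyd1_aPDL1 6 measurements
#>   day volume_mm3
#> 1  -3  100.00000
#> 2   0  171.60069
#> 3   4   30.01505
#> 4   9   22.79592
#> 5  14   39.48478
#> 6  20  102.14537

cohorts <- simulate_cohorts(groups[c(1, 2, 3, 4)], kin,
                            n_replicates = 10, noise_level = 0.02, seed = 7)
ds <- encode_dataset(cohorts, groups)      # targets scaled to cm^3
fit <- train(ds, train_config(epochs = 500, seed = 7, holdout_n = 5))
print(fit)
#> <pulsar_fit> 536 parameters, 500 epochs; final train loss 0.02912, val loss 0.0326

by_g <- split(ds$samples, sapply(ds$samples, `[[`, "group_id"))
a4 <- group_attention(fit$params, by_g$g04_20Gyd1_aPDL1, "cross")
a3 <- group_attention(fit$params, by_g$g03_20Gyd1_iso,  "cross")
d  <- difference_map(a4, a3)               # attributable to anti-PD-L1
print(d)
#> <difference_map> g04_20Gyd1_aPDL1 - g03_20Gyd1_iso (cross); peak +0.04246 at row 4, col 1
```

The 20 Gy pulse on treatment day 1 shrinks both arms after day 0; in the
antibody arm the delayed synergy kill keeps the tumor suppressed through
day 14 (39 vs hundreds of mm³ in the isotype arm) before regrowth. In the
difference map — cross-attention of the antibody arm minus the isotype arm
— every row before the first antibody dose (step 4, treatment day 1) is
exactly zero, a direct consequence of the causal mask; the dominant entry
sits at row 4, where the first drug token's attention over the course
start is redistributed. The losses are in model units (volume changes in
cm³), so 0.029 corresponds to a ~0.17 cm³ root-mean-square error per
measured step. `render_heatmaps(d, "maps/")` writes the corresponding
figure, with the causally masked future shown in grey.

## Package layout

```
R/                 simulator, encoding, model, attention analysis, pipeline
src/               compiled training core (forward/backward + AdamW)
tests/testthat/    unit, property, and end-to-end acceptance tests
scripts/           acceptance report generator
vignettes/         methods vignette (model, assumptions, design choices)
inst/cli/          thin command-line front end (simulate/encode/train/run-all)
```
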