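---
title: "Modeling the PULSAR effect: simulator, token encoding, and attention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the PULSAR effect: simulator, token encoding, and attention analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsarformer)
```

## The problem

PULSAR (personalized, ultra-fractionated stereotactic adaptive radiotherapy)
delivers tumoricidal radiation as widely spaced pulses, leaving room between
pulses for the adaptive immune response to develop. When combined with
PD-L1 checkpoint blockade, the net effect on tumor growth — the *PULSAR
effect* — depends on pulse dose, pulse spacing, drug timing, and the
kinetics of T-cell recruitment. `pulsarformer` provides a complete,
reproducible pipeline for studying this interaction *in silico*:

1. a mechanistic simulator of murine tumor-volume trajectories under
   combined treatment schedules;
2. a token encoding of schedules and sparse volume measurements onto a
   28-day axis;
3. a deliberately minimal (536-parameter) causal-masked encoder–decoder
   transformer that predicts volume changes between adjacent measurements;
4. attention-map extraction with group-differencing arithmetic that
   attributes attention changes to a single varied treatment factor.

The transformer treats the radiation course and the antibody course as two
"sentences": the encoder reads the radiation sequence, the decoder reads
the anti-PD-L1 sequence, and cross-attention expresses how strongly a drug
token at one day interacts with a radiation token at an earlier day.

## The mechanistic simulator

The simulator produces the group-mean trajectory of each treatment arm on a
28-step daily axis whose first step is the first measurement day, three
days before the first pulse. The daily update of the measured volume
$V(t)$ is

$$V(t+1) = V(t)\, S(D_t)\, \exp\!\big(\lambda_{\mathrm{eff}}(t) - k_{\mathrm{drug}}(t)\big),$$

with the three mechanisms:

* **Exponential growth.** Untreated tumors grow as $V_0 e^{\lambda t}$.
  The default $\lambda = 0.18\,\mathrm{day}^{-1}$ (about a four-day
  doubling time) is typical of an aggressive, immunologically cold murine
  carcinoma; with $V_0 = 100\ \mathrm{mm}^3$ a control animal reaches the
  1500 mm^3 survival endpoint in roughly two weeks, matching the short
  course of such experiments.
* **Linear-quadratic radiation kill.** A pulse of dose $D$ multiplies the
  volume by $S(D) = e^{-(\alpha D + \beta D^2)}$ on the pulse day
  (measurements on a pulse day precede irradiation). Because this factor
  acts on the measured *gross* volume rather than on a clonogen count, the
  defaults are volume-response coefficients,
  $\alpha = 0.025\ \mathrm{Gy}^{-1}$, $\beta = 0.0025\ \mathrm{Gy}^{-2}$,
  preserving the standard tumor ratio $\alpha/\beta = 10$ Gy. Classic
  clonogenic coefficients ($\alpha \approx 0.3\ \mathrm{Gy}^{-1}$) would
  shrink the measured volume by eight orders of magnitude after a single
  20 Gy pulse — a cell-survival statement, not a caliper one — and would
  collapse every irradiated arm to an indistinguishable near-zero curve.
  With the volume-response defaults, 10/15/20/40 Gy pulses reduce gross
  volume to roughly 61%, 40%, 22% and 0.7%, giving the dose discrimination
  the roster needs.
* **Repopulation with lag.** After a pulse, regrowth is fully suppressed
  for `repop_lag` days (default 1) and then relaxes toward $\lambda$ with
  half-time `repop_halftime` (default 5 days):
  $\lambda_{\mathrm{eff}} = \lambda\,(1 - 2^{-(\tau - \mathrm{lag})/T_{1/2}})$
  for $\tau$ days since the most recent pulse.
* **Delayed immune synergy.** Once an anti-PD-L1 dose has been given,
  a kill rate $k_{\mathrm{drug}}(t) = k \cdot g(\tau)$ acts, where
  $g(\tau) = (\tau/L)\,e^{1 - \tau/L}$ is a gamma-like kernel of the time
  $\tau$ since the most recent pulse, peaking at 1 when $\tau = L$
  (`synergy_lag`, default 5 days) and truncated beyond
  $3\times$`synergy_width` (default width 3 days). The delayed peak
  encodes the observation that checkpoint blockade needs days of T-cell
  recruitment after a pulse before it acts; the kernel shape itself is a
  modeling choice — any smooth, delayed, transient bump would serve.
  A deliberate consequence: with no radiation at all the synergy kernel
  never activates, so the antibody-only arm coincides with the control
  arm — the hallmark of a "cold" tumor where checkpoint blockade alone
  fails.

Endpoint censoring removes measurements from the first day on which the
survival criteria hold (any caliper dimension above 2 cm, or volume above
1500 mm^3). Since only volume is simulated, the dimension rule is checked
on the cube-equivalent side $(2V)^{1/3}$; ulceration, the third criterion
of live-animal protocols, is not a function of the simulated state and is
not modeled.

### The treatment roster and augmentation

`build_default_groups()` returns 24 schedules: 12 radiation arms crossed
with isotype control / anti-PD-L1. The first six arms are the named
experimental arms (no radiation; 20 Gy d1; 40 Gy d1; 20 Gy d1+d10;
10 Gy d1+d2; 10 Gy d1+d10); the remaining six complete the roster with
further dose/interval permutations over {10, 15, 20, 40} Gy and
{1, 2, 4, 10}-day spacings. Antibody doses are placed on treatment days 1
and 10, concurrent with the pulse days used by the two-pulse arms.
Measurements fall on days −3, 0, 4, 9, 14, 20 relative to the first pulse:
the first three are fixed by the experimental description (three days
before, the day of, and four days after the first pulse); the later three
are chosen to cover the synergy window and the survival horizon while
keeping six measurements, hence five volume-change targets per animal.

Augmentation draws each replicate volume independently and uniformly from
$[\,\bar V(d)(1-p),\ \bar V(d)(1+p)\,]$ around the group mean. The noise
level $p$ is parameterized over {0.02, 0.10, 0.15} with default 0.02, the
level used for attention analysis; higher levels emulate the larger
inter-animal variance of the raw measurements. What uniform resampling
around a mean deliberately does *not* emulate: intra-animal correlation
across days, heteroscedastic caliper error, and divergent responder /
non-responder subpopulations. Tests passing on these cohorts therefore
validate the machinery (encoding, optimization, attention arithmetic), not
the biology of any particular animal.

## Token encoding

Each course becomes two $28 \times 5$ token matrices: one signal channel
plus a four-dimensional sinusoidal positional code
$[\sin d, \cos d, \sin(d/100), \cos(d/100)]$ shared by both sequences at
every step. Two frequency pairs make all 28 positions distinct while
keeping the token five-wide; a 4-bit binary code could not address 28
positions. Radiation signals are normalized by the 40 Gy roster maximum so
all inputs lie in $[0, 1]$; anti-PD-L1 administrations encode as 1 and
isotype controls as 0 (the isotype antibody carries no blockade — it *is*
the no-drug condition).

Targets are the volume changes between adjacent measurements,
$VC_i = V(d_{i+1}) - V(d_i)$, placed at the step of the *later*
measurement — the change exists only once the second measurement has been
taken, which is exactly what the causal mask assumes. All other steps hold
zero and are excluded from the loss by the mask. Summing the masked
entries telescopes to the net volume change of the course, which the test
suite verifies to machine precision.

Volume changes are computed in mm^3 and scaled by `vc_scale = 1e-3`
(i.e. expressed in cm^3) when a dataset is assembled. This is standard
target conditioning: a 536-parameter model trained at learning rate
$10^{-4}$ needs outputs of order one, and hundreds of mm^3 would demand
head weights far outside the reachable range of a short AdamW run. The
scale is stored on the dataset so predictions can be mapped back.

## The model

The architecture is intentionally minimal — one encoder layer, one decoder
layer, one attention head, $d_{\mathrm{model}} = d_{\mathrm{ff}} = 5$ —
for a small-data regime where every parameter must earn its place, and so
that the attention maps stay directly interpretable. Attention is the
standard scaled dot-product
$\mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$ with the causal mask applied in
*all three* attention blocks (encoder self-, decoder self-, and
cross-attention): a drug token on day $t$ may only interact with radiation
up to day $t$. Each sub-block is followed by a residual connection and a
layer norm (scale + shift, $\varepsilon = 10^{-5}$); the feed-forward
blocks use ReLU; the head maps each 5-dim decoder state to one scalar.
This configuration counts exactly

$$\underbrace{4\cdot30 + 60 + 2\cdot10}_{\text{encoder }200}
  + \underbrace{8\cdot30 + 60 + 3\cdot10}_{\text{decoder }330}
  + \underbrace{6}_{\text{head}} = 536$$

trainable scalars (closed form $426 + 22\,d_{\mathrm{ff}}$ at
$d_{\mathrm{model}} = 5$), and `count_parameters()` enforces it. Whether
the layer norms are strictly necessary is an open design point; the choice
here is constrained by the parameter count and by training stability.

Training minimizes the masked L2 loss — the mean squared error over
measured steps only — with AdamW at learning rate $10^{-4}$, weight decay
$10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$,
batch size 32, 5000 epochs. The 1200-sample corpus is split 80/20 at the
sample level, stratified by group; the 100-sample validation holdout is
drawn from the test portion (the corpus description uses both "20%" and "a
holdout of 100"; nesting the holdout inside the test split honors both).
Initialization is uniform Glorot, seed-controlled; no dropout and no
learning-rate schedule are used. The training loop (forward, analytic
backpropagation, AdamW) is compiled code; the R-level `forward()` used for
analysis is an independent implementation of the same mathematics, and the
test suite pins the two together (loss equality to 1e-12, analytic versus
finite-difference gradients).

Numerical edge cases are fixed deliberately: a fully masked attention row
(impossible under a lower-triangular mask, since row $i$ always keeps its
diagonal) is defensively defined as an all-zero weight row; softmax is
computed with per-row max subtraction; `lr = 0` must leave parameters
bit-identical; an all-empty target mask is an error, never a silent zero.

## Attention extraction and group differencing

After training, per-sample attention maps are averaged within a group
(averaging preserves row normalization and masked zeros; since
augmentation perturbs only outputs, all samples of a group share inputs
and therefore maps — the mean is a formality kept for ingesting measured
data, where inputs could differ). The central analysis operation is the
difference map: for two groups that differ in exactly one factor,
$D = A_{\text{group a}} - A_{\text{group b}}$ attributes every nonzero
entry to that factor. Identities that the suite enforces: $D = 0$ for
identical groups, $D(a,b) = -D(b,a)$, entries bounded in $[-1, 1]$, and —
a causality corollary — rows before the first day on which the two
schedules differ are exactly zero.

Maps are oriented rows = decoder (drug) query steps, columns = encoder
(radiation) key steps, the mathematical convention of
$\mathrm{softmax}(QK^\top)$; axis labels state this explicitly wherever a
map is rendered. Peak reports use 1-based step indices together with day
labels relative to the first pulse; ties in `peak_locator()` break to the
lowest row, then the lowest column, so reports are deterministic.

## Reproducibility and problem sizes

Every stochastic stage (simulation, augmentation, initialization, batch
shuffling, splitting) flows from one master seed through fixed offsets, so
a pipeline run is reproducible bit-for-bit; the manifest records the
configuration hash and the seed. The test suite exercises the full study
conditions — 24 groups × 50 replicates = 1200 samples trained for 5000
epochs (a few minutes of CPU time), plus a 20-sample noiseless capacity
check at 2000 epochs — and smaller property checks use reduced cohorts
(2–8 groups, 1–10 replicates, tens to hundreds of epochs), sizes chosen so
the whole suite stays fast while still covering every code path at the
full corpus scale once.

## Known limitations

* The simulator is a single-compartment volume model: no explicit T-cell
  compartment, no immune memory across pulses beyond the kernel, no
  abscopal effects, no responder heterogeneity.
* Fourteen of the 24 roster schedules are permutation placeholders; only
  the named arms carry experimental provenance, and conclusions should
  lean on those.
* Attention maps are read here as descriptive statistics of a trained
  model, not as validated biological mechanism; the group-differencing
  arithmetic isolates *model* attention attributable to a factor, which is
  at best an interpretable proxy for synergy.
* Measured-data ingestion (`load_real_trajectories()`) expects group-mean
  construction and augmentation to have been applied upstream or accepts
  per-animal trajectories as-is; fitting the simulator's kinetic
  parameters to data is out of scope.
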