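---
title: "Methods: multi-label odor classification under label imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label odor classification under label imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorclass)
```

`odorclass` models the relationship between a molecule's measurable
signatures — vibrational spectrum, electron-ionization mass spectrum,
structural fingerprint — and the set of odor descriptors humans assign to
it. This vignette documents the statistical machinery, the parameters that
matter, the numerical decisions taken where the design was genuinely open,
and what the synthetic validation data can and cannot tell you about real
odorant datasets.

## 1. Featurization

### Vibrational spectra

A vibrational spectrum arrives as a peak list: positions in cm⁻¹ with
non-negative intensities. Direct comparison of peak lists across molecules
fails because chemically equivalent modes shift by a few wavenumbers
between compounds. `smooth_vibrational()` therefore smears every peak with
a Gaussian kernel of unit area,

$$s(x) = \sum_k \frac{I_k}{\sigma\sqrt{2\pi}}
  \exp\!\left(-\frac{(x - \bar{x}_k)^2}{2\sigma^2}\right),$$

and samples $s$ on a bounded frequency scale (BFS). Defaults: kernel width
$\sigma = 10$ cm⁻¹ (the typical inter-compound mode shift), sampling step
$L = 5$ cm⁻¹, BFS endpoints 1 and 4000 cm⁻¹. Sampling at the grid points
$L, 2L, \dots, \lfloor 4000/L \rfloor \cdot L$ yields exactly
$4000/L = 800$ descriptors.

Numerical choices:

- **Grid convention.** Bin centers sit at integer multiples of $L$
  (5, 10, …, 4000), which is the unique uniform grid of step $L$ giving
  exactly $\lfloor \text{bfs\_hi}/L \rfloor$ points; `smoothing_config()`
  exposes every endpoint should a different convention be needed.
- **No kernel truncation.** The Gaussian is evaluated exactly over the
  whole grid (an 800 × #peaks dense product — trivial at this scale), so a
  peak just outside the BFS still contributes its tail rather than raising
  an error.
- **Normalization.** Each smoothed spectrum is divided by its own maximum,
  mapping it to [0, 1]. Per-spectrum (rather than global) scaling was
  chosen for symmetry with the mass-spectrum normalization below; it
  discards absolute intensity, which for heterogeneous source spectra is
  instrument-dependent anyway. An all-zero spectrum stays all-zero.

Before normalization the transform is linear in the intensities, each
peak's Riemann mass $L\sum_x s(x)$ recovers its intensity to well under
1%, and shifting an isolated peak by exactly $L$ shifts the argmax bin by
one — these are the invariants the unit tests pin down.

### Mass spectra

Fragment intensities below 50 m/z mostly reflect odorless fragments and
those above 262 m/z low-volatility compounds, so `window_mass_spectrum()`
keeps the inclusive integer window 50–262 (213 bins), zero-fills missing
m/z, and divides by the maximum intensity *within the window*. Non-integer
m/z are rounded to the nearest integer with a warning (or rejected via
`non_integer = "error"`); co-incident peaks accumulate. A spectrum with no
peak in the window remains all-zero rather than producing 0/0.

### Fingerprints

`smiles_to_fingerprint()` produces Daylight-style path fingerprints —
every linear fragment of the molecular graph hashed into 1024 bits — via
OpenBabel's FP2 through ChemmineR/ChemmineOB. The fingerprint is a
function of the molecular graph, so any SMILES spelling of the same
molecule gives the identical bit vector; unparsable SMILES raise an error
naming the offending string.

### Fusion

`fuse_features()` concatenates modality blocks column-wise
(VS + MS = 1013 columns; VS + MS + FP = 2037) and records each block's
column range in an attribute so downstream attribution can be traced back
to its modality. Nothing fancier is attempted: concatenation is the
baseline fusion whose improvements any learned fusion must beat.

## 2. Imbalance measures

For a binary label matrix $Y$ with label counts $c_1, \dots, c_L$:

- $\mathrm{Card} = $ mean labels per instance; $\mathrm{Dens} =
  \mathrm{Card}/L$.
- $\mathrm{IRLbl}(y) = \max_{y'} c_{y'} / c_y$ — 1 for the most frequent
  label, larger for rarer ones.
- $\mathrm{MeanIR}$, $\mathrm{MaxIR}$: mean and maximum of IRLbl.
- $\mathrm{CVIR} = \mathrm{IRLbl}_\sigma / \mathrm{MeanIR}$ with the
  sample standard deviation (divisor $L - 1$).

Labels that end up with zero positives (possible after splitting or
undersampling) would make IRLbl infinite; they are excluded with a warning
by default (`zero_count = "exclude"`), and the exclusion count is carried
in the report. All three ratios are verified against brute-force
recomputation from the definitions at $10^{-12}$ in the test suite.

## 3. Resampling

**ML-ROS** appends $\lfloor nP/100 \rfloor$ clones of instances carrying
minority labels. The semantics follow the published algorithm precisely:

1. MeanIR is computed **once**, on the input dataset, and serves as the
   fixed minority threshold throughout the run.
2. A label is minority while its *current* IRLbl (refreshed after every
   clone; `recompute_every` trades fidelity for speed) strictly exceeds
   that threshold; a label that crosses it stops driving cloning.
3. Each clone is drawn uniformly from the bag of (instance,
   minority-label) pairs — the algorithm's "random instance of a minority
   label" left unspecified at pair level; the bag construction makes rare
   labels with few carriers proportionally less likely than populous
   minority labels, which matches cloning-by-label-bag round-robins in
   expectation.
4. Clones are bit-identical copies with ids suffixed `.c1, .c2, …` for
   provenance.

The algorithm is deliberately self-limiting: once no label sits above the
threshold, cloning stops early with a warning even if the quota is unmet.
On long-tailed data (the regime oversampling exists for) the quota is
comfortably attainable and MeanIR and CVIR strictly decrease; on
near-balanced data MeanIR can legitimately drift upward when clones
co-carry the majority label, which is why the monotonicity property is
asserted on long-tailed generated data only.

**ML-RUS** mirrors this: $\lfloor nP/100 \rfloor$ deletions drawn
uniformly from instances carrying *no* minority label, IRLbl refreshed per
deletion so newly-minority labels become protected; minority carriers are
never deleted.

**Order relative to splitting.** Resampling is applied to the training
partition only (resample-then-train, after the split). Oversampling before
splitting would place clones of one instance on both sides of the
partition and leak test information into training; this choice is the
conservative one and is used everywhere in the package's own experiments.

**Iterative stratified splitting** assigns instances greedily, processing
labels rarest-first and sending each carrier to the partition with the
larger remaining desired count for that label (ties: larger overall
deficit, then a seeded coin flip). A label with a single positive goes to
the training side, with a warning. The resulting per-label train/test
proportion gaps beat the median of seeded random splits in the test
suite's Monte-Carlo comparison.

## 4. Classifiers

### Cost-sensitive MLP

`csmlp()` is a fully connected network — ReLU hidden layers, one sigmoid
output per label — trained with the focal loss

$$FL = -\frac{1}{N}\sum_{i=1}^{N}\sum_{j=1}^{C}
  \Big[(1-p_{ij})^{\gamma}\, y_{ij} \log(p_{ij}+\epsilon)
  + p_{ij}^{\gamma}\,(1-y_{ij}) \log(1-p_{ij}+\epsilon)\Big].$$

At $\gamma = 0$ this is binary cross-entropy; as $\gamma$ grows,
confidently-correct entries are down-weighted by $(1-p)^\gamma$ (resp.
$p^\gamma$) so the gradient concentrates on hard entries — in an
imbalanced dataset, overwhelmingly the rare labels' positives. Cost
sensitivity is realized *solely* through this loss; there is no separate
class-weight matrix.

Implementation notes, all of which are unit-tested:

- The gradient of $FL$ with respect to the logits is derived analytically
  (including the $\gamma < 1$ branch, where probabilities are clamped to
  $[10^{-12}, 1-10^{-12}]$ so the $(1-p)^{\gamma-1}$ powers stay finite)
  and verified against central finite differences.
- Optimizer: Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), mini-batches of
  32, learning rate $10^{-3}$; He initialization for ReLU layers;
  inverted dropout (default rate 0.3) on hidden activations.
- **Checkpointing.** 10% of the training rows (iteratively stratified) are
  held out; after each epoch the model is scored by micro-F1 on this
  slice, and the weights of the best epoch are returned. Strict
  improvement is required, so the earliest epoch attaining the maximum
  wins ties.
- Default architecture 512–256 with $\gamma = 2$. These are exposed, not
  sacred: the reference architecture for this problem family is not
  public, and the package's own experiments use smaller stacks (64–32)
  matched to the synthetic problem sizes below.
- Training is deterministic given `seed`; one seed governs
  initialization, batch order, dropout masks and the validation split.

A label with no positive training instance trains to a near-constant
probability and is flagged with a warning rather than an error.

### Decomposition methods

`binary_relevance()` fits one independent binary model per label;
`classifier_chain()` additionally feeds classifier $j$ the 0/1 relevances
of the $j-1$ earlier labels (true labels at training time, the chain's own
thresholded outputs at prediction time), letting it exploit label
correlations; the chain order defaults to dataset order with an optional
seeded shuffle. Base learners: logistic regression (`glm.fit`), random
forest (the tree-ensemble baseline, one forest per label), and a
1-nearest-neighbour memorizer used by the test suite to verify the
transformation logic independently of any learner's inductive bias.

## 5. Evaluation

Micro scores pool true/false positives over all (instance, label) cells —
frequent labels dominate; macro scores average per-label scores equally —
rare labels count fully. Zero-division yields 0 (with a warning) for micro
scores; for macro averages and AUROC, labels without both classes are
*skipped and counted* (`n_labels_skipped`), since a 0 would silently
depress the average by an arbitrary convention — on datasets with very
rare labels the two conventions differ materially, which is why the choice
is surfaced in the report. AUROC uses the midrank (Mann–Whitney)
statistic, cross-checked against pROC, and is reported both macro-averaged
and on the pooled cells. `ks_compare()` wraps the two-sample
Kolmogorov–Smirnov test (asymptotic p) for comparing label-proportion
profiles between datasets.

## 6. Shapley attribution

`shapley_values()` treats features as players whose coalition value is the
model output with coalition features taken from the explained instance and
the rest imputed from background rows (held-out test rows are the
recommended background). For $K \le 12$ the $2^K$ coalitions are
enumerated exactly; beyond that, a Monte-Carlo estimator averages marginal
contributions over sampled feature orderings, drawing one background row
per ordering. The base value $\phi_0$ is the mean background prediction,
so exact enumeration satisfies efficiency
($f(x) = \phi_0 + \sum_i \phi_i$) to machine precision; under sampling the
residual is reported as `efficiency_gap` rather than silently absorbed.
The estimator is validated against an independently-written brute-force
enumerator and checked for the null-player, symmetry and convergence
properties.

`aggregate_top_features()` ranks features per label by **mean absolute**
Shapley value over the explained instances — the absolute value is the
standard importance reading; a signed mean would cancel features that push
different instances in different directions — takes each label's top
$k = 20$, and weights the union by cross-label occurrence frequency,
normalized to sum 1. `overlay_importance()` joins these weights back onto
an averaged spectrum for plotting.

## 7. The synthetic data generator

`synthetic_study()` generates datasets with the statistical structure of
real odorant data while keeping a recoverable ground truth:

- **Label marginals.** Frequencies decay from `head_frequency` (default
  0.27) to `tail_frequency` (default 0.01) over the label ranks via the
  warped-geometric family
  $p_\ell = h \cdot (t/h)^{((\ell-1)/(L-1))^{\theta}}$, with $\theta$
  solved numerically so $\sum_\ell p_\ell$ equals `cardinality_target`
  (default 3.16). A plain geometric decay cannot satisfy head, tail *and*
  cardinality simultaneously (at the default shape it implies ~8.6 labels
  per molecule); the warp keeps the head and tail exact and the decay
  monotone while hitting the target. Infeasible combinations fail fast
  with the attainable range in the message.
- Labels are sampled independently per molecule from these marginals
  (no co-occurrence model — see limitations), empty molecules are redrawn,
  and columns are re-ordered by realized frequency so marginals are
  non-increasing in column order by construction.
- **Planted signal.** Each label owns fixed diagnostic positions
  (3 vibrational wavenumbers on the 5 cm⁻¹ grid, ≥10 cm⁻¹ apart; 1
  integer m/z in 50–262; 5 fingerprint bits), included with probability
  `signal_strength` (default 0.9) when the label is present, at
  intensities in [0.5, 1]. `noise_peaks` (default 3) random peaks at
  intensities in [0.05, 0.5] are added per molecule, so the signal is not
  separable by intensity alone. The truth mapping is returned for
  recovery tests.
- **Stream order.** One seed governs everything; labels, spectra,
  fingerprints and SMILES assignment draw from sub-seeds (seed, +1, +2,
  +3) so each artifact is individually reproducible.
- SMILES are drawn from a built-in vocabulary of ~50 small valid
  molecules; they exercise the fingerprint code path, but the *learnable*
  fingerprint signal comes from the planted-bit generator so its strength
  stays controllable.

**What passing on this data shows — and what it does not.** The generator
emulates the label-frequency shape, cardinality, and peak-position-coded
signal of real data; it does **not** emulate label co-occurrence structure
(real odor descriptors are correlated; labels here are independent),
vibrational/fragmentation physics, intensity-coded information, or
feature correlations within a spectrum. Recovery results (e.g. held-out
micro-F1 ≥ 0.9 at full signal strength, ≥ 70% of planted features in each
label's attribution top-20) therefore validate the *pipeline's
correctness*, not the real-world predictability of odor, which is far
lower.

## 8. Problem sizes and defaults used in the package's experiments

The test suite and the acceptance script run the full pipeline at sizes
chosen to exercise every mechanism while remaining comfortable on a single
CPU: 400–1200 molecules, 8–60 labels for dataset-level checks (head 0.27,
tail 0.01, cardinality 3.1 for the long-tail experiments), MLPs of 64–32
hidden units trained 40–60 epochs on the 213-bin mass-spectrum modality,
Shapley sampling with 20 orderings over ~25 instances, and exact
enumeration up to 12 features. The defaults of `synth_config()` (2606
molecules, 109 labels) reproduce the full-scale label-distribution shape
when needed.

## 9. Known limitations

- Independent-label generation understates the benefit Classifier Chains
  can extract from real co-occurrence structure; the CC-vs-BR tests use
  explicitly constructed correlated labels instead.
- ML-ROS's fixed-MeanIR threshold makes large oversampling percentages
  unattainable on mildly imbalanced data by design; the implementation
  stops early with a warning rather than forcing the quota.
- The CSMLP is plain dense backpropagation in R; it is deliberately sized
  for hundreds-to-thousands of instances and ~10³ features, not for
  large-scale deep learning.
- Exact Shapley enumeration is capped at 12 features; beyond that the
  sampling estimator's Monte-Carlo error decreases as
  $O(1/\sqrt{n_\text{permutations}})$ and is surfaced via
  `efficiency_gap`.
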