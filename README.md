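# odorclass

Multi-label odor classification from molecular spectra and fingerprints,
with first-class support for the severe label imbalance that odorant
datasets exhibit.

## The problem

Predicting how a molecule smells is a multi-label problem: a single odorant
typically carries several descriptors ("fruity", "sweet", "green", ...) out
of a vocabulary of a hundred or more, and the descriptor frequencies are
extremely long-tailed — the most common odor can appear on more than a
quarter of all molecules while the rarest appear on a handful. Models
trained naively on such data learn the head of the distribution and ignore
the tail. `odorclass` implements a complete, tested pipeline for this
setting, aimed at cheminformatics researchers working on
structure–odor or spectrum–odor relationships:

- **Featurization** of three molecular modalities into fixed-length
  vectors:
  - *Vibrational spectra*: each peak is smeared by a Gaussian kernel
    `K(x) = 1/(σ√2π) · exp(−(x−x̄)²/(2σ²))` and sampled on a bounded
    frequency scale (1–4000 cm⁻¹, step L = 5 cm⁻¹, σ = 10 cm⁻¹),
    giving 800 descriptors per molecule, max-normalized to [0, 1].
  - *Mass spectra*: intensities at integer m/z in the inclusive 50–262
    window (213 bins), divided by the windowed maximum.
  - *Fingerprints*: 1024-bit Daylight-style path fingerprints from SMILES.
  - Modalities fuse by simple column concatenation.
- **Imbalance measurement**: label cardinality and density, the per-label
  imbalance ratio `IRLbl(y) = max_y' count(y') / count(y)`, its mean
  (MeanIR), maximum (MaxIR) and coefficient of variation
  (CVIR = sd(IRLbl)/MeanIR).
- **Resampling**: multi-label random oversampling (ML-ROS) clones
  instances carrying minority labels (IRLbl > MeanIR) until a P% size
  increase, refreshing IRLbl after every clone; ML-RUS deletes instances
  carrying no minority label. Iterative stratified splitting keeps
  per-label proportions balanced across train/test partitions.
- **Classifiers** behind one fit/predict contract: a cost-sensitive
  multilayer perceptron (`csmlp`) trained with the focal loss

  ```
  FL = −1/N Σᵢ Σⱼ [ (1−p)^γ y log(p+ε) + p^γ (1−y) log(1−p+ε) ]
  ```

  (ReLU hidden layers, per-label sigmoid outputs, dropout, Adam,
  best-epoch checkpointing by validation micro-F1), plus Binary
  Relevance, Classifier Chains and a per-label random-forest baseline.
- **Evaluation**: micro/macro precision, recall and F1, rank-based AUROC,
  and a two-sample Kolmogorov–Smirnov comparison of label-proportion
  profiles.
- **Attribution**: exact (K ≤ 12) and permutation-sampling Shapley values
  with per-label top-k aggregation, frequency-proportional feature
  weights, and spectrum overlays.
- **Synthetic data**: a generator producing odor-like datasets with a
  controlled long-tailed label distribution and planted, recoverable
  spectral signal, so every stage above can be validated end to end
  without any external download.

## Worked example

```r
library(odorclass)

cfg <- synth_config(n_molecules = 600, n_labels = 25, cardinality_target = 3.1,
                    head_frequency = 0.27, tail_frequency = 0.01,
                    signal_strength = 0.95, noise_peaks = 2, n_diag_ms = 2,
                    seed = 1)
study <- synthetic_study(cfg)
imbalance_report(study$labels)
#> <imbalance_report>
#>   Card   Dens   CVIR  MaxIR MeanIR
#>  3.260  0.130  1.198 25.857  6.160

X  <- spectrum_matrix(study$ms_peaks, window_mass_spectrum)
sp <- iterative_stratified_split(study$labels, 0.2, seed = 2)
train <- multilabel_dataset(X[sp$train, ], study$labels[sp$train, ])
train_ros <- ml_ros(train, percentage = 10, seed = 3)   # 10% more instances

fit <- csmlp(train_ros, hidden = c(64, 32), epochs = 60, gamma = 2, seed = 4)
#> <csmlp> layers 213-64-32-25, gamma 2, dropout 0.3
#>   best epoch 54/60 (validation micro-F1 0.8626)

evaluate_predictions(study$labels[sp$test, ], predict(fit, X[sp$test, ]))
#> <evaluation_report>
#>     micro-F1      micro-P      micro-R     macro-F1 AUROC(macro) AUROC(micro)
#>        0.845        0.993        0.735        0.567        0.970        0.982
```

The imbalance report shows the generated data is genuinely long-tailed
(the most frequent of the 25 odors covers ~30% of molecules, MeanIR > 6);
after a 10% ML-ROS pass and focal-loss training, the held-out micro-F1 of
0.845 reflects that the planted peak→label signal (95% penetrance, 2 noise
peaks per molecule) is largely recovered, while the lower macro-F1 shows
the rarest labels remain hardest — exactly the gap the imbalance tooling
is there to diagnose. Shapley attribution
(`shapley_values()`, `aggregate_top_features()`, `overlay_importance()`)
can then map each label's decisions back to the spectral bins driving
them.

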