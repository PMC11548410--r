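---
title: "Synthesizing post-stroke reaching kinematics: model and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing post-stroke reaching kinematics: model and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Machine-learning models for wearable stroke-rehabilitation monitoring are
chronically data-starved: labeled reaching trials from stroke survivors are
expensive to collect, heterogeneous across patients, and imbalanced across
impairment levels. One remedy is generative augmentation — training a
conditional generative adversarial network (cGAN) on the available trials and
adding class-conditioned synthetic trials to the classifier's training set.

`reachsynth` implements that pipeline end to end for 5-second, 9-channel
upper-limb kinematic trials sampled at 60 Hz: trunk (T8 marker) position
x/y/z in centimeters and axial rotation in radians, plus shoulder (x, y, z)
and elbow (x, y) joint angles in radians. Trials are labeled with one of ten
short reach-and-return tasks and one of three impairment groups — healthy
controls, mild stroke (Fugl-Meyer upper-extremity score above 42), and a
pooled moderate + severe group (score 42 or below) — yielding 30
task-by-impairment classes (`code = task_index * 3 + group_index`).

## Data model and preprocessing

Every trial is a 300 x 9 matrix. Longer recordings are cropped to their
first 300 samples (movement onset is at trial start in the source protocol);
shorter ones are extended by repeating the final sample, which preserves the
resting posture at the end of a completed reach. Positions are converted to
centimeters and angles to radians on read; the CSV reader dialect declares
the source units (meters/degrees by default, the common motion-capture
export convention).

Two clinically distinct labelings coexist and should not be confused:

* `severity_band()` — the three-way clinical banding of the Fugl-Meyer
  score (below 25 severe, 25–53 moderate, above 53 mild).
* `assign_impairment_group()` — the two-way split of stroke trials at a
  threshold of 42 used for class conditioning, with a score of exactly 42
  placed in the moderate + severe group. The pooling exists because severe
  impairment is rare in the source cohort; the cohort medians (mild 55,
  moderate 42, severe 21) then fall on the intended sides of the threshold.

## The movement simulator

Because the source recordings cannot be redistributed with the package, a
parametric simulator (`simulate_dataset()`) generates structurally faithful
stand-ins, and every test and the acceptance analysis run on it. Each trial
is

    signal = envelope(t) x (template * group_gain * amplitude_jitter) + noise

* **Envelope** — a reach-and-return profile: minimum-jerk
  (`10t^3 - 15t^4 + 6t^5`) out for the first half of the movement and back
  for the second. Movement duration is N(3.0 s, 0.4 s) truncated to
  [1.0, 4.8] s, so every movement starts at the window origin and returns to
  baseline inside the window.
* **Templates** — ten fixed 9-vectors of peak excursions (2–4 cm trunk,
  0.05–0.25 rad trunk rotation, 0.1–1.5 rad joint angles), chosen so the
  tasks are distinct in range-of-motion (ROM) space. This gives the task
  classifier a learnable signal at desk scale.
* **Group gains** — trunk channels are multiplied by 1.0 / 1.5 / 2.2 and
  arm channels by 1.0 / 0.8 / 0.55 for control / mild / moderate + severe.
  This encodes the two robust phenomena the synthetic data must reproduce:
  compensatory trunk displacement grows with impairment, and arm excursion
  (e.g., forearm pronation–supination) shrinks.
* **Noise** — white Gaussian noise lowpass-filtered at 4 Hz and rescaled to
  per-channel SDs (0.25 cm positions, 0.01–0.03 rad angles). The 4 Hz
  cutoff is deliberate: it leaves measurable energy above 2 Hz in the raw
  simulated data, so the GAN post-filter and the spectral loss have
  something real to remove, while the noise-free movement keeps at least
  95% of its non-DC power below 2 Hz.

Each trial draws from a substream seeded by a counter, so datasets are
bit-reproducible and insensitive to generation order.

What the simulator does **not** model: joint limits, inter-joint coupling,
multi-phase object interactions, subject-level idiosyncrasy beyond amplitude
jitter, or the absolute amplitudes of any particular motion-capture corpus.
Passing tests on simulated data therefore demonstrate that the pipeline's
machinery (conditioning, spectral shaping, protocol hygiene) works — not
that the GAN meets any clinical realism bar on real recordings.

## The conditional GAN

The generator concatenates a noise vector (default length 100) with a
learned 16-dimensional class embedding, passes it through a dense layer with
batch normalization, ReLU and dropout 0.4, reshapes to 75 time steps, and
applies two upsampling blocks (x2 upsampling, then Conv1D with 256 and 128
filters, kernel 15, batch norm, ReLU, dropout). A final 9-filter Conv1D
produces the channels, centre-cropped or zero-padded to 300 samples.

The discriminator mirrors it: the class embedding is broadcast over time as
extra input channels, followed by two stride-2 Conv1D blocks (128 then 256
filters, LeakyReLU 0.2, dropout 0.4), flattening, a minibatch-discrimination
layer, and a dense logit. Minibatch discrimination projects each sample's
features through a learned tensor into several small vectors and appends
`sum_{j != i} exp(-||M_i - M_j||_1)` per kernel — a collapsed (all-alike)
generator batch produces conspicuous values, counteracting mode collapse.
The sum excludes `j = i` so a batch of one is well defined (zeros).

Both networks train with Adam (learning rate 3e-4, beta1 0.5) on binary
cross-entropy. Channels are standardized to zero mean / unit variance over
the training set first — the mixed cm/rad scales would otherwise dominate
every loss — and samples are de-standardized on generation.

### Spectral loss

Plain cGANs produce trajectories with excess power above 2 Hz. The spectral
loss counteracts this during training: per channel, the one-sided magnitude
FFT spectrum (151 bins at length 300) of each sample is averaged over the
batch separately for real and generated data, and the mean squared
difference between the two batch-mean spectra is added to the generator
loss with weight lambda. Its analytic gradient is computed through the FFT
(`d|X_k|/dx_t = Re(conj(X_k)/|X_k| * e^(-i w_k t))`) and verified against
finite differences in the tests. A `paired` mode comparing per-sample
spectra in batch order is available behind a config switch; batch-mean is
the default because the pairing of real and generated samples within a
batch is arbitrary.

Raw magnitude spectra scale with signal length, so at 300 samples the
spectral term is numerically on the order of hundreds while the adversarial
term is order one. With lambda = 1 the spectral gradient swamps the
conditioning signal: the generator converges to samples whose spectra match
the class-blind batch average (a mixture of all class frequencies), and
class-conditional recovery fails. The default is therefore lambda = 0.05,
at which conditional recovery and high-band suppression both hold in the
package's own acceptance runs; lambda remains exposed in
`gan_train_config()`.

### Conditioning and balance stabilizers

Three further training choices proved necessary for class conditioning to
emerge at small data scales, where the discriminator can otherwise win on
signal texture alone and never enforce label consistency:

* **Matching-aware discriminator** (`mismatch_weight`, default 0.5): each
  step also scores real signals paired with deliberately wrong (deranged)
  labels as fake. This is the standard conditioning device for cGANs with
  concatenated labels; without it the generator's label pathway receives
  almost no gradient.
* **One-sided label smoothing** (`real_label_smooth`, default 0.9) and a
  **slower discriminator** (`d_lr_factor`, default 0.5): both keep the
  discriminator from saturating, which would starve the generator of
  informative gradients.
* Class embeddings are initialized at scale `1/sqrt(embed_dim)` so the
  discriminator's label channels are commensurate with the standardized
  signal channels.

After training, a zero-phase 4th-order Butterworth lowpass at 2 Hz
(forward–backward, with odd-reflection edge padding and steady-state filter
initialization so 300-sample windows are not distorted at their ends) is
applied to generated trials before they are used anywhere.

## Realism evaluation

* **Range of motion** — per-channel max minus min, the standard kinematic
  impairment feature. Real and synthetic ROM distributions are compared per
  (task, channel, group) cell with two-sided Welch t-tests (unequal
  variances are expected between real and synthetic spreads; the pooled
  Student variant is a config switch). The full 10 x 9 x 3 grid of raw
  p-values mirrors the conventional reporting layout for such comparisons; no multiple-testing
  correction is applied, matching how such grids are conventionally
  reported with a 0.05 bolding threshold. Cells with fewer than two trials
  per side are flagged rather than tested.
* **High-band power ratio** — the share of non-DC periodogram power above
  2 Hz, Parseval-consistent, averaged over samples and channels; the
  quantitative handle on the "too much high-frequency energy" failure mode.
* **t-SNE** — trials are flattened to 2700-vectors after per-channel
  standardization, reduced to 50 principal components, and embedded in 2-D
  (exact O(N^2) t-SNE: perplexity calibration by bisection, early
  exaggeration 12 for 100 iterations, momentum 0.5 then 0.8, 400
  iterations, perplexity lowered to N/4 for small N). The embedding is a
  qualitative check that synthetic trials occupy the same class regions as
  real ones.

## Task classifier and augmentation experiment

The classifier is a small 1-D FCN: Conv1D(64, kernel 3, ReLU) → maxpool 2 →
Conv1D(128, kernel 3, ReLU) → maxpool 2 → flatten → dense(100, ReLU) →
dropout 0.5 → softmax. "Same" padding keeps the arithmetic 300 → 150 → 75,
so the first dense layer holds 9600 x 100 + 100 = 960,100 parameters. It
trains with Adam on sparse categorical cross-entropy. The default target is
the 10 tasks; a 30-class task-by-impairment mode is a config switch, since
confusion matrices over tasks are the primary reported artifact.

`run_experiment()` performs the stratified five-fold cross-validated ratio
sweep: for each fold, a cGAN is trained **on the training portion only** —
the defensible protocol, since a GAN trained on all data would leak
held-out trials into the augmented training sets (`gan_global = TRUE`
exists to mimic the leaky alternative). The same per-fold bundle serves
every ratio condition (Real Only, 2:1, 1:1, 2:3, 1:2 real:synthetic) for
comparability. Synthetic counts are `round(n_real * synth/real)`, allocated
across classes proportionally to real class counts with largest-remainder
rounding, and filtered at 2 Hz before joining the training set. Evaluation
is always on the held-out real fold. Precision, recall and F1 are
support-weighted; support-weighted recall equals accuracy identically
(each class contributes `n_i * (c_ii/n_i) / N`), which is also the internal
consistency check on the reported tables. The ± values are across-fold
standard deviations.

## Problem sizes and numerical choices

The package's own acceptance analysis runs everything at desk scale on the
simulator, with sizes chosen once as a realistic small study:

* Toy conditional-recovery runs: 2 classes x 32 sinusoid trials (0.5 Hz vs
  1 Hz), generator reshape 75 x 8 with 12/8 filters, kernel 9, learning
  rate 1e-3, 300 epochs; spectral-loss ablations (lambda 0 vs 0.05) at 40
  epochs over 5 paired seeds.
* Ratio-sweep runs: 30 classes x 20 simulated trials (600 total), GAN with
  reshape 75 x 12, 20/12 filters, kernel 9, 6 epochs per fold; FCN with
  16/32 filters, 3 epochs; 5 folds. The classifier is deliberately
  under-trained: augmentation is useful precisely when the baseline is
  data- or training-limited, and real-world task classifiers on small
  stroke cohorts operate far below ceiling. A longer schedule saturates the
  simulator's tasks (the real-only baseline reaches ~0.95) and leaves
  augmentation nothing to improve; at 3 epochs the baseline sits near 0.90
  and the 1:1 condition recovers the expected direction of effect.

Published-scale layer widths (256/128 generator filters, 64/128 FCN
filters, kernel 15, 100-dimensional noise) remain the package defaults for
real use; the reduced widths above are configuration choices for the
bundled analyses, not separate code paths.

Other numerical details: batch statistics need at least two samples, so
trailing batches of one are skipped; batch-norm running statistics use
momentum 0.9 and are frozen at sampling; dropout is disabled at sampling so
generation is deterministic given noise, label and bundle; degenerate
zero-variance-both-sides t-tests return p = 1 when means agree; all
randomness flows through R's RNG seeded per config, so training runs,
datasets and the full experiment are bit-reproducible given their seeds.

## Known limitations

* The GAN and FCN run on a compact in-package network engine (im2col
  convolutions with BLAS matrix products, C++ kernels for the hot paths,
  exact hand-derived backward passes). It is single-threaded CPU code aimed
  at desk-scale studies, not a GPU training stack.
* Realism statistics are limited to ROM, band power and t-SNE; smoothness
  metrics (spectral arc length, velocity peaks, inter-joint coupling) are
  out of scope.
* The simulator's amplitudes are stylized; absolute agreement with any real
  corpus is neither attempted nor claimed.
* Cross-validation is stratified by class, not leave-subject-out; with few
  subjects per group, subject-level generalization is a separate question.
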