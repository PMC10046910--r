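---
title: "Kernel cross-spectral functional connectivity networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel cross-spectral functional connectivity networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kcsfcnet)
```

## The decoding problem

Binary motor-imagery (MI) brain-computer interfaces ask a subject to imagine
moving the left or the right hand while multichannel EEG is recorded; the
decoder must recover the imagined side from a single epoched trial
$X_r \in \mathbb{R}^{N_c \times N_t}$ with label $y_r \in \{0, 1\}$. Class
information in MI is carried less by single-channel power than by the
*joint* spectral structure across channels — which sensors co-vary, in which
rhythm, and how strongly. `kcsfcnet` implements KCS-FCnet, a shallow neural
decoder whose bottleneck is an explicit functional connectivity
representation, so the same fitted object yields both a prediction and an
interpretable channel-pair map.

## The model

The network composes, per trial:

1. **Temporal convolution.** Each channel is convolved (valid mode, stride
   1, no bias) with $N_f$ learnable kernels $w_f \in \mathbb{R}^{\Delta t}$,
   producing $N_f$ band-focused versions of every channel. The kernel
   length defaults to half the sampling rate ($\Delta t = f_s/2$ samples,
   a fixed 0.5 s span), tying the filters' frequency resolution to the
   data rate.
2. **Batch normalization + ELU** (one scale/shift pair per filter map).
3. **Gaussian-kernel connectivity.** For every unordered channel pair
   $(c, c')$ and filter $f$, the similarity
   $\kappa_G(z_c, z_{c'}) = \exp\!\left(-\lVert z_c - z_{c'}\rVert^2 / 2\sigma^2\right)$
   of the filtered signals is computed with one global, *trainable* scale
   $\sigma$. Because $\kappa_G$ is a stationary positive-definite kernel of
   the difference $z_c - z_{c'}$, its spectral (Bochner) representation
   reads as a cross-spectral distribution over the band selected by the
   filters: the layer measures frequency-resolved statistical dependence,
   not just amplitude correlation.
4. **Filter averaging.** The $N_f$ connectivity maps are averaged,
   realizing the expectation over filters and collapsing to one
   $N_c(N_c-1)/2$-vector per trial (the strict upper triangle; the kernel
   is symmetric, so nothing is lost).
5. **Batch normalization + ELU + dropout (0.5) + dense softmax readout**
   with weights $v \in \mathbb{R}^{N_c(N_c-1)/2 \times N_y}$.

Trainable parameters: $N_f\,\Delta t + 2N_f + 2 + \tfrac{N_c(N_c-1)}{2}N_y
+ N_y + 1$ — e.g. 4,301 for the 64-channel, $N_f = 4$, $\Delta t = 64$
configuration (`count_parameters()`), comfortably in the lightweight
(<20k) regime for EEG decoders.

### Training

`kcs_fit()` minimizes mean categorical cross-entropy with full-batch Adam
(learning rate $10^{-3}$, 500 epochs by default, no callbacks), treating
$\Theta = \{w_f, v, b, \sigma, \text{BN scales/shifts}\}$ as trainable.
Design choices worth knowing:

* **$\sigma$ is log-parameterized** (`log_sigma`), so positivity is
  structural rather than enforced by clipping, and it is initialized by
  the *median heuristic*: $\sigma^2$ = half the median squared pairwise
  channel distance on a forward pass of the training batch with the
  initial filters, so the median kernel value starts at $e^{-1}$. A fixed
  value is available via `sigma_init = "fixed"`. An all-zero batch makes
  the heuristic degenerate; it falls back to $\sigma = 1$ with a warning.
* **Max-norm constraints** are re-projected after every update: each
  convolution kernel onto $\lVert w_f \rVert_2 \le 2$, each readout column
  onto $\lVert v_{\cdot k} \rVert_2 \le 0.5$. Projection (rather than
  penalty) keeps the constraint exactly satisfied at every epoch.
* **Batch normalization** uses batch statistics during training and
  running averages (momentum 0.1, variance floor $10^{-3}$) at inference,
  so prediction and connectivity extraction are deterministic.
* The backward pass is written in full (convolution, both batch norms,
  the kernel block including $\partial/\partial\sigma$, the readout) and
  is verified in the test suite against central finite differences to
  $10^{-4}$ relative error.
* Ties in predicted class go to the lowest class index; training aborts
  with a diagnostic if the loss becomes non-finite.

## Preprocessing

`preprocess()` applies, in fixed order: Fourier-method downsampling to 128
Hz (FFT truncation — an ideal low-pass resampler, not decimation),
a fifth-order Butterworth band-pass over 4–40 Hz (covering theta through
beta rhythms), and clipping to the MI window 0.5–2.5 s after the cue.
The filter runs forward-backward by default (zero phase, effective order
10): the analysis window is short, so group-delay distortion of a causal
pass would shift rhythm onsets by a meaningful fraction of the epoch;
`zero_phase = FALSE` restores the causal single pass. Clip windows are
half-open `[t0, t1)` in samples, so a 2 s window at 128 Hz is exactly 256
samples. An optional amplitude threshold (`reject_threshold`) drops
trials with extreme voltages; it is off by default because the synthetic
generator produces no artifacts.

## Evaluation and subject grouping

`cross_validate()` implements the five-repeat shuffled 80/20 scheme:
five independent shuffles, 80% training / 20% held-out scoring, seeded;
a shuffle that leaves either portion single-class is redrawn (the model
cannot fit one class, and AUC is undefined without both). Metrics per
fold: accuracy (argmax), Cohen's kappa $(p_o - p_e)/(1 - p_e)$, and AUC
(probability a random positive outranks a random negative, ties ½).
`grid_search_nf()` searches $N_f \in \{2, 3, 4\}$ on folds *shared across
candidates* — sharing removes split noise from the comparison but means
the winner's reported folds are the selection folds, a mild optimism that
is inherent to non-nested selection and flagged here.

`build_score_matrix()` produces the six-column subject summary used for
stratification: mean accuracy, mean *normalized* kappa
$(\kappa + 1)/2$, mean AUC, and the complements $1 - \mathrm{sd}$ of each,
so every entry lies in $[0, 1]$ and larger is better. Kappa is normalized
per fold, before aggregation, so the complemented standard deviation is
also bounded; standard deviations are population-form over folds.
`cluster_subjects()` fits k-means ($k = 3$, 10 seeded restarts) and names
the clusters G I/G II/G III by decreasing centroid accuracy;
`order_subjects()` orders subjects along the first principal component
(sign anchored to correlate positively with accuracy);
`transfer_labels()` assigns new subjects to existing centroids without
refitting (nearest centroid, ties to the best group). With exactly $k$
subjects each subject is its own centroid (k-means requires strictly
fewer centers than points); identical-score degenerate input yields all
G I with a warning.

## Connectivity interpretation

* **Pruning** (`prune_connections()`): per channel pair, trial-wise
  connectivity values are split by class and compared with the two-sample
  Kolmogorov–Smirnov test; pairs with $p \le 0.05$ are kept. The exact
  null distribution is used when $n + m \le 25$, the asymptotic
  approximation otherwise. *No multiple-testing correction is applied* —
  the mask is a raw per-pair rule, so about 5% of null pairs survive by
  chance; treat the mask as descriptive screening, not confirmatory
  inference. Note the discreteness of the KS statistic makes the test
  conservative at the 0.05 level, increasingly so as the per-class trial
  count grows past a few dozen; the package's null-calibration
  simulations therefore use 20 trials per class, where the measured
  rejection rate sits close to (just under) the nominal level.
* **Quadratic Rényi entropy** (`renyi_entropy()`): the literature applies
  "quadratic Rényi entropy of the pruned connectivity matrix" without a
  unique formula, so the package operationalizes it over the distribution
  of significance weights: each significant pair gets $w_i = 1 - p_i$,
  the weights are normalized to $q$, and $H_2 = -\log_2 \sum q_i^2$ bits.
  This has exact closed forms ($0$ for ≤1 retained pair, $\log_2 m$ for
  $m$ equally weighted pairs) and increases with more, more evenly
  retained connections — the qualitative behaviour the measure is used
  for. The matrix-eigenvalue variant ($-\log_2 \mathrm{tr}(N^2)$ of the
  trace-normalized weight matrix with unit diagonal) is available via
  `method = "eigen"`; note its scale behaves differently (it is maximal
  for an empty mask, where the matrix is the identity).
* **Edges and relevance**: `top_percentile_edges()` min-max normalizes
  mean connectivity jointly across the supplied subjects (so strengths
  are comparable between them) and keeps pairs at or above the pooled
  99th percentile — the edge list any connectogram/Circos plotter can
  consume. A per-subject normalization is a config choice away
  (pass one subject at a time). `channel_relevance()` collapses pairwise
  evidence per channel, either from significant $1 - p$ values or from
  class-averaged absolute readout weights $|v|$ (per-class maps are
  obtainable by passing a single column).
* **Layout**: `tsne_layout()` embeds score-matrix rows in 2-D with exact
  t-SNE at perplexity 10 (the subject counts involved are tens, where
  the exact gradient is appropriate; implemented in-package and
  deterministic per seed).

## The synthetic generator, and what passing tests mean

`generate_subject()` emulates the statistical skeleton of a two-class MI
recording: balanced trials, per-channel 1/f ("pink") background noise of
unit variance (spectrally shaped white noise — EEG-like spectra stress the
band-pass stage more honestly than white noise), and, for each coupling
entry, one shared band-limited Gaussian source added at zero lag to both
channels of the designated pair for the designated class, with
per-channel source variance `snr`.

The shared source enters the two channels with *opposite polarity* (an
antiphase dipole projection). This is deliberate: the model's
connectivity statistic is a stationary kernel of the channel *difference*
$z_c - z_{c'}$, and a source added with identical sign cancels exactly in
that difference — it would raise in-band coherence while leaving the
planted pair invisible to the very detector under test (only second-order
batch-norm/ELU effects would remain). With antiphase injection the
dependence lives in the difference itself: in-band coherence rises
identically, and the kernel layer, the KS pruning and the filter spectra
all see the planted structure.

The reference condition (the `synthetic_spec()` defaults) is 80 trials of
16 channels at 128 Hz, 3 s long, with an alpha-band (8–13 Hz) pair planted
for class 1, a beta-band (18–24 Hz) pair for class 0, and `snr = 2` —
sizes chosen as a realistic single-subject session that a laptop-scale
test suite can fit repeatedly. On it, the test suite verifies end to end
that cross-validated accuracy is high, that both planted pairs are
flagged by the pruning, that the learned filters' aggregate frequency
response (restricted to the 4–40 Hz band where the input carries energy;
outside it the filters' response is gradient-free and unidentifiable)
peaks inside a planted band, and that an `snr = 0` control decodes at
chance within the binomial band.

The generator does *not* emulate volume conduction (no mixing matrix),
ocular/muscular artifacts, inter-trial nonstationarity, or realistic
channel covariance. Passing tests therefore demonstrate that the
implementation recovers known planted structure under EEG-like spectra —
not that the architecture attains any particular accuracy on real
recordings.

## Numerical choices

* Pair order is fixed lexicographic ($(1,2), (1,3), \dots$;
  `channel_pairs()`), shared by every connectivity vector, readout row
  and p-value matrix.
* Batch-norm variance floor $10^{-3}$; Adam $\beta_1 = 0.9$,
  $\beta_2 = 0.999$, $\epsilon = 10^{-8}$; Glorot-uniform initialization.
* Squared distances are clamped at 0 against cancellation error before
  the kernel exponential.
* All randomness (simulation, initialization, dropout, splits, k-means,
  t-SNE) flows from explicit seeds; `run_pipeline()` derives per-stage
  substreams from one root seed, and repeated runs are byte-identical.
* Test-suite and acceptance-script problem sizes (one to three synthetic
  subjects, 80 trials, 16 channels, 200 null replications) are the
  package's reference sizes: large enough that every statistical check is
  stable under its stated tolerance, small enough to re-run routinely.

## Applying the pipeline to real recordings

The same protocol runs on real data: convert trials to the package
container (`eeg_trial_set()` + `write_trials()`; any reader producing an
R × channels × samples array with labels will do, e.g. for the public
64-channel, 512 Hz Giga MI corpus, GigaDB accession 100295), then
`kcsfcnet run --config cfg.yaml` executes resample → band-pass → clip →
$N_f$ grid search with 5-fold 80/20 CV → score matrix → k-means ($k=3$)
grouping → per-subject KS pruning at 0.05 → entropy, relevance and
99th-percentile edge export. Multi-hour, multi-subject corpora are
outside the test suite's scope; on such data expect qualitative, not
numerical, agreement with published group-level results.

## Known limitations

* Binary classes only; the readout generalizes to $N_y > 2$ but the
  generator and metrics assume two.
* Full-batch training: memory grows with $R \cdot N_c \cdot N_t$ (the
  lag-embedded design matrix); mini-batching is not implemented.
* The grid search reuses its CV folds for reporting (see above).
* KS pruning p-values are unadjusted; entropies computed from them
  inherit that choice.
* No artifact handling beyond the optional amplitude threshold.
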