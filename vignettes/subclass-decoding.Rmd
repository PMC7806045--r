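---
title: "Subclass-regularized tangent-space decoding of ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subclass-regularized tangent-space decoding of ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

In a screen-free brain-computer interface, candidate objects in the user's
environment are highlighted one after another (here: by a laser pointer
mounted on a robot arm), and the EEG response to each highlighting is
classified as *target* (the user attends this object) or *non-target*. The
attended object is then the candidate whose highlightings collect the
highest target scores. Because physical objects differ in surface and
salience, and because the first stimulus of a highlighting sequence evokes
a larger response than the later ones, the single-stimulus responses fall
into *subclasses* (by object instance `o`, sequence position `q`, or the
initial/subsequent grouping) with visibly different amplitude, latency and
waveform. A single pooled classifier averages over this structure; fully
separate per-subclass classifiers starve themselves of data. The pipeline
implemented here — centered tangent space with multi-target-shrinkage
regularized LDA (`cts_reg_lda`) — sits between the two: it aligns the
subclasses geometrically and then shares statistical strength across them
in a data-driven way.

## Signal representation

Each 1 s window $X_k \in \mathbb{R}^{N_c \times N_t}$, time-locked to a
highlighting onset, is

1. band-pass filtered (0.5–16 Hz) and downsampled to 100 Hz as part of the
   continuous recording, so $N_t = 101$ samples;
2. baseline-corrected by the mean of the preceding 200 ms;
3. rejected if its peak-to-peak amplitude strictly exceeds 100 µV in any
   channel;
4. augmented with class prototypes after xDAWN spatial filtering:
   $\tilde X_k = (W_t \bar X_t;\; W_{nt} \bar X_{nt};\; W_t X_k;\;
   W_{nt} X_k) \in \mathbb{R}^{8 \times N_t}$, where $\bar X_i$ are the
   class-mean (prototype) responses and $W_i$ the two leading xDAWN
   filters per class. The covariance of $\tilde X_k$ then carries, besides
   the spatial covariance of the filtered signal, its cross-covariance
   with the prototypes — i.e. temporal/phase information about the ERP —
   in its off-diagonal blocks;
5. summarized as the Ledoit–Wolf-shrunk $8 \times 8$ covariance $C_k$,
   which is symmetric positive definite (SPD) by construction.

Covariances are classified in the tangent space of the SPD manifold under
the affine-invariant Riemannian metric: at a reference point $C^m$ (the
Fréchet mean of the training covariances), each $C_k$ maps to the
symmetric matrix $S_k = \mathrm{logm}(C^{m\,-1/2}\, C_k\, C^{m\,-1/2})$,
vectorized with $\sqrt2$-weighted off-diagonals into
$s_k \in \mathbb{R}^{36}$ so that Euclidean geometry in vector form
matches the Frobenius inner product. A shrinkage LDA
$w = C_{LDA}^{-1}(\mu_t - \mu_{nt})$ provides the decision values.

## The three pipelines

* **`ts_lda`** — one Fréchet mean, one tangent space, one LDA; subclasses
  ignored.
* **`sep_ts_lda`** — per subclass $j$, its own Fréchet mean $C_j^m$,
  tangent space and LDA, fitted only on that subclass's windows.
* **`cts_reg_lda`** — every subclass is *centered* by parallel transport
  along the geodesic to the identity,
  $C \mapsto C_j^{m\,-1/2}\, C\, C_j^{m\,-1/2}$, after which all subclass
  tangent spaces coincide at $I$ and class means of different subclasses
  can be combined directly. Each subclass classifier's class mean is
  replaced by the multi-target-shrinkage (MTS) combination
  $\mu^{MTS}_{i,j} = (1-\sum_{j'} \alpha_{j'})\,\mu_{i,j} +
  \sum_{j'} \alpha_{j'}\, \mu_{i,j'}$, with weights $\alpha \ge 0$,
  $\sum \alpha \le 1$ chosen per subclass and class by minimizing an
  estimate of the mean squared error of the combined mean.

Parallel transport makes the cross-tangent-space mapping unnecessary: once
all subclass means live in the tangent space at the identity, the
matrix-exponential/logarithm round trip between tangent spaces cancels and
the combination reduces to the plain convex form above. This is the only
form the package implements.

### The MTS quadratic program

The estimated MSE is quadratic in $\alpha$: variance terms
$(1-\sum\alpha)^2 \hat V_j + \sum \alpha_{j'}^2 \hat V_{j'}$ with
$\hat V$ the summed per-dimension sample variance of the cell divided by
its count, plus a bias form built from inner products of mean differences
$\langle \hat\mu_{j'} - \hat\mu_j,\, \hat\mu_{j''} - \hat\mu_j\rangle$.
These inner products are debiased (the shared $\hat\mu_j$ inflates each by
$\hat V_j$; squared norms additionally by $\hat V_{j'}$), the diagonal is
floored at zero, and the bias matrix is projected onto the PSD cone so the
program stays convex. Because the dimension is the number of *other*
subclasses (at most 7 here), the program is solved exactly by enumerating
the stationary point of every face of the feasible polytope
($2^m$ subsets × sum-constraint active/inactive) and keeping the feasible
minimum — no iterative solver tolerance enters the result. Tests verify
the solution against a step-0.02 grid search and an independent
interior-point solver.

Two details the source material leaves open were decided as follows:

* **Within-class covariance for `cts_reg_lda`** is pooled over all
  centered subclasses (each subclass×class cell centered at its own mean
  first). Only the means are subclass-specific and regularized; the
  scatter estimate uses all the data, which mirrors the rationale of the
  centering step. With pooling disabled and $\alpha \equiv 0$ the pipeline
  provably collapses to `sep_ts_lda`, and a test asserts score equality.
* **MTS is applied independently per class** (target and non-target), one
  weight vector each, following the per-class indexing of the convex
  combination.
* Degenerate cells (fewer than two windows of a class in a subclass) fall
  back to the pooled class mean with a warning; a subclass lacking a class
  entirely is an error for the subclass-aware variants.
* Prototypes and xDAWN filters are fitted once per training fold on the
  pooled data and shared by all variants and subclasses; per-subclass
  refitting would cut the prototype sample size by $N_{sub}$ for no
  demonstrated benefit.

## Numerical choices

* Matrix functions go through the symmetric eigendecomposition.
  Eigenvalues below $10^{-12}$ times the largest raise an error instead of
  being clipped: upstream shrinkage guarantees strictly positive spectra,
  so degeneracy signals a pipeline bug.
* The Fréchet mean uses fixed-point tangent averaging (step size 1,
  tolerance $10^{-8}$ on the mean-tangent Frobenius norm, at most 50
  iterations, arithmetic-mean initialization), with a warning and the
  current iterate on non-convergence.
* The band-pass is a 4th-order Butterworth applied forward and backward
  (zero phase, so ERP latencies are preserved offline). An FIR realization
  with sub-hertz transition bands would need on the order of $10^4$ taps
  at 1 kHz; the IIR filter is the standard offline choice and its
  magnitude response is verified in tests. Downsampling is plain
  decimation, valid because the 16 Hz band edge sits far below the output
  Nyquist frequency; the constructor refuses output rates that violate
  this.
* Epoch windows are inclusive at both ends ($[0, 1]$ s → 101 samples at
  100 Hz); baselines are half-open ($[-0.2, 0)$ s). Onsets are snapped to
  the nearest sample. Artifact rejection uses a strict inequality at
  100 µV; a window at exactly the threshold is retained.
* The xDAWN evoked-response estimate uses a least-squares fit under a
  stimulus-onset (Toeplitz) design spanning all stimuli that overlap a
  window, since at 250 ms SOA every 1 s window contains several responses;
  a small ridge ($10^{-8}$ of the mean design diagonal) stabilizes the
  normal equations.
* Ties in object selection go to the lowest object id, documented and
  deterministic. Scores are raw LDA decision values; no probability
  calibration is applied because the argmax over candidates is invariant
  to any monotone calibration.

## The session simulator

The simulator generates the paradigm's schedule structure exactly — trials
× repetitions × per-object 3 s highlighting sequences at 250 or 500 ms
SOA, one target object per trial, targets balanced across objects — and a
continuous multi-channel recording as a linear superposition of source
templates projected through fixed spatial patterns, plus noise:

* **Templates.** Non-target responses are a biphasic N1/P2-like deflection
  (peaks near 120 and 200 ms, −2.5/+3 µV); targets add a parietal positive
  bump centered at 300 ms with ≈80 ms width and 5 µV default amplitude.
  These echo the qualitative shape of laser-highlighting ERPs; the exact
  study waveforms are not reproducible from printed material and are not
  claimed.
* **Subclass heterogeneity.** Per-object multiplicative gains and latency
  shifts; the first stimulus of every sequence is boosted (×1.5 by
  default), emulating the larger initial response. The `heterogeneous`
  preset (gains 1.5/1.2/0.7/0.5, latency shifts 0/0/10/25 ms) mirrors the
  salient vs less-salient object split; the `homogeneous` preset has
  identical objects.
* **Noise.** Spatially correlated pink noise: white noise shaped by an
  order-6 pole/zero cascade approximating a $1/f$ power spectrum above
  1 Hz (flat below, so drifts do not dominate the RMS budget), mixed
  through a smooth exponential spatial correlation over a fictitious
  spiral montage, scaled to 9 µV RMS per channel. Blink-like frontal
  artifacts (≈150 µV, ≈0.4 s) occur at 2/min and exercise the rejection
  rule.
* All randomness flows through one integer seed; distinct seeds play the
  role of distinct participants.

The defaults (24 trials, 3 repetitions, 4 objects, 31 channels at 1 kHz)
reproduce the study's per-session bookkeeping: 864 target and 2,592
non-target highlightings per session at 250 ms SOA, and — pooled over 13
simulated participants — 234 initial and 2,574 subsequent target windows
attributed to a single object.

What the simulator does *not* model: realistic head geometry and volume
conduction, eye-movement-dependent attention effects, non-stationary
alpha/fatigue dynamics, and per-object differences in waveform *shape*
beyond gain and latency. Passing the simulation-based tests therefore
shows that the pipelines behave as intended under controlled subclass
structure, not that the specific AUC levels transfer to any real
recording.

## Evaluation protocol

Cross-validation is five-fold and chronological at the trial level: trials
are sorted by time and split into contiguous blocks, so no window of a
test trial precedes training data and no trial straddles the boundary.
The reduced-data condition keeps only the first of the three repetitions
of every trial (33 % of windows, class balance preserved by design).
Performance is the window-level AUC (Mann–Whitney statistic, ties counted
half), computed per fold and averaged; a pooled-scores variant is
available as an option. Paired pipeline comparisons across simulated
participants use the two-sided Wilcoxon signed-rank test (exact null up to
n = 25 without ties or zeros, otherwise a normal approximation with Pratt
zero handling and tie correction) under Holm–Bonferroni adjustment.

## Problem sizes used in the test suite

The simulation-echo tests run the presets at their study-scale defaults
(24 trials, 31 channels, 1 kHz) for 10 seeds each: the heterogeneous
preset at the 33 % data fraction — where mean regularization matters most —
and the homogeneous preset on the full data. The amplitude ladder
(monotonicity of AUC in the target amplitude over 0/2/5/8 µV) and the
chance-level control (amplitude 0) use a smaller session (10 trials,
500 ms SOA, 200 Hz) since they probe qualitative behaviour rather than
study-scale effect sizes; these sizes are the package's own choice and are
stated here so results can be reproduced exactly.

## Known limitations

* The per-subclass LDA decision values of `sep_ts_lda` and `cts_reg_lda`
  are pooled into one window-level AUC without cross-subclass score
  calibration; with strongly unequal subclass SNRs this pooled AUC can
  understate within-subclass separability. Object selection is unaffected
  (it compares scores within a trial produced by the same subclass
  structure).
* EDF recordings are not read; convert to BrainVision or the native
  container.
* The MTS variance estimates assume roughly isotropic cell scatter in the
  36-dimensional tangent space; with very few windows per cell the
  debiased distance estimates are noisy, which is precisely the regime the
  pooled-mean fallback and the convex constraints are there to guard.
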