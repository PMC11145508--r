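---
title: "Removing ECG artifacts from surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing ECG artifacts from surface EMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgclean)
```

## The problem

Surface electromyography (sEMG) records muscle activity from skin
electrodes. When electrodes sit on the trunk or proximal upper limb, the
heart's electrical activity (ECG) bleeds into every channel. The two
signals overlap in time and in frequency — sEMG occupies roughly
20–250 Hz, ECG roughly 0–100 Hz — so neither gating nor plain band-pass
filtering can separate them without destroying the low-frequency part of
the EMG. `semgclean` implements a blind-source-separation approach: if the
channels are (approximately) instantaneous linear mixtures
$x(t) = A\,s(t)$ of statistically independent sources, an unmixing matrix
$W$ can be estimated from the data alone, the separated component carrying
the heartbeat can be recognised automatically, and the record can be
rebuilt without it.

The pipeline, in order:

1. **Multi-level wavelet denoising** of every channel (broadband sensor
   noise suppression).
2. **Centering and PCA whitening** of the channels.
3. **Negentropy FastICA** with deflation to extract independent
   components.
4. **Fuzzy-entropy scoring** of each component and a sorted-entropy gap
   rule to decide which components are ECG.
5. **Reconstruction** of the channels with the ECG components removed.

## Wavelet denoising

Each channel is decomposed by a cascaded two-channel Daubechies filter
bank with downsampling (`dwt_decompose()`, default `db4`, 9 levels; the
filter taps are the standard published constants). Only detail
coefficients are shrunk — the coarsest approximation is left untouched —
and the signal is rebuilt by the synthesis bank (`dwt_reconstruct()`).
Signals of arbitrary length are handled by half-point symmetric boundary
extension; the per-level analysis lengths are recorded so the round trip
is exact to floating-point precision (the test suite requires relative
error below $10^{-8}$ across `db2`/`db4`/`db8`, levels 1–9 and lengths
$2^8$–$2^{12}$).

Three shrinkage rules are provided (`apply_threshold()`). With threshold
$\lambda$ and coefficient $w$:

* **hard**: $w$ if $|w| \ge \lambda$, else 0 — discontinuous at
  $\pm\lambda$;
* **soft**: $\mathrm{sign}(w)(|w| - \lambda)$ — continuous but biased by a
  constant $\lambda$ at all amplitudes;
* **improved** (the default):
  $w - 2\lambda / (1 + e^{\,w - \lambda})$ for $w \ge \lambda$,
  $w + 2\lambda / (1 + e^{-w - \lambda})$ for $w \le -\lambda$, and 0
  inside the dead zone. This map is zero at $\pm\lambda$ (continuous),
  odd, and its shrinkage decays to zero for large $|w|$, so strong signal
  coefficients pass essentially unbiased while near-threshold (noise-like)
  coefficients are suppressed.

An alternative sign convention for the exponent
(`variant = "as_printed"`) is also continuous and odd but retains a
constant $2\lambda$ bias at large amplitudes, defeating the stated purpose
of the rule; we keep it available for comparison and default to the
asymptotically unbiased form.

Thresholds default to the universal rule per level,
$\lambda_j = \hat\sigma\sqrt{2\ln N_j}$, with
$\hat\sigma = \mathrm{median}(|D_1|)/0.6745$ estimated from the finest
detail level (`estimate_lambda()`). Manual per-level thresholds are
accepted. A decomposition-depth selector (`select_level()`) scores each
candidate depth by the decibel ratio of reconstruction power to
removed-residual power and returns the smallest depth that beats the
level-1 baseline, falling back to the configured maximum (default 9); the
criterion is a documented operational surrogate — with the universal
threshold the score usually decreases with depth, so the fall-back depth
is the common outcome, which matches the default depth of 9.

## Whitening and FastICA

Channels are centered (`center_channels()`) and whitened by
eigendecomposition of the sample covariance $C = X X^\top / m$
(`pca_whiten()`): $Z = \Lambda^{-1/2} U^\top X$ has identity covariance.
Directions whose eigenvalue falls below `var_floor` (relative to the
largest, default $10^{-9}$) are dropped; the pipeline refuses to continue
with fewer than 3 usable dimensions because the component classifier needs
at least three entropy values.

FastICA maximises a negentropy surrogate
$J(w) = \big(E[G(w^\top z)] - E[G(\nu)]\big)^2$ with the standard
log-cosh contrast: $G(u) = \log\cosh u$, $g = \tanh$,
$g' = 1 - \tanh^2$. (A contrast must supply both $G$ and its derivative;
log-cosh is the self-consistent choice for a tanh-based fixed-point
update.) The Gaussian baseline $E[G(\nu)]$ is computed once by 32-node
Gauss–Hermite quadrature — deterministic, no sampling noise. The
fixed-point update (`fastica_update()`) is

$$ w \leftarrow \mathrm{normalize}\!\left(E[z\,g(w^\top z)] -
   E[g'(w^\top z)]\,w\right). $$

Because the fixed-point iteration is sensitive to its random start, each
component's start vector is first polished by a few steepest-ascent steps
on the negentropy surrogate, $w \leftarrow \mathrm{normalize}(w +
\lambda_{\text{step}} E[z\,g(w^\top z)])$ (`gradient_refine()`, default 5
steps). The step size is found by backtracking (start 1, halve, at most
10 halvings) so the surrogate never decreases; if no step improves it the
refinement stops early with the best vector found. A pure-gradient mode
(`mode = "gradient_only"`) is available for comparison.

Components are extracted sequentially by deflation
(`extract_components()`): after every update the candidate vector is
re-orthogonalised (Gram–Schmidt) against the rows already found and
renormalised. Convergence is declared when successive vectors align to
within `tol` (default $10^{-6}$); non-convergence after `max_iter`
(default 200) flags the component but does not abort. Identical seeds
give identical unmixing matrices.

## Fuzzy entropy and ECG identification

ECG is rhythmic and smooth; sEMG and sensor noise are broadband and
irregular. Fuzzy entropy (`fuzzy_entropy()`) quantifies this: length-$m$
windows (default $m = 2$) are mean-removed, compared by Chebyshev
distance, graded by the smooth membership $\exp(-\ln 2\,(d/r)^2)$ with
tolerance $r = 0.2\,\mathrm{SD}$ by default, and the entropy is
$\ln \Phi^m - \ln \Phi^{m+1}$. With a relative tolerance the measure is
scale-invariant, which matters because ICA components have arbitrary
scale; components are nevertheless standardised first so that an absolute
tolerance option behaves sensibly. A constant series returns 0 with a
warning (all distances vanish). The $m$ and $r$ defaults are the
near-universal convention for fuzzy/sample entropy of physiological
series. The O($N^2$) pairwise kernel is compiled code; on long records the
entropy is computed on a single centered window (default 5000 samples) —
placement is deterministic, and 5 s of data at 1 kHz is ample for a
stable estimate.

Components are sorted by entropy ascending (`classify_components()`).
Scanning boundary indices $k = 2..n-1$, the first $k$ whose following gap
is strictly smaller than its preceding gap,
$\Phi_{k+1} - \Phi_k < \Phi_k - \Phi_{k-1}$, marks the end of the
low-entropy (cardiac) group. Whether the boundary component itself is
eliminated is genuinely ambiguous; flagging through $k$ would include the
first component *after* the dominant entropy jump, which contradicts the
low-entropy rationale, so the default `"exclusive"` mode flags the $k-1$
components below the jump and a `"literal"` mode (flag $k$) is provided.
If no index satisfies the strict inequality nothing is flagged and the
record passes through unchanged (minus denoising). With equal gaps the
strict inequality correctly never fires.

## The synthetic-data generators

No recorded data ship with the package; every test runs on synthetic
ground truth built by seeded generators:

* `generate_semg()` — band-passed white Gaussian noise (zero-phase
  Butterworth, default band 20–250 Hz at 1 kHz), amplitude-modulated by
  raised-cosine contraction-burst envelopes over a resting baseline
  (default rest level 0.15). This is the standard stochastic surrogate
  for interference-pattern EMG.
* `generate_ecg()` — Gaussian-bump PQRST trains at a configurable heart
  rate (default 72 bpm) with optional RR jitter: quasi-periodic, smooth,
  and therefore low-entropy, which is the property the classifier relies
  on.
* `generate_interference()` — 50 Hz mains sinusoid, slow baseline wander,
  white sensor noise.
* `mix_sources()` — instantaneous linear mixing with optional sensor
  noise; ground truth (sources and mixing matrix) is retained.
* `simulate_contaminated()` — the package's reference condition: 60 s at
  1 kHz (a typical contraction-protocol recording length), three channels
  mixing a unit-variance bursting sEMG source, an ECG train rescaled so
  its total mixed power sits `contamination_db` decibels below the sEMG's
  (default 0 dB — heavy contamination), and white noise at 0.3 relative
  SD, through a fixed full-rank matrix.

What the surrogate does *not* model: motor-unit action-potential
structure, ECG pathologies, electrode motion transients, or convolutive
(non-instantaneous) mixing. Passing tests therefore demonstrate that the
algorithm chain is implemented correctly and behaves as designed under
the stated statistical assumptions — not that it reaches any particular
performance on clinical recordings.

## Numerical choices and degenerate inputs

* Boundary handling: half-point symmetric extension; reconstruction is
  truncated to the recorded per-level lengths, making the round trip
  exact for arbitrary (non-dyadic) lengths.
* Requested depths beyond
  $\lfloor \log_2(n / (L_f - 1)) \rfloor$ ($L_f$ the filter length) are
  errors naming the feasible maximum.
* Whitening of an all-zero (zero-variance) input is a degenerate-input
  error; rank-deficient inputs lose dimensions via `var_floor`.
* A zero-norm ICA update vector triggers a reseeded restart (up to 5);
  repeated degeneracy is an error naming the component.
* Ties in the entropy sort are resolved by `order()`'s stable sort; equal
  gaps never satisfy the strict gap inequality.
* All randomness flows from user-supplied seeds; a pipeline seed fans out
  to per-source seeds deterministically, and the caller's RNG state is
  always restored.

## Evaluation metrics

`correlation_coefficient()` (Pearson), `rmse()`, and two quantities whose
definitions vary across the literature and are therefore fixed explicitly
as this package's definitions: `snr_db(ref, est)` $= 10\log_{10}(\sum
\mathrm{ref}^2 / \sum(\mathrm{ref} - \mathrm{est})^2)$ and
`relative_error(est, ref)` $= \|est - ref\|_2 / \|ref\|_2$. Every
`evaluate_record()` row records what the reference was
(`ground_truth` in simulation; `pre_cleaning` when no clean reference
exists). `amari_index()` is the standard separation oracle: zero exactly
on scaled permutations, order $n$ for maximally mixed matrices.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data:
round-trip grids up to $2^{12}$ samples, ICA fixtures of $n = 20000$
samples (20 seeds), fuzzy-entropy oracle comparisons at $N = 300$
(50 series), and 50-seed end-to-end runs at the 60 s reference condition.
These sizes give stable statistics for every property tested while
keeping a full run in the minutes range on one CPU.

## Known limitations

* Instantaneous linear mixing is assumed; propagation delays between
  electrodes (convolutive mixing) are out of scope.
* The entropy-gap rule needs at least three separated components and
  assumes the non-cardiac components cluster in entropy; with exactly
  three channels it can only ever flag one component in exclusive mode.
* At heavy contamination the wavelet stage itself limits how closely the
  cleaned record can approach the uncontaminated truth: thresholding is
  nonlinear, so denoising a contaminated mixture differs from denoising
  the clean mixture even after perfect component removal, and the
  universal threshold grows with record length. End-to-end recovery
  numbers should be read with that ceiling in mind.
* One scalar per component family: the classifier cannot distinguish ECG
  from other highly regular artifacts (e.g. uncorrected mains hum), which
  would also be flagged as low-entropy components — arguably desirable,
  but it is not ECG-specific.
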