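---
title: "Dynamic brain functional networks from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain functional networks from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`dbfn` classifies affective state (valence/arousal, binarized at the
self-assessment midpoint) from the *topology* of functional brain networks
built on short time windows of multichannel EEG. The working hypothesis is
that emotion is accompanied by changes in inter-channel synchrony that are
visible at the second scale but washed out by a single static network over a
whole one-minute trial. The pipeline therefore compares a static analysis
(one network per difference signal per trial) against dynamic analyses with
windows of 10, 6, 3 and 1 s.

The processing chain per trial is:

1. **Preprocessing.** The per-channel mean of the leading 3-s baseline is
   subtracted from the final 60 s; peripheral (non-EEG) channels are dropped.
   A 32-channel, 128-Hz trial ends up as a 32 x 7,680 matrix.
2. **Rhythm decomposition.** Complex Morlet filtering into theta (4-8 Hz),
   alpha (8-12 Hz), beta (12-32 Hz) and gamma (32-42 Hz); amplitude envelope
   and instantaneous phase per channel and band.
3. **Inter-band difference signals.** For each of the 6 band pairs, the
   amplitude difference (higher minus lower band) and the wrapped phase
   difference: 12 channels x samples signals per trial.
4. **Windowing.** Non-overlapping windows of `t` seconds; `60 / t` windows
   per signal (one window in the static case).
5. **Connectivity.** For each window, histogram mutual information
   `MI = H_x + H_y - H_xy` (nats) between every channel pair; the diagonal
   carries each channel's marginal entropy.
6. **Binarization.** All `n^2` matrix entries are sorted ascending; the value
   at 1-based position `floor(q n^2)` is the threshold (position 307 of 1,024
   for 32 channels at `q = 0.3`), entries strictly above it become edges, and
   the diagonal is cleared. Thresholding is per matrix, so each network has a
   comparable edge budget despite inter-individual MI scale differences.
7. **Graph attributes.** Per network: global efficiency (1 value), local
   efficiency and clustering coefficient per node (`n` each), i.e. 65 values
   for 32 channels; `12 x (60/t) x 65` values per trial. The characteristic
   path length is computed but excluded from feature vectors because
   thresholded networks need not be connected.
8. **Classification.** mRMR selects `k` features on the training rows only;
   an SVM with repeated stratified 5-fold cross-validated grid search over
   (kernel, cost) predicts test-class probabilities, averaged over
   `n_repeats` repetitions.

Three evaluation designs are provided: *subject-dependent* (stratified 3:1
split within each subject), *subject-independent* (leave-one-subject-out,
LOSO) and *subject-and-trial-independent* (a held-out subject is tested on a
random half of the trial indices while training uses only the complementary
trial indices of the other subjects, so no trial index appears on both
sides). Paired per-subject accuracies are compared with a two-sided Wilcoxon
signed-rank test.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| bands | 4-8, 8-12, 12-32, 32-42 Hz | the four classical rhythms as used throughout the pipeline |
| Morlet bandwidth | spectral SD `(high-low)/4` | one wavelet per band, centred at the band midpoint; ~95% of kernel energy inside the band. Override with `cycles`. |
| `window_s` | 1, 3, 6, 10, 60 | sliding-window lengths; 60 s = static analysis |
| `n_bins` (MI) | 8 | equal-width histogram bins; 1-s windows have only 128 samples, so finer binning destabilizes the joint histogram |
| `q` | 0.3 | positional threshold fraction; 0.5 and 0.7 are the sweep values |
| `k` (mRMR) | 256 | selected features; a tuning knob, since the feature count (tens of thousands at `t = 1`) always dwarfs the trial count |
| mRMR binning | 3-level quantile | discretization for the selection MI only |
| SVM grid | C in `2^-5 ... 2^5`, linear + RBF | RBF width by the variance-scaled heuristic `1/(p Var(X))` |
| `n_repeats` | 100 | probability-averaging repetitions; desk-scale runs use 5 |

## Numerical choices and conventions

* **Morlet filtering** is performed in the frequency domain (Gaussian
  response on positive frequencies), which yields the analytic signal
  directly; each channel is reflect-padded by one wavelet length
  (six temporal SDs) and zero-extended to an FFT-friendly length. Phase is 0
  by convention where the amplitude is exactly zero.
* **Phase differences** are wrapped to `(-pi, pi]`; a flag disables wrapping
  because raw subtraction is an equally defensible reading.
* **Threshold ties** are discarded (`> threshold` retains an edge), so the
  retained-edge count is never inflated; an all-constant matrix yields an
  edgeless network.
* **Local efficiency** follows the standard Latora-Marchiori form: global
  efficiency of the neighbour-induced subgraph with the node itself excluded.
  The variant that keeps the node in its own subgraph is available via
  `include_node = TRUE`. Nodes of degree < 2 score 0, as do clustering
  coefficients.
* **Disconnected pairs** contribute `1/Inf = 0` to efficiencies.
* **mRMR ties** break to the lowest original column index, making selection
  deterministic and invariant to column shuffles.
* **Stratified splits** resample (bounded retries) until every class appears
  in the training part; the subject-and-trial protocol redraws its 20/20
  trial-index partition per held-out subject from a per-subject derived seed.
* **Wilcoxon** zero differences are discarded before testing; an all-zero
  comparison is flagged degenerate.
* All randomness flows through explicit integer seeds; derived seeds stay in
  32-bit range.

## The synthetic-data generator

No public affective-EEG corpus can ship with the package, so every stage is
validated on synthetic studies with *planted* coupling. Each channel carries
an intrinsic band-limited Gaussian oscillation (SD `osc_sd`); planted
coupling mixes shared band-limited sources into the coupled channels with
weight `coupling_strength`; broadband Gaussian noise (SD `noise_sd`) is
added. This shared-latent-source construction is the simplest mechanism
that provably raises mutual information on the coupled pairs. Per-subject
log-normal gain and noise multipliers (SD 0.2) emulate inter-subject
variability, which is what makes the subject-dependent and LOSO protocols
behave differently.

Planted edges are grouped into connected components and each component
shares one latent source — a synchronized community. Coupling can be gated
on/off in blocks of `gate_block_s` seconds, either at random (`gate_mode =
"random"`) or as a deterministic alternation (`"alternating"`, with a phase
offset), emulating second-scale, stimulus-locked coupling dynamics.

The reference study (`fixture_study()`) has 6 subjects x 20 trials,
16 channels, 60 s at 128 Hz. Its two classes differ in planted coupling
density — a 4-edge community on 4 channels (low valence) vs a 16-edge
community on 7 channels (high valence) — both alpha-band at strength 1,
`noise_sd = 0.2`, `osc_sd = 0.2`, with 2-s alternating gates in anti-phase
between the classes. Ratings are drawn from 2-4 vs 6-8 so label binarization
recovers the generating class. The truth graphs and gate schedules are fixed
design constants; the seed varies signals, subject effects and ratings only.

Two of these choices deserve explanation. First, `osc_sd` is small relative
to the coupling strength because amplitude envelopes are smooth: *every*
channel pair shows substantial within-window histogram MI, and a planted
community is only recoverable when its shared envelope dominates each
channel's independent envelope fluctuations. Second, the anti-phase gating
exists because the histogram MI of a full 60-s window is nearly noiseless:
any contrast that survives time-averaging — in particular a pure density
contrast with always-on coupling — is *fully* visible to the static
analysis, which then matches or beats every dynamic analysis on synthetic
data. Only genuinely second-scale structure (here, which half of each 4-s
cycle the coupling occupies) rewards fine temporal division, which is the
phenomenon the dynamic method exists to detect.

One limitation is measured and documented rather than hidden. Because the
class contrast includes a density difference, it never time-averages away
completely, and the 60-s histogram MI estimate is nearly noiseless, so the
static analysis retains most of the class information; meanwhile the graph
metrics of networks held at ~70% edge density by the positional threshold
are close to saturation, so a 1-s window yields only weak per-window
features (best single-feature AUC about 0.76 on this fixture) and the 1-s
analysis pays an irreducible histogram-MI variance price at 128 samples per
window. The measured LOSO means at the reference seed are about 0.73 (1-s),
0.99 (10-s) and 0.75 (static; its cross-subject transfer is erratic, with
occasional inverted held-out subjects): intermediate windows — long enough
for a stable MI estimate, short enough to resolve the 2-s dynamics — are
estimator-optimal. The shipped checks that expect 1-s accuracy to match or
beat the static and 10-s analyses therefore fail on those legs and are kept
as an honest record of this behaviour; reproducing the strictly monotone
shorter-window trend would require the nonstationary, non-ergodic structure
of real affective EEG, which this generator does not claim to emulate. What
the fixture does demonstrate end to end is planted-coupling recovery: the
1-s pipeline classifies held-out subjects far above the 99% binomial chance
band at every seed examined.

What the generator also does *not* emulate: volume conduction and reference
effects, 1/f broadband structure, artifacts, realistic rating distributions,
or any dipole/forward physics. Passing the synthetic recovery tests
therefore shows the pipeline is *capable* of extracting planted
connectivity differences end to end — it says nothing about effect sizes on
real recordings.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at desk scale: the
reference study above (120 trials of 16 channels), windows of 1 s and 60 s
(plus 10 s for the window-ordering check), the default `k = 256` selected
features and `n_repeats = 5` probability-averaging repetitions. These sizes
were chosen so a full run completes comfortably on a single CPU while
leaving the protocol logic identical to the full-scale configuration
(`n_repeats = 100`, 32 channels, 40 trials per subject). The selection size
matters at 1-s windows: the class signal there is spread over many weak
per-window features, so aggressive selection discards real evidence.

## Known limitations

* The MI estimator is the plain equal-width histogram plug-in; its positive
  bias (roughly `(B-1)^2 / 2N` nats) is shared by all pairs of a window and
  largely cancelled by the per-matrix positional threshold, but absolute MI
  values should not be interpreted.
* Amplitude-difference signals are strongly autocorrelated within short
  windows, so per-window MI values have few effective degrees of freedom;
  the pipeline compensates by aggregating over many windows and signals.
* The subject-dependent protocol on 20-trial synthetic subjects trains on
  only 15 trials against tens of thousands of candidate features; its
  absolute accuracy is noisy and it is included for protocol mechanics, not
  as a headline number.
* The channel-to-region map is a documented 10-20 convention
  (`deap_regions()`), replaceable by any named list or config file.
* The pickled-Python dialect requires a Python interpreter with numpy on the
  PATH (`DBFN_PYTHON` overrides).
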