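---
title: "Methods: replay, resting-state networks, and burst statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replay, resting-state networks, and burst statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(replayburst)
```

# The scientific problem

During rest, the brain spontaneously reinstates stimulus-specific
activity patterns in rapid, temporally compressed sequences ("replay").
Independently, whole-brain recordings can be segmented into recurring
resting-state-network (RSN) states — transient activity modes, each with
a characteristic spatial distribution of spectral power and coherence.
`replayburst` implements a complete, tested pipeline for asking how the
two phenomena relate in parcel-level multichannel recordings:

1. decode stimulus reactivations with sparse logistic classifiers
   trained on a functional localizer, and combine lagged pairwise
   reactivation probabilities into a replay probability trace;
2. infer K RSN states with a time-delay-embedded hidden Markov model
   (TDE-HMM);
3. test whether replay events evoke transient RSN-state activations
   (sign-flip cluster permutation statistics);
4. quantify the bursty temporal structure of replay and of state visits
   (Fano factors, interval-shuffle surrogates, state-conditioned
   inter-event intervals);
5. characterize states spectrally (state-conditioned multitaper power
   and coherence, NNMF frequency modes, high-frequency burst analyses).

Because suitable human recordings are not openly redistributable, the
package ships a first-class synthetic-data module that generates
fixtures with planted ground truth, so every stage of the pipeline is
testable end-to-end on a desktop.

# Models and statistics

## Replay decoding

For each stimulus $i$ a one-vs-rest L1-regularized logistic regression
is trained on the localizer features at a single peri-stimulus time
(chosen by cross-validation; 200 ms is both the generator's planted peak
and the default). Applied to resting data $X_t$, each decoder yields a
reactivation probability $\sigma(X_t \beta_i + b_i)$. For two ordered
4-item chains, the replay trace combines the six consecutive-pair joint
probabilities at lag $\tau$:

$$R_t = 1 - \prod_{(i \to j)} \bigl(1 - p_i(t)\, p_j(t+\tau)\bigr).$$

The source formula writes set operations ($\cap$, $\cup$) over
probabilities without defining their arithmetic; we read $\cap$ as the
product (independence) and $\cup$ as noisy-OR, the only closed-form
interpretation. Min/max fuzzy-logic readings were considered and
rejected as they destroy the gradient between weak and strong joint
evidence; the product/noisy-OR reading is the tested default.

$R_t$ is thresholded at the 99th percentile of its valid samples
(per-subject); events are the onsets of supra-threshold runs, merging
runs closer than $\tau$ samples. Event extraction is not further
specified in the source; run onsets are the natural choice because a
planted pair produces a contiguous excursion whose first sample is the
reactivation onset.

Lag-resolved *sequence evidence* is the mean lagged Pearson correlation
over task-ordered pairs minus the same mean over all other ordered pairs
(the control). A full GLM "sequenceness" analysis is out of scope; this
minimal cross-correlation statistic suffices to recover a planted lag.
Lags in ms are converted with `round(lag_ms * fs / 1000)`; the 10 ms
acceptance grid is not integral at 250 Hz, so rounding (rather than a
hard precondition) is used — the defining 40 ms / 250 Hz case stays
exact at 10 samples.

## TDE-HMM

Observations are time-delay embeddings: the column at time $t$ stacks
the window $X_{t-l:t+l}$ ($W = 2l+1$ samples, channel-major), so a
zero-mean Gaussian observation model
$P(\mathrm{vec}(X_{t-l:t+l}) \mid Z_t = k) \sim N(0, \Sigma_k)$
parameterizes each state by an embedded covariance — an implicit
description of per-channel spectra and cross-channel coherence. The
embedded data are PCA-reduced (default $2P$ components) before fitting.

Inference is multi-restart Baum-Welch EM (default 5 restarts, keep the
highest final log-likelihood). The source method uses stochastic
variational Bayes for multi-million-sample datasets and selects the
restart with the lowest free energy; at desk scale exact EM is the
appropriate substitute, and log-likelihood plays free energy's role for
restart selection. Numerical choices: random-responsibility
initialization per restart; covariance M-steps are ridge-regularized
only on near-singularity (condition number $> 10^{10}$), with the event
logged; convergence at relative log-likelihood change $< 10^{-6}$ or
500 iterations; bad-sample gaps split the chain into segments so no
transition is counted across them. Overlapping embedded windows violate
the observation-independence assumption; as in the source method this
is ignored for inference and noted here.

Defaults mirror the published constants where they exist (K = 12 for
full-scale analyses; fixtures use K = 4 for speed). The embedding
half-width $l = 7$ at 250 Hz (60 ms window) and the PCA dimension are
not printed in the source and are exposed as configuration.

`dual_fit()` freezes the state covariances and re-estimates only the
transition matrix and initial distribution on new data — the mechanism
for carrying canonical states to a second dataset or to localizer data.

## State labeling and visit statistics

From the transition matrix $\Theta$, self-transitions are removed
($\psi_{ij} = \theta_{ij} / (1 - \theta_{ii})$, zero diagonal), distance
is $d_{ij} = 1 - \psi_{ij}$, symmetrized
$\hat d_{ij} = (d_{ij} + d_{ji})/2$. The raw formula leaves
$\hat d_{ii} = 1$; we force the diagonal to zero before classical MDS
because a unit self-distance is a formula artifact that distorts the
embedding (for chain-like matrices the resulting order is insensitive to
this choice; the test suite checks the worked 3-state example under the
zeroed diagonal). States are labeled by their order along the first MDS
axis; the axis sign is fixed by making the largest-magnitude coordinate
positive, and exact ties break by original index — MDS orientation is
inherently arbitrary and the source states no rule, so this makes
labeling deterministic.

Visit statistics use the hard (Viterbi) path by default. A visit is a
maximal same-state run within a contiguous good segment; lifetimes of
visits truncated by bad segments or recording edges are excluded;
intervals are gaps between consecutive visit onsets of the same state.

## Spectral estimation

State-conditioned spectra cut hard-assigned state runs into complete
non-overlapping 2 s windows and average Slepian multitaper
cross-spectra per state (7 tapers, NW = 4 — implied by 2 s windows with
a 2 Hz half-bandwidth; 0.5 Hz grid; 1-45 Hz band). Coherence is
$|S_{xy}|^2 / (S_{xx} S_{yy})$. The source toolbox's soft-weighted
variant is deliberately out of scope; the hard-segment estimator is a
documented divergence and requires state visits of at least one window
length (the fixture world provides them).

The NNMF mode decomposition factorizes the matrix of all
(state, channel) power spectra and (state, channel-pair) coherence
spectra into nonnegative spatial loadings times spectral modes
(multiplicative updates, best of 10 restarts, modes sorted by spectral
centroid and normalized to unit mass for determinism). Two modes
separate a wideband component from high-frequency noise; three or four
resolve canonical delta/theta, alpha, and beta bands on suitable
fixtures.

Replay-evoked time-frequency maps weight each state's spectrum by the
non-baseline-corrected evoked state distribution
$B_{i,\tau,n}$ per subject, then average; the display baseline subtracts
each subject's time-mean. Coherence maps are thresholded with a
1-D 2-component Gaussian-mixture test: values are kept only if the
two-component fit beats a single Gaussian on BIC (EM happily splits a
unimodal sample into two halves whose means separate by ~1.6 SD, so a
separation rule alone cannot reject unimodal maps), the components'
means separate by more than one pooled standard deviation, and
posterior membership in the upper component exceeds 0.5.

High-frequency analyses reuse the multitaper machinery on a 600 Hz
wideband twin: state-conditioned PSD over 1-160 Hz, and replay-evoked
PSD in 30 ms event-centered windows (3 tapers, NW = 2; the ~33 Hz
resolution is recorded in the output metadata) against a baseline from
event times shuffled across subjects, preserving per-subject counts.
The 102-148 Hz summary band follows the source's choice, which excludes
power-line harmonics; the generator plants no line noise, so the band
is honored rather than needed.

## Evoked statistics

State posteriors are baseline-corrected by subtracting each subject's
session mean, epoched $\pm 0.5$ s around events (epochs touching edges
or bad data are dropped entirely; the exact epoch-exclusion rule is not
stated in the source), and averaged. Cluster statistics: lags with
group one-sample $t > 3$ form clusters whose mass is their length (the
source counts consecutive supra-threshold points, not summed t); the
null is the maximum cluster length under 5000 random per-subject sign
flips; $p = (\#\{\text{null} \ge \text{obs}\} + 1)/(n_{perm} + 1)$, so
$p$ is never zero and the minimum attainable value at 5000 permutations
matches a reported bound of $2 \times 10^{-4}$. Tests for evoked
increases are one-sided; condition comparisons (replay at lag 0 versus
localizer at the training time) are two-sided paired t tests with a
Bonferroni flag, computed on baseline-corrected values by default.
The replication ("inflexible cluster") test takes a cluster window from
dataset A, sets the threshold to the minimum dataset-B t inside it, and
asks for the permutation probability of an equally long cluster
anywhere in B at that threshold.

The percentile-threshold sweep repeats the lag-0 evoked computation for
thresholds at every percentile 1-99: variance-driven artifacts are
symmetric about the median, genuine coupling loads the high
percentiles, summarized by the asymmetry (value at the 99th minus value
at the 1st percentile).

## Burst statistics

For events in non-overlapping windows of length $W$,
$F_W = \sigma_W^2 / \mu_W$; 1 for Poisson, $> 1$ for bursty trains.
Windows are anchored at the recording start; trailing partial windows
are dropped; windows containing bad samples, or samples belonging to an
inter-event interval that overlaps bad data, are dropped (the source
excludes whole bad-crossing intervals; whether it dropped or rescaled
windows is unstated — dropping is our choice). The default grid is 30
log-spaced lengths from 0.1 to 30 s (the source grid, ~100 lengths, is
not printed; ours covers the "10 s or more" regime it highlights).

The IID-interval null is tested by interval shuffling: surrogate trains
permute each subject's inter-event intervals (first event preserved,
interval multiset exact), and the observed group Fano curve is compared
with the per-window maximum over 1000 surrogates ($p < 10^{-3}$ where
exceeded). State-visit burstiness treats visit onsets as events, with a
per-window one-way ANOVA across states (Bonferroni over windows) and
per-state two-sample t tests against the pooled remaining states,
reporting the largest p over windows, as in the source's convention.
Inter-replay intervals conditioned on the active state (argmax
posterior at the event sample) drop bad-crossing intervals and cells
with fewer than 10 observations.

# The synthetic world

The generator's defaults are a fixed stated world, not tuning knobs:

* 21 virtual subjects, 300 s at 250 Hz, 12 channels, plus a 600 Hz
  wideband twin; two 1 s bad segments per subject exercise the
  bad-data paths.
* K = 4 states with sticky Markov switching. States 1-2 (the
  replay-coupled pair, analogous to parietal-alpha and DMN networks)
  carry coherent 10 Hz and 3 Hz oscillations on channels 1-4 and 5-8;
  state 3 carries 25 Hz on channels 9-12; state 4 is unstructured.
  Oscillation amplitude 1.6, white noise SD 0.5.
* The transition matrix gives states 1-2 ~2 s visit lifetimes with rare
  entry, states 3-4 ~0.8 s, and 25% stationary occupancy of the coupled
  pair. Two stated-world constraints drove the dwell times: the
  hard-segment multitaper needs visits of at least one 2 s window, and
  coupled bouts of ~3 s give replay the multi-second clustering whose
  Fano curve rises toward the long-window regime.
* Replay events are a two-rate Markov-modulated Poisson process: 3 Hz
  during states 1-2, 0.1 Hz elsewhere — the minimal process that is
  Poisson conditionally yet rejects the IID-interval null. At each
  event a stimulus pattern and its task successor are planted 40 ms
  apart, each lasting 12 ms, with gain 3 relative to the localizer
  patterns. The source does not state reinstatement strength or
  duration; these values were calibrated once so planted effects are
  recoverable (the explicit design goal for the fixtures) and then
  frozen: with stronger/longer patterns the sigmoid saturates and the
  99th-percentile threshold ties at 1.0; at rate 3 Hz the top-1% sample
  budget (750 of 75 000 samples) covers ~250 events only if each
  excursion spans ~3 samples. This also caps achievable recall near
  0.85 — a structural property of percentile thresholding, documented
  rather than hidden.
* The localizer has 8 stimuli, 160 trials, Gaussian response envelopes
  peaking at 200 ms (SD 50 ms), peak SNR 1.
* High-frequency bursts: 102-148 Hz band-limited noise (SD 1) added to
  channels 5-8 of the wideband twin only during state 2.
* Every stochastic operation takes an explicit seed; the pipeline
  derives per-subject seeds as `base_seed + subject_index`.

What the generator does **not** emulate: realistic MEG forward models,
sensor noise covariance, head movement or ocular artifacts, line noise,
1/f background spectra, or source leakage. A green test therefore
establishes that the algorithms recover what they claim from data
obeying their assumptions — not that a particular neural effect exists,
nor that preprocessing of real recordings is handled.

# Design decisions on open points

* **Per-subject thresholding** of $R_t$ (not pooled): downstream
  statistics are per-subject, and the source is silent on pooling.
* **Event matching tolerance** in recovery metrics is ±2 samples (8 ms
  at 250 Hz).
* **Serialization**: no HDF5 bindings are available in the target R
  environment, so fixtures round-trip through a plain-text container
  (TSV matrices + JSON metadata) with the same fields; the pipeline
  writes TSV/JSON artifacts. The pipeline configuration is JSON.
* **Degenerate inputs**: constant decoder traces contribute zero
  correlation to sequence evidence (logged); constant replay traces
  yield zero events with a warning; states never visited yield empty
  statistics; a state with no complete spectral window yields NaN
  spectra with a message; Fano values from fewer than two windows are
  NA.

# Known limitations

* The hard-segment spectral estimator needs state visits longer than
  the taper window; brief states (as real MEG RSN states often are)
  require the out-of-scope soft-weighted estimator.
* EM inference is exact but quadratic in the embedded dimension and
  linear in T; multi-million-sample datasets would need the stochastic
  variational machinery that is deliberately out of scope.
* The Bernoulli thinning in the event generator permits at most one
  event per sample; at the default rates (≤ 3 Hz at 250 Hz) the
  distortion is negligible.
* Peak-frequency recovery from state-conditioned multitaper spectra is
  exact only for noiseless tones: the NW = 4 spectral window is
  approximately flat over its 2 Hz half-bandwidth, so in noise the
  argmax wobbles within one or two 0.5 Hz bins by design.
* In NNMF band-separation fixtures, near-noiseless channels are
  counterproductive: shared spectral sidelobes keep coherence high far
  outside the planted band, so moderate white noise (SD ~0.3 against
  unit-amplitude components) is part of the stated fixture world.
* Percentile thresholding ties recall to the event rate, as quantified
  above.
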