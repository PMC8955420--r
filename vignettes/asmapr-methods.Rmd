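---
title: "asmapr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{asmapr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(asmapr)
```

This vignette records the model, the numerical choices, and the design
decisions behind `asmapr`, in the spirit of a statistical-methods appendix:
what is computed, under which assumptions, and what the bundled synthetic
test bed does and does not establish.

## 1. The feature model

### Differential entropy as a log band-power feature

Each channel of a pre-cleaned EEG recording is cut into contiguous,
non-overlapping 1-s epochs (trailing partial epochs discarded). Per epoch
and frequency band we estimate the band power $P$ and define the
differential-entropy feature through the Gaussian closed form

$$\mathrm{DE} = \tfrac{1}{2}\,\ln(2\pi e\,P)\ \text{nats}.$$

The continuous entropy $h(X) = -\int f \ln f$ of a band-limited Gaussian
signal with variance $P$ equals exactly this expression, which is why DE
behaves as a calibrated logarithmic band-power feature. Two consequences
are load-bearing and tested: *scale equivariance*
($\mathrm{DE}(a\,x) = \mathrm{DE}(x) + \ln a$) and the *unit anchor*
($P = 1\,\mu V^2 \Rightarrow \mathrm{DE} = \tfrac12\ln 2\pi e \approx
1.4189$).

Band power comes from a per-epoch Hann-windowed periodogram, zero-padded to
`n_fft` points (default 256). The periodogram is normalised by the window
power $\sum w^2$ so that the sum over all frequency bins estimates the
signal variance (Parseval-consistent; tested against the time-domain
variance of white noise at 5%). A frequency bin belongs to band
$(\ell, h)$ iff $\ell \le f \le h$ — the five canonical bands delta (1–3),
theta (4–7), alpha (8–13), beta (14–30) and gamma (31–50 Hz) have gaps, and
bins in a gap belong to no band. Band power is the *sum* of member-bin
powers; whether one sums or averages only shifts DE by a per-band constant,
which cancels in every downstream difference feature and in min–max
normalisation. Epochs longer than `n_fft` samples are split into
`n_fft`-point frames whose periodograms are averaged.

Two estimator properties are worth knowing. First, with 1-s windows the
Hann mainlobe (≈ 2 Hz wide) smears energy across the edges of the narrow
low bands, so absolute delta/theta power is biased low by tens of percent;
the bias is common to all channels and cancels in the asymmetry features,
which is the reason the package's generator-calibration tests measure band
variance with an exact FFT brickwall rather than the 1-s periodogram.
Second, powers below $\varepsilon = 10^{-12}\,\mu V^2$ are clamped before
the logarithm so silent fixtures yield finite DE rather than $-\infty$.

DE series are optionally smoothed along the epoch axis with a centred
moving average (default span 5 epochs; the span is not prescribed by the
reference design, which only states that moving-average smoothing is
applied). The window shrinks symmetrically at the series edges, and
smoothing never crosses recording boundaries. Span 1 is exactly the
identity.

### Windows and the AsMap

DE features of $n$ consecutive epochs are grouped into non-overlapping
windows (3/6/12/30 s canonically; any positive multiple of the epoch
length is accepted) and averaged, giving one $C \times K$ DE matrix per
window. The AsMap for window $w$ and band $k$ is the complete pairwise
difference table

$$\mathrm{AsMap}(i, j, k) = \mathrm{DE}(i, k) - \mathrm{DE}(j, k),$$

a $C \times C \times K$ tensor with an exactly zero diagonal and exact
antisymmetry. It is invariant under any common gain applied to the input
recording (the $\ln a$ shifts cancel), which is tested. For CNN input each
band slice is min–max scaled to $[0,1]$; antisymmetry then becomes the
complementarity $v_{ij} + v_{ji} = 1$.

Decisions made where the reference design is silent:

* **Normalisation scope is per band slice**, not per tensor: it preserves
  inter-band contrast and makes single-band and all-band runs consistent.
  (Whether the original normalisation was per band or global cannot be
  determined from the source; either is a one-line change.)
* **A constant slice normalises to 0.5** — the midpoint keeps
  $v_{ij} + v_{ji} = 1$ true degenerately.
* **Row/column order is the montage's channel order**, fixed by
  configuration, because the CNN's spatial weights must mean the same
  channel pair across files. Loaders reorder file channels by name.

### Baselines

DE (flattened channel-major, band-minor), DASM, RASM and DCAU are computed
from the same windowed DE matrix. Pair features are ordered pair-major,
band-minor following the montage's pair lists. With the packaged
62-channel montage and five bands the lengths are 310, 135, 135 and 115.
Every DASM and DCAU entry is *identical* (not approximately equal) to the
raw AsMap entry at the pair's indices — an invariant the acceptance suite
checks exactly. RASM divides DE values that can be near zero in nats, so
divisors within $10^{-9}$ of zero are replaced by $\pm 10^{-9}$ and the
ratio capped at $\pm 10^9$, with a `capped` flag in the result.

The packaged montages are configuration files, not code. The 62-channel
file follows the SEED distribution order with 27 hemispheric and 23
frontal–posterior pairs (chosen to reproduce the published feature
dimensions; the source literature cites but never prints the lists — this
is an assumption, flagged in the file comments). The 32-channel DEAP-style
montage has 14 hemispheric and 11 frontal–posterior pairs.

## 2. Labels

Three schemes: `seed3` (negative/neutral/positive from codes −1/0/+1),
DEAP-style binarisation of 1–9 valence/arousal ratings at 5.5, and the
four-quadrant cross-product (HVHA/HVLA/LVHA/LVLA). Both published rating
intervals contain 5.5; the boundary is assigned to the *high* class
(`>=`), documented here because some reimplementations choose `>`.
Trial-level labels are assigned to every window of the trial; the
window-to-label mapping is not specified at the source and this is the
only interpretation consistent with the experiment design.

## 3. The classifier

Architecture (fixed by the reference design): conv 3×3 → ReLU → maxpool
2×2 → dropout 25% → conv 3×3 → ReLU → maxpool 2×2 → dropout 25% → flatten
→ dense 512 → dense 512 → softmax, with 32 and 16 feature maps. Decisions
made where the design is silent:

* **Valid (no) padding and floor division in pooling.** The flatten length
  is then $\lfloor(\lfloor (H-2)/2\rfloor - 2)/2\rfloor^2 \cdot 16$: 3136
  for 62×62 inputs, 576 for 32×32. Inputs smaller than 10×10 leave an
  empty map after the second stage and are rejected with the failing stage
  named.
* **Training recipe** (entirely unspecified at the source): Adam at
  learning rate $10^{-3}$, batch 64, at most 50 epochs, stratified 20%
  validation split, early stopping on validation loss with patience 5 and
  best-weight restoration. Chosen for single-CPU reliability; all of it
  is `train_config()` surface.
* **Split protocol**: stratified random split over windows by default.
  Because windows of one trial are correlated, the harness also offers a
  grouped split (`holdout_split(..., type = "grouped")`) holding out whole
  trials, which is the honest subject/trial-independent protocol; the
  published evaluation protocol cannot be recovered from the source, so
  the choice is exposed rather than hidden.
* **Implementation**: no deep-learning backend exists in the target
  environment, so the network is implemented natively on BLAS matrix
  operations (im2col GEMM convolution in an (H, W, N, C) internal layout;
  inverted dropout; deterministic inference). The backward pass is
  verified against central finite differences to ~1e-9 relative error in
  the test suite. The training seed fully determines initialisation,
  split, batch order and dropout masks, so runs are reproducible on one
  machine; across BLAS builds, floating-point summation order may differ.

Baseline feature vectors bypass the conv stack and feed the same two-layer
dense head directly, as in the reference comparison.

## 4. The synthetic test bed

The simulator stands in for the access-restricted emotional-EEG datasets.
Each channel is a sum over bands of Gaussian noise, brickwall band-passed
in the frequency domain (zero-phase) and rescaled to an exact target
variance, plus a broadband white floor. Class effects multiply one band's
target power on a channel subset.

The stated world (defaults): 200 Hz, 60-s trials, 62-channel montage, base
band powers delta 20, theta 10, alpha 8, beta 4, gamma 2 μV² (decreasing
with frequency, as in scalp EEG), broadband floor 1 μV², and a gamma-band
effect on the left-hemisphere channels with gains 0.5/1.0/2.0 for the
three classes, five trials per class. Gamma is the effect band because
high-frequency asymmetry is where the reference experiments found the
discriminative signal. With these settings an affected left–right pair's
expected raw AsMap gamma entry is $\tfrac12 \ln g$ — the module's
parameter-recovery property, checked at $g = 3$ against
$\tfrac12\ln 3 \approx 0.549$. (The broadband floor adds equal power to
both channels of a pair, diluting the realised ratio slightly below the
configured gain; at the default floor this bias is ≈ 0.03 nats, well
inside the ±0.1 acceptance tolerance, and it is a property of the stated
world, not of the estimator.)

Per-trial seeds derive from the master seed by an affine counter kept
inside the 32-bit range, so datasets are reproducible and no two trials
collide. What the simulator does *not* model: 1/f spectral shape beyond
the band staircase, volume conduction (channels are independent given
their band powers), non-stationarity, artifacts, or any topographic
structure beyond the left/right effect assignment. A green classification
test therefore establishes that the pipeline recovers class-conditioned
hemispheric band-power asymmetry end to end — not that it reproduces
published accuracies on real data, which the package explicitly does not
claim.

## 5. Numerical and degenerate-input conventions

* Epoching and windowing use floor rules; trailing partials are discarded
  everywhere, never padded.
* Band edges are inclusive on both sides; analysis bands beyond Nyquist
  are rejected by name.
* EDF output quantises to the 16-bit grid over a ±500 μV physical range
  (≈ 0.015 μV steps), widening automatically if the data exceed it; HDF5
  round trips are bit-identical; CSV carries 9 significant digits.
* Max-pooling ties resolve to the first element in (row, column, cross)
  order — relevant only on exactly-tied inputs such as constant AsMaps.
* A constant AsMap slice (perfectly symmetric DE) yields all-0.5 inputs
  and finite CNN features; RASM guards its divisor as described above.

## 6. Known limitations

* The native CNN is CPU-scale: fine for C ≤ 64 channels and a few hundred
  windows, not for GPU-scale experiments.
* The spectral estimator is the reference design's (1-s Hann, 256-point
  FFT); absolute narrow-band powers inherit its leakage bias, though all
  asymmetry features cancel it.
* The packaged pair lists are a documented reconstruction, not a published
  table; users with a definitive montage should load their own config.
* MAT-file adapters for the original datasets' export format are out of
  scope (no MAT reader in the dependency footprint).
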