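---
title: "Bio-Opto-Acoustic analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bio-Opto-Acoustic analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boatools)
```

This vignette is the package's own account of the science it implements:
the otolith oscillator model, the video-tracking estimator, the whole-brain
calcium pipeline, and the synthetic world used to test all three. It states
no empirical result that the test suite or the acceptance script does not
itself compute.

## The oscillator model

BOA stimulation oscillates an optical trap across an otolith, driving it
sinusoidally inside the intact ear. Newton's law for a body bound to hair
cells (elasticity constant $k$) and immersed in ear fluid (viscous drag
coefficient $\gamma$), solved in the Fourier domain, gives

$$x(f) = \frac{F(f)}{k + i\,2\pi\gamma f}$$

with an optional inertial term $-m(2\pi f)^2$ in the denominator that is
neglected by default — at the relevant scales drag and stiffness dominate,
and the measured curves do not resolve a mass term. The model predicts a
low-frequency plateau $F/k$, a corner at $k/(2\pi\gamma)$, a $1/f$
high-frequency asymptote, and phase falling from 0° to −90°. During real
acoustic stimulation what matters is the otolith's motion *relative to the
body*, giving the effective acceleration
$a_\mathrm{sound} = (1 - \rho_f/\rho_{ot})\,a$: the otolith's high density
relative to the ear fluid is what makes the ear sensitive.

### Fitting

`fit_mechanics()` minimizes squared residuals of **log**-amplitudes with
equal weight per frequency point. Measured curves span decades in both
axes; fitting in linear amplitude would let the plateau points dominate
and effectively ignore the high-frequency tail that determines $F/\gamma$.

Key numerical choices:

* **Identifiability.** Amplitudes alone constrain only $F/k$ and
  $F/\gamma$; the interface reports those ratios and returns absolute
  $\gamma, k$ only when the caller supplies $F$. Nothing is silently
  assumed about how the drive force was calibrated.
* **Parameterisation and scaling.** Internally $|x|^{-2} = u^2 + v\omega^2$
  with $u = k/F$, $v = (\gamma/F)^2$. Because $v \sim u^2/\omega_{max}^2$
  the two parameters differ by many orders of magnitude, so the optimizer
  (`nlminb`) runs on $(\log u, \log v)$. Two analytic starts are tried —
  the exact linear-least-squares seed for $A^{-2}$ (which is already the
  global optimum for noiseless data) and the plateau/half-power heuristic —
  and the lower objective wins.
* **Degenerate inputs.** A curve with no measurable decay drives $v$ to its
  floor; the fit then flags `gamma_zero`, reports `F_over_gamma = Inf` and
  the plateau as $F/k$. Fewer than two distinct positive-amplitude
  frequencies is an error, as is an all-equal two-point curve.

## Tracking and amplitude estimation

Otolith motion is recovered by cross-correlation registration refined by a
locally upsampled DFT around the coarse correlation peak (default
`upsample_factor = 100`, i.e. 0.01 px, which is sub-nanometre at a
100 nm/px pixel size). Every frame is registered against a **fixed**
reference (the first frame), not a running reference, so registration noise
does not accumulate as drift. Images are mean-subtracted before
correlation; a zero-variance frame is a hard error rather than a silent
(0, 0).

The displacement trace is summarized two ways:

* `compute_spectrogram()` — magnitude STFT of the stimulation-axis
  component with a 1 s Hann window and 50% overlap. One-second windows make
  1 Hz bins, so the standard stimulation frequencies (10, 100, 400,
  1000 Hz) fall exactly on bins. Hann was chosen for its leakage behaviour
  when the task is detecting narrow stimulus-locked lines; window and hop
  are exposed. The `per_frequency` normalization divides each frequency row
  by its own time mean, which flattens the $1/f$ background so
  stimulus-locked lines stand out; it is the documented interpretation of
  "normalized over frequency", which the source material does not define
  precisely. The trace is mean-detrended first, suppressing the step
  artifact that stray trap light adds at stimulus onset/offset.
* `estimate_amplitude()` — the vibration amplitude at the stimulation
  frequency over one epoch, $A = 2|X(f)|/\sum w$ from the Hann-windowed
  Fourier coefficient. On-grid frequencies use the bin directly; off-grid
  frequencies use a 3-point quadratic interpolation of $|X|$ around the
  peak. Mean subtraction makes the estimate invariant to constant offsets.

## The synthetic world

The generators define the package's stated test conditions; their defaults
are fixed once and the tests are written against them.

**Videos.** A disc of radius 20 px in a 64×64, 16-bit frame at
1000 frames/s, translated along the image-column (rostro-caudal) axis.
Default ground-truth amplitudes follow the measured displacement scale:
140 nm at 10 Hz, and 50 nm (saccule) / 15 nm (utricle) at 400 Hz, at a
pixel size of 100 nm/px. Edge pixels are anti-aliased by 8× supersampling
(naive rasterization quantizes subpixel motion and breaks tracking), and
the frame is then blurred by a Gaussian PSF (`psf_sigma = 0.7` px). The PSF
is not cosmetic: the rendered translation must be *band-limited* for
correlation registration to be unbiased, and a hard-edged disc is not —
without the blur, above-Nyquist edge energy attenuates recovered 0.15 px
motion by ~17%. A real microscope's optics impose exactly such a cutoff.
Photon noise (Gaussian counts, default off) and heartbeat-like background
drift (a ~2 Hz sinusoid plus a 1/f component, amplitude default 0) are
opt-in; the noise-on acceptance condition uses 100-count noise on a
9000-count disc and 100 nm drift. Rounding to integer counts is part of
the model (a camera quantizes).

**Calcium datasets.** Six fish × 2000 ROIs at 4 Hz (the volumetric rate of
a 25-plane × 10 ms scan; `volume_rate()`), over the default stimulus train:
{utricle, saccule, both} × {1, 10, 100, 1000 Hz} plus a 100 Hz speaker
tone, three 1 s trials per configuration with 4 s rest, preceded by 30 s of
baseline. The exact trial composition of the original protocol is not fully
printed anywhere, so this grid is an explicit, configurable assumption.
Two response profiles are planted: a broad profile responding to every
configuration with a 3× (super-additive) dual-otolith response, and a
saccule-specific low-frequency profile (1–100 Hz plus the tone); 5% of
ROIs each, the rest non-responders. Responses are GCaMP6s kernels
(difference of exponentials, rise 0.2 s, decay 3.5 s, peak-normalized —
"typical GCaMP response" values from the nuclear-GCaMP6s literature,
exposed in the spec). Profile amplitude scales (1.0 and 2.27 z-units) are
calibrated so that responders sit at $r^2 \approx 0.5$ against the
regressors at unit noise — the stated operating point of the recovery
tests. Seeds are explicit fields; identical specs give identical datasets
and the caller's RNG stream is never disturbed.

What a green test does **not** establish: the synthetic world has no
optics/PSF model beyond the Gaussian blur, no correlated (shot) noise, no
motion artifacts, no overlapping-source demixing errors, no anatomical
structure, and its planted clusters are exactly kernel-shaped. Recovery
here validates the estimator chain, not the biology.

## The calcium pipeline

The analysis follows the whole-brain procedure: pool traces across fish,
z-score each trace (zero-variance traces are excluded with a message —
they cannot be z-scored), then joint OLS of every trace on one regressor
per stimulus configuration plus intercept. Per-configuration regressors
(rather than one global stimulus column) are what allow clusters to be
distinguished by configuration-specific responses. Under the null, $r^2$
has mean $p/(n-1)$, which the tests verify; the conservative pre-selection
keeps $r^2 \ge 0.2$ (boundary inclusive), the within-cluster refinement
keeps $r^2 > 0.4$ (strict, reading "above 0.4" literally). Both are
configurable.

Clustering is k-means with the **cityblock** distance: Lloyd iterations
with component-wise *median* centroid updates (the L1-optimal centroid),
best of 5 random restarts by total within-cluster L1 cost, empty clusters
re-seeded from the farthest point. It is implemented in C++ because the
stated scale (≈1,200 selected traces × 900 frames × 120 clusters × 5
replicates, across 20 seeds) is not tractable in pure R within the
pipeline's runtime budget.

Cluster-level criteria:

1. *GCaMP6s profile responsivity*: the centroid must correlate with the
   tone regressor at ≥ 0.5 **within the tone-epoch response windows**
   (onset to offset + 2 s). A whole-trace correlation against the sparse
   tone-only column is mathematically capped near 0.27 for a centroid that
   also responds to the twelve other configurations — the criterion is
   about the *shape* of the tone response, so it is evaluated where that
   response lives.
2. *1 SD above baseline*: the centroid's peak in every tone epoch must
   exceed baseline mean + 1 SD. "Baseline" is pooled from the pre-stimulus
   rest and all frames ≥ 3 s after any epoch end and before the next
   onset; the source procedure does not define it, so this is the
   documented choice.
3. *Cross-fish representation*: the stated criterion ("less than 90% of
   the ROIs within the cluster are represented in each individual fish")
   is grammatically ambiguous. The default reading is a dominance cap — no
   single fish may contribute ≥ 90% of a cluster — with the alternative
   (every fish must be represented, a representation floor) switchable via
   `selection_thresholds(fish_criterion = "representation_floor")`.

Whether "responsive to tones" means the speaker epochs only or all 100 Hz
epochs is also unstated; the default is speaker epochs (`tone_targets`).
Peak responses are maxima over `[onset, onset + duration + 2 s]` — the lag
captures the indicator decay at 4 Hz sampling — and the super-additivity
index is mean(both) − mean(utricle) − mean(saccule) over trial peaks at one
frequency; positive means the dual stimulation drives the response beyond
the sum of its parts, which is exactly the planted structure of the broad
synthetic profile.

Pooling happens after per-trace z-scoring; because the statistics are
per-trace, z-score-then-pool and pool-then-z-score-per-trace coincide.

## Interfaces and determinism

Image stacks travel as uncompressed 16-bit grayscale multi-page TIFF
(a minimal reader/writer is built in — no installed package provides one —
and is cross-checked against an independent Python reader in the tests);
traces, curves and spectrograms as CSV; trains, configurations and
summaries as JSON. `run_command()` materializes every default into a
resolved config written next to its outputs, so a run can be reproduced
bit-for-bit from its own artifacts; summaries carry no timestamps.

## Known limitations

* Only the main-text oscillator model is implemented; any supplementary
  force decomposition or mass treatment is out of scope (the mass term is
  available behind `mass = TRUE` but off by default).
* Units of $\gamma$ and $k$ are whatever is consistent with nm and Hz; no
  absolute force calibration is attempted.
* Registration handles translation only — no rotation, scale, or
  multi-otolith joint tracking.
* The TIFF subset is deliberately small: uncompressed grayscale 8/16-bit.
* Desk-scale k-means at k = 120 on ~1,200 planted-structure traces
  necessarily shatters the two true profiles into many subclusters; the
  recovery tests therefore score ROI membership of the *union* of retained
  clusters, and super-additivity on the subclusters whose majority label is
  the planted super-additive profile.
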