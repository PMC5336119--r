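---
title: "Models and methods behind the eitproc pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the eitproc pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitproc)
```

# The measurement model

Electrical impedance tomography (EIT) drives a sinusoidal current of amplitude
$I$ and frequency $f$ through one pair of electrodes while sampling the
voltage on all electrodes in parallel. A *measurement* is the demodulated
amplitude (the modulus) of one electrode's voltage during one injection,
averaged over a chosen number of carrier periods; a *frame* is one complete
pass over the ordered list of injection pairs (the *protocol*). A frame of a
protocol with $p$ pairs on $e$ electrodes holds $p \times e$ measurements, or
$p(e - 2)$ after the two injecting electrodes are excluded.

`eitproc` implements the full software layer of such a system: a sample-level
simulator of the raw recordings, trigger decoding and segmentation,
demodulation, frame assembly and quality control, stimulus-triggered coherent
averaging, multi-frequency spectroscopy, and a linear difference-imaging
reconstruction — each stage usable on its own.

# The synthetic-recording generator

`simulateRecording()` synthesises the voltage on electrode $k$ during an
injection through pair $j$ at carrier $f$ as

$$ v_k(t) = \big(I\,Z_{jk}\,g(f)\,d(f) + w_k(t)\big)\,
   \sin\!\big(2\pi f (t - t_0)\big) + \varepsilon_k(t), $$

with $Z_{jk}$ the signed transfer impedance of the phantom, $g(f)$ the
amplifier's anti-aliasing magnitude gain, $d(f)$ an optional tissue-dispersion
gain, $w_k$ a per-channel random-walk amplitude drift, $\varepsilon_k$
additive white Gaussian noise, and $t_0$ the injection onset — the carrier
phase is reset at every switch, as a current source slaved to a trigger link
does. Controller events (injection start/stop, pair switches, frequency
changes, stimuli, out-of-compliance flags) are emitted at exact sample indices
and encoded as 16-bit values (low byte event class, high byte payload) held
for four samples on an integer status channel, the convention of EEG trigger
inputs.

Deliberate idealisations, and hence the limits of what a passing test shows
about physical hardware: electrode-skin contact impedance, amplifier
common-mode effects, mains interference and quantisation noise inside the
amplifier are not modelled; the anti-aliasing filter acts as a per-carrier
gain rather than a sample-domain filter (a gain curve is also how it is
corrected in post-processing); drift is the simplest nonstationary model — a
Gaussian random walk on each channel's carrier amplitude — chosen because the
reference behaviour it must reproduce (whole-record SNR degrading while
100-frame block SNR stays flat) depends only on nonstationarity, not on the
drift's fine structure.

## Noise calibration

For additive white noise of per-sample standard deviation $\sigma$, the
demodulated amplitude estimated as the mean Hilbert envelope over an
$N$-sample window has standard deviation $\sigma\sqrt{2/N}$, independent of
the band-pass bandwidth (the in-phase narrowband noise component, averaged
over the window). `whiteSdForDemodSd()` inverts this relation;
the property suite verifies both the $1/\sqrt{N}$ scaling and the absolute
constant by Monte-Carlo. This is how the end-to-end characterisation run is
pinned to a demodulated noise SD of 0.356 uV.

## The packaged phantoms

Two constructed transfer tables ship under `inst/extdata` (both labelled
synthetic). `phantomFixture("head16")` pairs with the 34-injection, 16-electrode
protocol: it is the package's own 2D FEM disc solution, monotonically rescaled
in log-amplitude (two parameters) so that at 100 uA and 2 kHz — through the
default first-order 3.2 kHz front end — exactly 363 of 544 channels clear the
250 uV rejection threshold and the retained channels have a geometric-mean
amplitude of 2.66 mV. The geometric mean is the right anchor because the
summary SNR is the mean of per-channel decibel values. The rescaling preserves
channel ordering and signs but not exact reciprocity; reciprocity tests use
`femPhantom()` directly. `phantomFixture("scalp32")` (31 pairs, 32 electrodes)
is a single global scaling of its FEM solution — hence exactly reciprocal —
placing 540 of 930 non-injection channels above 1 mV at 160 uA.

# Segmentation and demodulation

Segmentation replays the protocol against the decoded trigger events: a
frequency-change event opens a block (and the block's first injection), each
pair-switch the next injection. The first and last 10% of every injection span
are trimmed before measurement (`settleFraction`); fractional trimming adapts
across the 5 Hz–20 kHz carrier range where a fixed cycle count would not.
Spans overlapping an out-of-compliance event are kept but flagged invalid.

Demodulation is a zero-phase (forward–backward) Butterworth band-pass centred
on the carrier — order 5 by default, full bandwidth `min(carrier, 1 kHz)` —
followed by the Hilbert envelope and unwrapped phase of the analytic signal.
A time-resolution consequence the tests check at order-of-magnitude level:
a 1 kHz bandwidth resolves impedance steps with a rise time of a couple of
milliseconds. Two numerical details: the filter design is rejected if any
pole modulus reaches 1 (narrow bands at very low carriers need a lower order,
which the measurement functions expose); and analytic signals on lengths with
a large prime factor are computed on the next 2-3-5-smooth length and
truncated, because the mixed-radix FFT degenerates on such lengths — the
padding perturbs only the span edges, which the trim already discards.
The simultaneous low-frequency (EEG-band) signal is recovered from the same
raw channel by a zero-phase low-pass below the carrier band.

Phase is referenced to zero at the injection onset (where the simulator resets
the carrier) and reported alongside the modulus; imaging uses amplitudes only,
but the phase's sign (`cos` of it, for a resistive load) is what lets
reciprocity and time-difference imaging recover *signed* differential voltages
from moduli.

# Quality metrics

Per retained channel over a frame range: noise is the SD across frames, also
expressed as $100\,\mathrm{SD}/\mathrm{mean}$ percent and as
$20\log_{10}(\mathrm{mean}/\mathrm{SD})$ dB (capped at a 200 dB sentinel when
the SD is exactly zero); summaries are means ± SD over channels. The rejection
mask is computed from across-frame mean amplitudes so the channel set is
stable over a recording — drift and block-SNR series need a fixed set, and the
published channel counts (363, 540) are fixed numbers. Drift is the absolute
change between the first and last 100-frame block means (block size
configurable). The reciprocity error of a matched pair of injections —
disjoint electrode sets, voltage read across the other pair's electrodes — is
$100\,|1 - V_{\mathrm{small}}/V_{\mathrm{large}}|$ with the larger magnitude
in the denominator, which makes the metric symmetric in the two directions;
the convention with the swapped measurement in the denominator would give
0.990% instead of 1.010% for a 1% mismatch, and the symmetric choice removes
that asymmetry.

# Triggered (coherent) averaging

Stimulus events carry a uniformly random offset with respect to the carrier
phase (the simulator jitters each stimulus by $U(0, 1/f)$), so carrier
artefacts average out rather than accumulate. Epochs of the continuously
demodulated amplitude are cut around each stimulus; epochs crossing an
injection boundary or an out-of-compliance event are dropped and counted. The
evoked change is the trial mean minus its pre-stimulus baseline mean (10 ms by
default); $\sigma_{\mathrm{pre}}$ is the SD of the *averaged* trace in the
baseline window, because the triggered SNR is defined on the averaged signal;
a channel is significant when its peak $|\delta z|$ within the post-stimulus
search window (0–50 ms by default — onset and disappearance of somatosensory
responses bracket it, but no canonical window exists) exceeds
$3\sigma_{\mathrm{pre}}$. Trials are never re-weighted or artifact-rejected.
Note the false-positive rate of the 3-sigma rule grows with the width of the
search window (a max over more samples); the suite checks the single-sample
rate against a Monte-Carlo oracle and the monotonicity in window width. The
simulator's carrier-residual ablation (phase-locked stimuli) is not modelled
separately; the randomisation's effect is validated through the phase
uniformity of stimulus times and the $1/\sqrt{N}$ law of the averaged
baseline.

# Multi-frequency operation and spectra

Multi-frequency frames keep per-frequency injection durations of 32 carrier
periods below 200 Hz, 64 between 200 Hz and 1 kHz, and 128 above 1 kHz
(`periodsForFrequency`), so low frequencies do not dominate the frame period;
injected current can be halved below 200 Hz via a supplied lookup
(`amplitudeForFrequency`), a policy value rather than a hard-coded law.
Rejection masks are unioned across frequencies so every frequency sees the
same channel set. Frequency-difference datasets subtract the reference
frequency's amplitudes after dividing out the declared anti-aliasing gain
curve, leaving only the load's dispersion.

Sweep-mode spectra pool electrode means over repeated orderings (ascending,
descending, random) and report the relative change versus the reference
frequency — by default the lowest measured one. The dispersion generator
(`dispersionModel`) is an exponential-saturation drop calibrated so the
decrease from the declared reference frequency to the target frequency is
exactly the declared fraction (15% at 250 Hz for the healthy-tissue-like
default; ischaemic tissue is shallower, near 7%); its corner frequency
(60 Hz) sets the "non-linear" curvature of the drop. Whether two-terminal
measurements (voltage on the injecting pair) are pooled is configurable;
the default is four-terminal only.

# Reconstruction

The imaging chain is deliberately desk-scale: a structured 2D triangular disc
mesh with point electrodes (a few hundred P1 elements) replaces
million-element 3D head models, preserving the algorithmic content — adjoint
sensitivity matrix, zeroth-order Tikhonov inversion, cross-validated
hyperparameter, noise-based correction — at sizes where brute-force oracles
(finite-difference Jacobians, exhaustive reciprocity) can check every piece.
The complete-electrode model, layered head geometry and absolute imaging are
out of scope.

The forward problem $\nabla\!\cdot\!(\sigma\nabla u) = 0$ is assembled once
per mesh with a cached Cholesky factorisation; voltages are referenced to zero
mean over electrodes, and the matching adjoint source for a measurement
electrode is a unit current balanced by $-1/E$ on every electrode. The
sensitivity of measurement $m$ to element $e$ is
$J_{me} = -A_e \nabla u_{\mathrm{drive}}\!\cdot\!\nabla u_{\mathrm{meas}}$;
the suite checks it against central finite differences (max error below
$10^{-4}$ of the largest entry) and the discrete sensitivity-sum identity
$\sum_e J_{me}\sigma_e = -V_m$.

The inverse is $\hat{\delta\sigma} = \arg\min \|J\delta\sigma - \delta v\|^2 +
\lambda\|\delta\sigma\|^2$ via the normal equations. $\lambda$ is chosen by
k-fold (default 10) cross-validation over measurement rows with seeded fold
assignment, ties broken toward the larger (more regularised) value; the grid
is 20 points log-spaced over $[10^{-8}, 1] \cdot
\mathrm{tr}(J^\top J)/n_{\mathrm{elem}}$. Noise-free data select the smallest
grid values; heavier noise moves the choice up — both are property-tested.
Cross-validation over frames instead of rows, and leave-one-out, are
reasonable variants; k-fold over measurements is the declared choice.

The noise-based correction is defined here as a projected-noise z-score map:
the per-measurement noise covariance is propagated through the linear inverse
operator $R = (J^\top J + \lambda I)^{-1} J^\top$, each element's
reconstruction divided by its pure-noise SD, and elements with $|z|$ below 3
zeroed. Under a pure-noise null the surviving fraction matches the Gaussian
0.27% expectation in the suite. "Noise-based correction" has no single
standardised form in the EIT literature; this z-score map is the package's
own concrete definition, flagged here as an interpretation.

Time-difference imaging subtracts the mean of a reference frame block from
later frames using *signed* amplitudes (sign from the phase), and divides by
the phantom scale where the Jacobian was computed at unit conductivity.

# Problem sizes and seeds

All simulations in the test-suite and the acceptance script are sized for a
single CPU: the characterisation run uses the full published design (34 pairs,
16 electrodes, 100 frames of 3.4 s at 16 kHz — about 5.4 million samples);
sweeps use six frequencies between 20 and 250 Hz with at least 50 periods
each; reconstruction meshes have 112–352 elements. Every stochastic step takes
an explicit seed, and seeded runs are bit-reproducible (the RNG state is saved
and restored around each simulation; stimulus jitter uses a derived substream
so a zero-amplitude transient leaves the voltage data bit-identical to the
non-triggered simulation).

# Known limitations

* Point electrodes and 2D geometry: absolute voltage scales are not
  comparable to 3D heads; only the pipeline's relative behaviour is.
* The anti-aliasing filter's true order/shape for any particular amplifier is
  rarely published; `gainFilter` offers first-order, Butterworth-n and
  sinc-power-n magnitude models, and the filter-match error of a physical rig
  is not a reproducible target.
* Hardware-bound accuracy figures (reciprocity error of a physical phantom,
  in-vivo SNR) are represented by their computational contracts only.
* Real-time/streaming demodulation is not implemented; processing is
  post-hoc.
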