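---
title: "Laminar LFP analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar LFP analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hipplamina)
```

This vignette explains the science implemented by `hipplamina`: the
signal models behind each analysis, the parameters that matter and their
defaults, what the synthetic session generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## Signal model and conventions

All analyses run at an internal sampling rate of 1250 Hz; wide-band
acquisition (typically 20 kHz) is decimated with an 8th-order Chebyshev
type I anti-aliasing filter applied forward and backward. Two properties
of that filter are worth knowing: it is applied zero-phase, because
every downstream analysis (event latencies, phase estimates) is
meaningless under group delay; and, being an even-order Chebyshev-I
design, its pass band sits up to the ripple (0.05 dB per pass, about
1.1% for the double pass) below unity — a constant input emerges scaled
by the squared DC gain, not exactly unchanged. Band-pass filtering is a
4th-order Butterworth, also forward–backward, with odd-reflection end
padding so edges carry no startup transient.

One phase convention holds package-wide: 0° at the oscillation peak, 90°
at the descending zero-crossing, 180° at the trough, 270° ascending.
Hilbert-transform phases and the theta control-point phase both follow
it, so a neuron firing near theta troughs has a mean phase near 180°.

## Event detection

**Sharp-wave ripples.** The detection channel (pyramidal layer, chosen
as the channel maximising the ripple-band score: Welch power 100–250 Hz
over 70–300 Hz, 4-s Hann windows, 50% overlap) is referenced against a
ripple-free channel, filtered at 80–250 Hz plus a 200–500 Hz control
band, and the Hilbert envelope thresholded at five times its overall
median — "overall" meaning the full analysed epoch, not per window, so
detection is invariant to global gain. Peaks within 20 ms merge to the
highest; onset/offset are the half-threshold crossings; and each
candidate must pass four checks (detection-channel ripple power at least
twice the reference's; mean frequency, computed as unwrapped-phase span /
360 / duration, above 100 Hz; at least four cycles; ripple-band power at
least twice the control band's). The envelope is not smoothed before
peak-picking. In tetrode mode (no ripple-free reference exists) the
referencing and the first check are skipped.

**Dentate spikes.** Detected during rest epochs only — the caller crops
the recording first; running on awake data inflates the 7×median
absolute-value threshold with theta power. Candidate peaks above
P75 + 20·IQR of the peak distribution are discarded as artifacts
(computed per channel), channels are pooled, and a 50-ms dedup keeps the
highest peak. Classification computes each event's CSD vector from the
pyramidal channel to the deepest DG channel at the event peak, projects
onto the first principal component, splits with a two-component Gaussian
mixture, and assigns DS1 to the class whose mean-CSD sink is shallower
(further from the hilus); coincident sinks label everything DS1.

## Theta: masked EMD and cycle phase

Plain band-pass filtering distorts the asymmetric theta waveform, so
theta is isolated by masked empirical mode decomposition: six mask
frequencies (350, 200, 70, 40, 30, 7 Hz), mask amplitude three times the
SD of the whole input series computed once, four mask phases averaged per
IMF. IMF-6 is the theta component, and the decomposition is complete by
construction (IMFs + residue = input to machine precision). Sifting uses
natural cubic-spline envelopes through extrema with endpoint clamping,
stopping when the mean-envelope energy falls below 5% of the residual's
or after 8 iterations.

Cycles are candidate peak–trough–peak triplets whose extrema exceed the
envelope of the decomposition residue (the gate is applied to the
extremum magnitude; the comparison side was unspecified and this is the
conservative reading). Validity requires half-cycles of 31–100 ms and
periods of 71–200 ms; validity is per-cycle, so a valid cycle may adjoin
an invalid one. Phase interpolates linearly between the five control
points; per-cycle phase spans exactly 360° even for asymmetric waveforms,
which makes the *occupancy* of phase bins non-uniform — precisely the
bias the spike-coherence normalisation corrects.

## CSD and layer landmarks

The CSD is the negative second spatial difference (sinks negative), then
Gaussian-smoothed along depth with σ = 50 μm (σ in channel units is
50/spacing; kernel truncated at 4σ, renormalised at the edges) to
standardise spatial resolution across probes. Landmarks: `pyr` by ripple
power; `rad` by the strongest sink at the ripple-envelope peak between
`pyr` and the fissure; `hf` by theta (5–12 Hz) power; `l-m` 40–50 μm
above the fissure; `omol`/`mmol` as the deepest DS1/DS2 sinks below the
fissure; `imol` as the secondary sharp-wave sink below the fissure; `gr`
as the strongest dentate-spike source strictly below `mmol` (the search
range "beneath the molecular layers" was open; strictly-below-`mmol` is
the narrowest reading). Landmarks violating the dorsoventral ordering are
dropped with a warning rather than silently reordered.

## The waveform embedding

Each channel contributes two z-scored mean waveforms: 500 ms around
ripple-envelope peaks and 150 ms around the descending zero-crossings of
*pyramidal* theta (the descending zero-crossing is the alignment point
that balances jitter between peak and trough). z-scoring removes gain, so
the embedding sees waveform *shape* only. PCA is applied separately to
the two banks (four components each) to balance their dimensionality,
and the concatenated 8-D points are embedded with ISOMAP: a k = 15
neighbourhood graph with Euclidean edge weights (disconnected components
bridged by their shortest connecting edge), geodesics by Dijkstra's
algorithm, classical MDS of the geodesic matrix. Channels are first
resampled to a common 50-μm depth step per subject by nearest-channel
selection (not waveform interpolation — the channels are *sampled*).

**Out-of-sample projection** is the one genuinely invented component:
the source method projects tetrode features into the embedding but the
extension is unspecified. We use the standard Nyström/kernel extension:
geodesic distances from a new point to all training points are estimated
through its k nearest training neighbours
(`d(x, i) = min_j ||x − x_j|| + D[j, i]`), then plugged into the
double-centred MDS kernel. For a training point this reproduces its
fitted coordinate exactly, which the tests assert.

**Trajectory.** Layer centres (across-subject means) are connected in
anatomical order; between each adjacent pair, `floor(distance /
point_spacing)` intermediate control points are added (the count rule's
rounding was ambiguous — its own worked cases force `floor`), each the
across-subject average of anatomically equidistant channels' fitted
coordinates. The default `point_spacing = 20` is meaningful only
relative to the embedding's scale, which varies between fits; the fitted
diameter is stored in the model and the trajectory-building helper takes
the spacing as an argument (the validation suites use `diameter / 40`).
A quadratic interpolating B-spline through the control points, sampled
densely, gives the polyline, its arc-length table, and each layer's
linearised position. Linearised positions of *layer centres* are
anatomically ordered on synthetic data; individual-channel positions
within CA1 saturate in places, because z-scored shape features cannot
distinguish channels that differ only in the *amplitude* of a shared
waveform component — micro-steps of a simulated tetrode inside one layer
therefore do not always project monotonically, while layer-scale descent
does, matching the intended use (targeting layers, not micrometry).

**Layer decoding** uses uniform-weight leave-one-out k-NN (k = 4,
matching the smallest per-layer sample size), a row-normalised confusion
matrix, and mutual information in bits against a label-shuffle null.
The deep/superficial split of linearised positions fits a two-component
1-D Gaussian mixture and thresholds at the interior intersection of the
weighted component densities, warning when the component means are
closer than half the pooled SD.

## Theta-nested gamma

Morlet spectrograms use 24 logarithmically spaced frequencies (18–310
Hz) and L1-normalised kernels, so amplitudes compare across frequencies.
The wavelet width is 6 cycles — unspecified in the source and exposed as
a parameter, since it trades frequency against time resolution. Profiles
average amplitude in 36 theta-phase bins (10°; also a choice, validated
as stable under refinement to 72), excluding samples outside valid
cycles, and are reported both raw and min-normalised per frequency.

Fast gamma is isolated spatially: ICA (a seeded symmetric FastICA with
tanh contrast, estimated on a uniform time subsample and applied to the
full trace) over channels within 200 μm of the target; components with a
global Welch spectral peak above 100 Hz *and* at least 1% of the channel
variance qualify (the variance floor keeps whitened noise-floor
components from qualifying); the strongest is returned, sign-aligned to
the target's 100–250 Hz band. Burst main frequencies take the envelope
maximum per theta cycle, keep the top quartile, and average spectrogram
columns in 40-ms windows around the retained peaks. Speed modulation is
the least-squares slope of log2 mean-normalised amplitude across six
equally populated speed quantiles; per-cycle speed is the mean over the
cycle (the speed estimator was unspecified; smoothed finite differences
over 250 ms are used when deriving speed from position).

## Spike-train statistics

The waveform score is the mean over the 32 template samples of
(mean/SD)²; the printed formula renders ambiguously, so a square-root
variant sits behind a flag, with the mean-of-squares reading as default
and the 0.75 gate applying to whichever is configured. QC also fails
units with > 2% of inter-spike intervals under 2 ms or a positive-polarity
template. Cell type comes from the trough-to-peak latency of the
100×-quadratically-upsampled template, thresholded at the intersection
of a two-component Gaussian mixture (the threshold ships as a procedure,
not a frozen constant).

Spike-phase coherence divides the 64-bin spike-phase histogram by the
gated phase-occupancy histogram before computing the mean vector length —
without this, theta's asymmetric dwell times inflate apparent locking to
the falling phase (the tests construct exactly this null and require the
corrected MVL to vanish). Gates: gamma analyses keep samples above the
75th envelope percentile; ripple analyses keep within-event samples; at
least 250 gated spikes are required. Significance uses spike-shift
surrogates: each spike is reassigned to a random sample matching its
theta phase within one 10° bin and its gamma amplitude within one decile
(the matching tolerances are invented — the source says "matching"
without numbers), and p is the fraction of 10,000 surrogate coherences
at or above the observed. Mean phases always come from the continuous
phase domain, never from trigger-aligned averages. Trough-triggered
averages take one trough per theta cycle (the deepest), keep the top
quartile by depth, and bin spikes at 2 ms over ±100 ms — one trigger per
cycle avoids inflating rhythmicity through the band-pass filter.

## Resampling

Bootstrap CIs are percentile intervals (0.5th–99.5th) over resampled
means; permutation tests shuffle group labels and double the one-tailed
p for two-tailed use; the laser-response test swaps baseline/response
rates per trial with probability one half and requires both the 99th
percentile of that null and a 2-SD rate increase. Defaults follow the
canonical 100,000 resamples; the validation suites run at 10,000 (and
1,000–2,000 for the type-I calibrations), which leaves the percentile
estimates' Monte-Carlo error well below the tolerances being asserted.
Whether the laser null should swap per trial independently or permute
trial labels globally was open; independent per-trial swaps are used.

## The synthetic generator

`generate_session()` builds: 1/f background noise (exponent 1, 15 μV SD);
awake theta with a slowly wandering frequency (8 ± 0.7 Hz), a
phase-distortion asymmetry (coefficient 0.3) making falling phases
longer than rising ones, amplitude peaking at the fissure with a
secondary molecular-layer bump, and phase reversing ~180° across the
fissure then drifting a further ~70° toward the granule layer; rest-epoch
SWRs (0.25 Hz) with a radiatum-negative sharp wave reversing at the
pyramidal layer, a delayed dentate component (inner-molecular sink,
infragranular source), and a 140-Hz, ~6-cycle ripple on the pyramidal
channel; two dentate-spike classes (0.25 Hz each) with molecular-layer
sinks at omol/mmol and a granular source; per-layer theta-phase-gated
gamma bursts; and inhomogeneous-Poisson units with von Mises theta
coupling and SWR gain. Default durations are 360 s awake + 240 s rest
(a 10-minute session); the embedding suites use four 180 + 180 s
subjects, sized so that mean waveforms are stable (~35 SWRs, ~1400
cycles each) while the whole validation run stays lightweight.

What it does *not* emulate: spatially correlated noise, electrode drift,
behavioural state transitions, realistic spike waveform variability
across channels, volume-conducted cortical rhythms, or the real data's
exact spectra. Passing tests on it therefore demonstrates that the
algorithms recover known structure under laminar geometry and realistic
SNR — not that they are robust to every artifact of real recordings.

Two validation-design notes. The gamma-burst phase-recovery check uses a
symmetric-theta configuration (`theta_asym = 0`): with an asymmetric
waveform the "true" phase of an injected burst differs between the
analytic-signal and control-point phase conventions by up to ~15°, so
the ground truth itself would be convention-dependent; asymmetry is
instead exercised by the occupancy-normalisation null. And the
trajectory-consistency null calibration draws trajectories as
random-phase Fourier series, making the observed pair exchangeable with
its phase-shift surrogates by construction — the condition under which
the z-score should be (and is) standard normal. Both trajectories are
randomised independently per surrogate draw, the stricter of the two
possible nulls.

## Numerical choices and degenerate inputs

Welch estimates demean each segment; the analytic signal comes from the
FFT half-spectrum method; peak dedup is greedy from the highest peak;
ties in channel argmax selections resolve to the lower (more dorsal)
index; `count_cycles` rejects negative phase spans; constant input to
the masked EMD returns zero IMFs and the constant residue; a constant
speed vector is an error (quantiles undefined); mixture fits use mclust
with the density intersection solved by root-finding between the
component means, falling back to the midpoint when no interior sign
change exists. The discrete Fréchet distance is computed in C++ (the
surrogate calibrations evaluate ~10^5 distances); trajectories are
resampled to 100 arc-length-equidistant points before comparison, and
identical trajectories report infinite similarity rather than an error.

## Known limitations

Sleep/wake scoring is out of scope (epochs are caller-supplied); the
embedding's absolute scale — and hence the literal trajectory point
spacing — is configuration, not a constant; NWB/Neuropixels-native
input is not supported (the bundled reader uses a simple serialized
matrix + JSON sidecar layout); and spike sorting is consumed, never
performed.
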