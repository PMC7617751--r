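# hipplamina

Laminar analysis of hippocampal local field potentials (LFPs) along the
CA1-to-dentate-gyrus (DG) axis, for electrophysiologists working with
linear silicon probes or independently movable tetrodes.

A probe spanning CA1 and the DG records a stereotyped laminar sequence of
network events: sharp-wave ripples (SWRs) whose sharp wave reverses
polarity across the pyramidal layer while a 100–250 Hz ripple rides the
pyramidal channel; theta (5–12 Hz) whose amplitude peaks at the
hippocampal fissure and whose phase reverses across it; and dentate
spikes (DS1/DS2), brief DG deflections whose current sinks sit in the
outer vs mid molecular layer. `hipplamina` turns those signatures into
quantitative tools:

* **Event detection** — SWRs from the ripple-band envelope (threshold
  5× its median, 20-ms peak merge, onset/offset at half threshold) with
  four physiological acceptance checks (reference-power ratio, mean
  frequency > 100 Hz from the unwrapped Hilbert phase, ≥ 4 cycles,
  control-band power ratio); dentate spikes at 7× the median absolute
  1–200 Hz signal with an artifact bound of P75 + 20·IQR, classified into
  DS1/DS2 by PCA of per-event CSD vectors and a two-component Gaussian
  mixture.
* **Theta** — masked empirical mode decomposition (mask frequencies
  350/200/70/40/30/7 Hz, mask amplitude 3×SD); IMF-6 is theta. Cycles are
  delineated peak–trough–peak with interval rules (half-cycles 31–100 ms,
  periods 71–200 ms) and a residue-envelope amplitude gate, and phase is
  linearly interpolated between five control points (peak = 0°,
  descending zero = 90°, trough = 180°).
* **Current source density** — `CSD_n = −(LFP_{n−1} − 2·LFP_n + LFP_{n+1})`
  with 50-μm Gaussian depth smoothing, and CSD-based anatomical
  landmarking of eight layers (pyr, rad, l-m, hf, omol, mmol, imol, gr).
* **Waveform embedding** — per-channel mean SWR (500 ms) and theta
  (150 ms) waveforms, individually z-scored; PCA (4 + 4 components);
  2-D ISOMAP (k = 15, Dijkstra geodesics); a cross-animal trajectory
  through layer centres with arc-length linearisation; Nyström
  out-of-sample projection for tetrode placement; leave-one-out k-NN
  layer decoding with mutual-information validation; deep/superficial
  splitting by a Gaussian-mixture density intersection.
* **Theta-nested gamma** — L1-normalised Morlet spectrograms (24 log
  frequencies, 18–310 Hz), phase-resolved amplitude profiles, spatial-ICA
  isolation of fast gamma, burst main-frequency estimation, and speed
  modulation (log2 slope across six speed quantiles).
* **Spiking statistics** — waveform-score QC, trough-to-peak cell-type
  classification, occupancy-normalised spike-phase coherence (64 bins),
  spike-shift surrogate tests matched on theta phase and gamma amplitude,
  and trough-triggered firing averages.
* **Resampling** — bootstrap percentile CIs (0.5–99.5%), permutation
  tests, and the optogenetic laser-response test.
* **Synthetic sessions** — a laminar generator with full ground truth
  (event times, layer map, unit coupling parameters), so the entire
  pipeline is testable end to end without restricted data.

## Worked example

```r
library(hipplamina)

sess <- generate_session(session_spec(seed = 1))   # 10-min, 32-channel session
rec  <- sess$rec

pyr <- select_reference_channel(rec)               # ripple-band score argmax
swr <- detect_swr(rec, pyr, ref_ch = 1)
head(swr[, c("t_peak", "n_cycles", "mean_freq")], 3)
#>     t_peak n_cycles mean_freq
#> 1 363.6208 4.545479  138.5817
#> 2 372.1400 5.186938  144.0816
#> 3 383.0000 5.836113  137.6442

rest <- sess$truth$epochs[2, ]
ds <- detect_dentate_spikes(crop_recording(rec, rest$t_start, rest$t_end),
                            sess$truth$dg_channels, top_ref = 1)
ds <- classify_ds(ds, crop_recording(rec, rest$t_start, rest$t_end),
                  pyr_ch = pyr, dg_deep = max(sess$truth$dg_channels))
ds$t_peak <- ds$t_peak + rest$t_start
table(ds$ds_class)
#> DS1 DS2
#>  62  55

landmark_layers(rec, swr, ds)
#>  pyr  rad  l-m   hf omol mmol imol   gr
#>    7   11   14   15   17   19   21   24
```

Each detected SWR reports its envelope-peak time, cycle count from the
unwrapped ripple phase, and mean intra-event frequency (cycles/duration;
an event of 6.75 cycles in 50 ms is 135 Hz). The layer map gives the
channel index of each anatomical landmark; here it recovers the
generator's ground truth exactly.

The full pipeline (`run_pipeline()`, or the `inst/cli/hipplamina.R`
front-end) chains ingestion, detection, theta extraction, landmarking and
profile computation, and writes CSV/JSON artifacts plus a run manifest.

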