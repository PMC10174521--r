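---
title: "Detecting second-messenger signaling events with dynamic regions of interest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting second-messenger signaling events with dynamic regions of interest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynroi)
```

## The problem

Fluorescence recordings of second messengers — Ca²⁺ indicators, cAMP FRET
biosensors — show transient signals whose footprint grows, shrinks, moves,
merges and splits over time. Measuring them inside a fixed polygon (a static
ROI) underestimates signals smaller than the polygon and overestimates
signals that outgrow it. `dynroi` instead segments the recording itself and
tracks each event's changing perimeter: a *dynamic* region of interest.

## The detection model

The input is a five-axis intensity array $U(c, t, z, y, x)$ of arbitrary
units. The pipeline applies, in order:

1. **Temporal smoothing.** Every pixel trace is smoothed along $t$ with a
   Savitzky–Golay filter of polynomial order 3,
   $U_{\text{smooth}} = \mathrm{SG}_t(\text{order}, \text{window})\,U$.
   The filter is a local least-squares polynomial fit; boundary frames are
   handled by evaluating the polynomial fitted to the first/last full
   window at the boundary positions (fit-and-extrapolate). We deliberately
   avoid mirror padding so that an event starting near the first frame is
   not reflected into spurious pre-onset signal.
2. **Background subtraction.** The per-pixel temporal minimum of the
   *smoothed* stack is subtracted:
   $U_{\text{filt}} = U_{\text{smooth}} - \min_t U_{\text{smooth}}$.
   Static fluorescence (cell outlines, uneven illumination) vanishes; every
   pixel trace afterwards has minimum exactly zero.
3. **Blurring and thresholding.** Each frame is blurred in $xy$ with a
   Gaussian of width $\sigma$ ($V = G_\sigma * U_{\text{filt}}$), and a
   binary mask is formed, $V_{\text{bin}} = V > \theta$, with $\theta$
   chosen from the intensity histogram by the Yen (default), Otsu or
   Triangle criterion, either globally per channel (default) or per frame.
4. **Masking and accumulation.** $U_{\text{mask}} = U_{\text{filt}} \odot
   V_{\text{bin}}$ (Hadamard product), and the per-voxel sums over time
   $V_{\Sigma} = \sum_t V_{\text{bin}}$, $U_{\Sigma} = \sum_t
   U_{\text{mask}}$ are kept for visualization and site-frequency analysis.
5. **Site labelling.** Active voxels are grouped into 4-D connected
   components over $(t, z, y, x)$ — *sites* — under face connectivity (8
   neighbours in 4-D; full 80-neighbour connectivity is selectable).
   Components with fewer than `min_event_voxels` voxels (default 8) or
   spanning fewer than `min_event_frames` frames (default 2) are treated as
   noise and discarded; set both to 1 to disable.
6. **Dynamic ROIs and metrics.** Each site is sliced into per-frame
   cross-sections (the dynamic ROI), yielding per-frame area, centroid and
   mean intensity, and per-event descriptors: amplitude *delta f*, duration,
   maximal area, starting slice, bounding box, origination site, and
   convergence/divergence topology.

Because the ROI follows the signal, there is no static baseline region and
the conventional $f/f_0$ normalization is undefined. Amplitude is therefore
reported as **delta f**: the maximum over frames of the cross-section mean
of the background-subtracted intensity (a peak-single-voxel variant is
available via `amplitude_method = "peak_voxel"`). The cross-section mean is
the default because it is stable against single-voxel noise.

Convergence and divergence are read off the shape of the 4-D site: per-frame
spatial components are linked across consecutive frames by voxel overlap;
two or more branches mapping onto one is a merge (the event is flagged
*convergent* and the incoming branches recorded as parents of the merged
branch), one branch mapping onto several is a split (*divergent*, with
daughter branches). Reversing the time axis exactly swaps the two roles — a
property the test suite exercises.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sg_order` | 3 | polynomial order of the temporal filter |
| `sg_window` | `"auto"` | odd window length in frames; `"auto"` = nearest odd to $T/20$, clipped to $[5, 31]$ |
| `blur_sigma` | 0.35 px | $xy$ Gaussian width before thresholding |
| `threshold_method` | `"yen"` | `"otsu"` and `"triangle"` selectable |
| `threshold_mode` | `"global"` | one threshold per channel; `"per_frame"` for drifting baselines |
| `threshold_bins` | 4096 | uniform histogram bins for the threshold search |
| `min_event_voxels` | 8 | minimum site size in voxels |
| `min_event_frames` | 2 | minimum temporal span in frames |
| `connectivity` | `"face"` | 4-D neighbourhood (8 vs 80 neighbours) |

The `"auto"` window rule is a heuristic for recordings whose signal band is
unknown: it preserves transients spanning at least ~5% of the recording.
When the band *is* known, pass a window matched to it — the validation
harness fixes `sg_window = 41` because its synthetic pulse has a temporal SD
of 10 frames (FWHM ≈ 23 frames), and a cubic window of about twice the FWHM
maximally suppresses noise while passing the pulse essentially unattenuated.

### Why Yen, a small blur, and a fine histogram

These defaults were calibrated on the synthetic pulse family before the
validation statistics were frozen, and the reasoning is worth recording:

* **Global Otsu is bistable on noise-dominated stacks.** When active signal
  occupies a fraction of a percent of the voxels, the between-class variance
  criterion has two competing maxima: cutting the background noise mode in
  half, and cutting between noise and signal. Below SNR ≈ 5 the middle
  split frequently wins, marking ~half of all voxels active. Yen's entropic
  criterion — which the method offers as its "more stringent" option — cuts
  the noise tail reliably across the whole SNR range, so it is the default.
  (We verified our Otsu/Yen/Triangle implementations bit-for-bit against
  scikit-image on shared arrays.)
* **Blur trades low-SNR pooling against high-SNR halo.** At SNR ≤ 2 a small
  spatial blur is physically necessary: after temporal filtering the noise
  maximum over ~450 000 background voxels still overlaps the per-voxel
  signal amplitude, and only spatial pooling separates them. But a blur of
  σ ≥ 0.55 px pushes the half-maximum halo of a sharp-edged signal above
  threshold at high SNR, systematically inflating detected areas by 2–4
  pixels. σ = 0.35 px sits in the stable window between the two failure
  modes.
* **4096 histogram bins.** With 256 bins the Yen threshold's placement at
  low SNR is quantized coarsely enough that it occasionally jumps above the
  signal plateau, losing most of an event. A finer histogram removes those
  catastrophic misses without affecting behaviour elsewhere.
* **Tie-break on flat maxima.** On noiseless data the histogram has exactly
  empty gaps between intensity bands, and the Otsu/Yen objective is exactly
  constant across such a gap. The threshold is taken at the *midpoint* of a
  flat maximal plateau, keeping it clear of both class boundaries; with a
  unique maximum (any noisy data) this is ordinary argmax and matches
  scikit-image exactly.
* **Noiseless data use Otsu.** On binary movies the background is an exact
  zero atom and Yen's criterion collapses towards it, capturing the faint
  shoulders left by temporal smoothing. Otsu lands mid-range between
  background and signal, which (with the midpoint tie-break) recovers the
  binary events voxel-exactly. `validate_polygonal()` therefore defaults to
  Otsu with `blur_sigma = 0` and size filters disabled.

## The synthetic ground-truth harness

Two generator families emulate the validation data; both are first-class,
seeded, and return machine-readable truth manifests.

**Noiseless polygonal scenarios** (`generate_polygonal_dataset()`): a fixed
catalogue of 15 binary sequences (60 frames, 64×64) jointly containing
exactly 57 events across six scenario classes — concentric growth/decay,
unidirectional propagation, periodic pulse trains (each pulse a separate
temporally contiguous event), convergence (two blobs drifting together and
merging), divergence (its time reverse), and static blobs. Two catalogue
invariants matter for exact recovery: every pixel of every event is active
for at least 2 consecutive frames (a window-5 cubic temporal filter reduces
a single-frame pixel to 17/35 of its amplitude, below any mid-range
threshold — so single-frame pixels are unrecoverable by design), and the
growth/decay scenario grows by adding concentric square rings but decays by
removing rings from the centre outwards, so that per-frame areas are
strictly unimodal while respecting the 2-frame dwell. On this dataset the
pipeline attains 100% recall with zero false positives and voxel-level
Jaccard 1.0 per event.

**Gaussian pulses in noise** (`generate_pulse_stack()`): 181-frame, 50×50
stacks of i.i.d. Normal(1, 1) background noise (not clipped at zero) plus a
temporally Gaussian pulse — peak amplitude $A$ at frame 90, temporal SD 10
frames — over a centred 6×5-pixel (30 px) footprint. With unit noise SD the
amplitude equals the SNR. `run_snr_sweep()` varies SNR, runs the full
pipeline per replicate, matches the detected site overlapping the footprint
(largest overlap), and reports the percent error of the detected spatial
spread at peak signal intensity — the cross-section area at the site's
frame of maximal summed intensity — against the 30-pixel truth. The
maximal per-frame area is recorded alongside; it is an extreme-value
statistic over ~40 active frames and is biased upward by single stray
voxels, which is why the peak-intensity frame, the quantity the ground
truth is defined at, is the one scored.

`cmd_validate()` pools percent errors over SNR > 1. At the study scale (18
SNR values from 1.5 to 10, 10–20 replicates each) the mean lands near 0.7%
with an SD near 2%: errors are zero for SNR ≥ 2.5 in almost every
replicate, and the residual dispersion comes from occasional ±1–3 voxel
misestimates at SNR 1.5–2, the regime where single-voxel detection is below
the noise ceiling. Below SNR 1 detection degrades sharply — the matched
area collapses or the pulse is missed — which the degradation test
quantifies with a one-sided comparison of percent errors at SNR 0.5 versus
2.0.

What the generators do *not* emulate: correlated (shot or detector) noise,
photobleaching trends, cell motion, out-of-focus light, and anisotropic
z-spread. Passing the harness therefore demonstrates correctness of the
algorithmic chain under the stated noise model, not performance on any
particular microscope.

## Degenerate inputs and numerical choices

* A constant-intensity channel (or frame, in per-frame mode) has no
  threshold; the mask is all-false and a warning — not an error — is
  emitted.
* Thresholds compare strictly (`>`), so an exactly-zero background after
  background subtraction is never masked in.
* The blur kernel is truncated at $4\sigma$ and renormalized; padding is
  half-sample symmetric, which conserves total plane intensity exactly.
* Site ids are assigned by the lexicographically smallest $(t,z,y,x)$ voxel
  of each component, making labelling independent of scan order.
* Durations are reported in seconds when `frame_interval_s` is calibrated
  and in frames (tagged) otherwise; areas in µm² when `pixel_size_um` is
  set and in voxels otherwise.
* All randomness flows through explicit integer seeds; fixed-seed runs are
  bit-reproducible, including archive bytes.

## Known limitations

* Temporal linking of cross-sections is by voxel overlap only — the
  criterion that defines "temporally contiguous" here. Signals that skip
  frames entirely (oscillating faster than the frame rate) appear as
  separate events.
* The global threshold assumes a stationary background; slow drifts are
  better served by `threshold_mode = "per_frame"`, at the cost of
  cross-frame comparability of amplitudes.
* Locally windowed (neighbourhood) adaptive thresholding and learned
  segmentation are out of scope.
* f/f₀-normalized amplitudes are intentionally not provided; delta f values
  are comparable only within a recording (arbitrary units).
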