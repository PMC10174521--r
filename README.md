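# dynroi

Automated detection and characterization of second-messenger signaling
events — Ca²⁺ transients, cAMP elevations — in multidimensional fluorescence
time-lapse recordings, using **dynamic regions of interest**: instead of
measuring intensity inside fixed polygons, the pipeline segments the
recording and tracks each signal's changing perimeter over time. Static ROIs
underestimate signals smaller than the polygon and overestimate signals that
outgrow it; dynamic ROIs do neither. The package is aimed at labs
quantifying endothelial calcium activity, biosensor (FRET) cAMP dynamics,
and similar spatiotemporal signaling data in 2-D to 5-D stacks.

## Method

For an input stack $U(c,t,z,y,x)$:

$$U_{\text{smooth}} = \mathrm{SG}_t(3, w)\, U \qquad
  U_{\text{filt}} = U_{\text{smooth}} - \textstyle\min_t U_{\text{smooth}}$$

$$V = G_\sigma * U_{\text{filt}} \qquad
  V_{\text{bin}} = V > \theta \qquad
  U_{\text{mask}} = U_{\text{filt}} \odot V_{\text{bin}}$$

Per-pixel cubic Savitzky–Golay smoothing over time, temporal-minimum
background subtraction, xy Gaussian blur, adaptive thresholding (Yen, Otsu
or Triangle; $\theta$ global per channel by default), masking. Active voxels
are grouped into 4-D connected components over $(t,z,y,x)$ — *sites* — and
each site's per-frame cross-sections form its dynamic ROI, from which
per-event descriptors are computed: amplitude **delta f** (peak
cross-section mean of the background-subtracted intensity; f/f₀ is
undefined without a static baseline region), duration, maximal area,
starting slice, bounding box, origination centroid, and
convergence/divergence topology with parent/daughter branch links.

Synthetic ground-truth generators (noiseless polygonal scenario movies with
a 57-event manifest, and Gaussian pulses over a 30-pixel footprint embedded
in Normal(1, 1) noise) plus an SNR validation harness are included as
first-class, tested code. See the methods vignette
(`vignettes/dynamic-roi-detection.Rmd`) for the model, parameter rationale
and limitations.

## Worked example

Detect events in a synthetic SNR-5 pulse recording:

```r
library(dynroi)

gen <- generate_pulse_stack(pulse_params(amplitude = 5), seed = 42)
res <- detect_events(gen$stack, validation_config())
res
#> DetectionResult for 'pulse_snr5': 14 event(s)

# the real pulse is the large site; the rest are small noise specks
sizes <- vapply(res$sites, function(s) s$n_voxels, 0L)
m <- res$metrics[[which.max(sizes)]]
c(area_at_peak = m$area_at_peak_intensity, max_area = m$max_area,
  delta_f = round(m$delta_f, 2), start = m$start_frame, end = m$end_frame)
#> area_at_peak     max_area      delta_f        start          end
#>        30.00        30.00         5.01        72.00       110.00
```

The matched event's spatial spread at peak signal intensity is exactly the
30-pixel embedded footprint; delta f ≈ 5.0 reflects the amplitude-5 pulse
after smoothing and background subtraction, and the event spans frames
72–110 around the pulse peak at frame 90. From a file instead:

```r
cmd_detect("movie.tif", "out/")        # archive + CSV + report under out/
```

writes `out/results.jsonl.gz` (a gzip JSON-lines archive, one record per
event, schema-versioned), `out/report/events.csv` and histogram/projection
figures. A thin CLI wraps the same functions:

```sh
exec/dynroi detect --input movie.tif --out out --threshold yen --sigma 0.35
exec/dynroi validate --out val --reps 10 --seed 1
exec/dynroi make-fixtures --out fixtures --seed 1
```

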