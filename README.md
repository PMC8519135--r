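# glycotrace

In-depth analysis of continuous glucose monitoring (CGM) traces for hepatic
glycogen storage disease (GSD).

Patients with hepatic GSD cannot mobilise liver glycogen and depend on
carefully timed carbohydrate therapy (continuous gastric drip feeding,
uncooked cornstarch) to avoid hypoglycemia. Conventional review of CGM
downloads — eyeballing daily overlays and spot glucose values — misses both
subtle drifts and sudden changes in glucose homeostasis. `glycotrace`
implements a reusable, tested pipeline for the quantities that make those
changes visible:

- **Ingestion** of Dexcom-CLARITY-style CSV exports at the 5-minute device
  cadence (288 readings/day), with the validated 2.2 mmol/L sensor floor
  enforced: sub-floor (`"Low"`) readings are set to the floor rather than
  dropped, so hypoglycemia does not silently vanish from the statistics.
- **Descriptive and variation metrics** per intervention interval: median,
  min, max, range, SD, variance, CV = 100·SD/mean, and a 95% reference
  interval mean ± 1.96·SD.
- **Glycemic control** as ADA-2020 range occupancies: time under range
  (level-2 `< 3.0`, level-1 `[3.0, 3.9)` mmol/L), time in range
  (`[3.9, 7.8]` and `[3.9, 10.0]`) and time above range (`> 7.8`, `> 10.0`);
  the four exclusive bands partition every trace to exactly 100%.
- **Nocturnal windowing**: the clock interval [01:00, 05:00) is analysed
  separately (48 samples/night) to limit confounding by diet and physical
  activity.
- **Starch-load summarisation**: initial/max/end glucose, time-to-max,
  rising slope (max − initial)/t_max and falling slope in mmol/L/h,
  trapezoidal AUC, plus paired-crossover arm comparison (two-tailed paired
  *t*-test over complete pairs; arm means over all available loads).
- **Dynamics**: glucose′ and glucose″ by three-point finite differences, and
  two cumulative-sum formulations —
  method A, `CUSUM_t = Σ_{i≤t} (glucose_i − reference mean)`, and
  method B, `CUSUM_t = Σ_{i≤t} (glucose_calculated_i − glucose_i)`, where
  `glucose_calculated` comes from a per-patient "hypercube" regression:
  mean observed glucose binned over the (glucose′, glucose″) plane.
- **Spectral analysis**: per-night DFT amplitude spectra
  (`amplitude = 2·|X_k|/n`), component detection, and a night-by-night
  spectrogram with the three outcome parameters — dominant frequency
  (cycles/hour and cycles/night), number of frequencies, amplitude. Stable
  glucose management shows as low frequency, few components, small
  amplitude.
- **A synthetic CGM generator** (baseline + sinusoids + hypoglycemic dips +
  meal excursions + seeded sensor noise + floor clipping) so the whole
  pipeline is verifiable against known ground truth without patient data.

Everything is tidyverse-native: traces and results are tibbles, verbs take
the data frame first and pipe, fitted models support `tidy()`/`glance()`,
and result types have `autoplot()` methods.

## Worked example

```r
library(glycotrace)

path <- system.file("extdata", "dexcom_synthetic_sample.csv", package = "glycotrace")
tr <- read_dexcom_csv(path)   # 72 readings, "Low" rows clipped to 2.2 mmol/L

round(descriptive(tr), 2)
#>      n mean median min max range   sd variance cv_percent ri95_low ri95_high
#> 1   72 4.35    4.4 2.2 6.4   4.2 1.08     1.16       24.8     2.23      6.46

round(time_in_ranges(tr), 1)
#>   tur_l2 tur_l1 tir_39_78 tir_39_100 tar_78 tar_100
#> 1    9.7   27.8      62.5       62.5      0       0
```

9.7% of readings sit in level-2 hypoglycemia and another 27.8% in level-1 —
this synthetic trace carries a deliberate nocturnal hypoglycemic dip — while
62.5% of time is in the tight 3.9–7.8 mmol/L target band and none above it.

Starch-load curves summarise back to their anchors:

```r
spec <- load_curve_spec(initial = 4.0, max_value = 8.4, t_max_min = 185,
                        end_value = 3.0, end_time_min = 475)
round(load_summary(generate_load_curve(spec))[
  , c("initial", "max_value", "t_max_min", "slope_rise", "slope_fall", "auc")], 2)
#>   initial max_value t_max_min slope_rise slope_fall  auc
#> 1       4       8.4       185       1.43      -1.12 46.7
```

and the bundled reference table of a published UCCS-vs-Glycosade crossover
reproduces its group comparison:

```r
compare_arms(starch_load_reference(), c("max", "slope_rise"))
#>   metric     arm_a     arm_b mean_a mean_b n_a n_b n_pairs mean_diff t_stat p_value
#> 1 max        Glycosade UCCS    7.91   8.8    9  11       9      -1.0  -2.48   0.038
#> 2 slope_rise Glycosade UCCS    2.97   4.76   9  11       9      -1.9  -3.54   0.008
```

UCCS loads peak higher (8.8 vs 7.9 mmol/L, paired p = .038) and rise more
steeply (4.8 vs 3.0 mmol/L/h, p = .008) than the extended-release starch —
the slower absorption profile that motivates Glycosade in GSD.

The full pipeline (`run_pipeline()`) chains ingestion, intervention
partitioning, metrics, CUSUM/derivative series and the nocturnal
spectrogram into CSV data products with a provenance JSON; see the methods
vignette (`vignettes/glycotrace-methods.Rmd`) for the underlying models and
conventions.

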