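# suturetension

Phase analysis and relaxation modelling of the tension inside knotted
surgical sutures.

A knotted suture loop compresses the enclosed tissue, and an in-loop force
sensor shows that this tension is far from constant: a non-elastic
monofilament (3/0 polypropylene) loses a large share of its tension within
the first hour, in three stereotyped phases. The first minute is a **rapid
cutting phase** in which the suture cuts into the tissue and tension drops
from the knotting peak P0 to the 1-minute value P1; the following hour is a
**constant declining phase** in which the gap above the final plateau loses
a fixed percentage per minute (plastic deformation); what remains is a
**plateau phase** at Pplat, the residual structural resistance of the
tissue. Collagen-poor tissue (liver) loses the most tension to cutting;
collagen-rich tissue (skin, stomach) retains the highest plateau fraction.

The package is for biomechanics and surgical-research groups working with
suture-tension or comparable force-relaxation records. It provides:

* a documented plain-text trace format with readers/writers and block-mean
  decimation (`read_trace()`, `write_trace()`, `resample_trace()`);
* a seeded synthetic-cohort generator emulating the measurement setting
  (6 sutures per organ x 5 organs, 60 min at 250 Hz, 0.077 gf resolution,
  Gaussian sensor noise), parameterized by published tissue characteristics
  (`builtin_profiles()`, `simulate_cohort()`);
* phase segmentation into P0 / P1 / Pplat with censoring-aware half-tension
  times (`segment_phases()`, `half_tension_time()`);
* the relaxation model

  ```
  y(t) = a * exp(-b * t^c) + d,     t in minutes from the 1-min transition
  ```

  with a = P1 − Pplat, b the decay rate per minute, d = Pplat, and c = 1 by
  default (constant per-minute decline `100*(1 − exp(−b))` %), fitted by
  bounded least squares (`fit_relaxation()`, `decline_per_minute()`,
  `half_time_from_fit()`);
* tissue-level reporting with Kruskal–Wallis omnibus tests, gated pairwise
  Mann–Whitney tests, and pooled collagen/protein-content correlations
  (`summarize_by_tissue()`, `collagen_correlations()`), plus an end-to-end
  pipeline (`run_pipeline()`) and a CLI (`inst/cli/suture-relax.R`).

## Worked example

Generate the noiseless "mean liver" trace (all profile SDs set to zero) and
push it through segmentation and the relaxation fit:

```r
library(suturetension)

profile <- zero_sd_profile(builtin_profiles()$liver)
params  <- sample_suture_params(profile, mode = "relative")
trace   <- synthesize_trace(params, sensor_config(noise_sd_n = 0))
trace
#> <tension_trace> liver_1 (liver): 900000 samples @ 250 Hz, 3600.0 s, 1.045-2.600 N

segment_phases(trace)[, c("p0", "p1", "pplat", "rcp_loss_pct",
                          "plateau_ratio_pct", "half_time_min")]
#>    p0    p1 pplat rcp_loss_pct plateau_ratio_pct half_time_min
#> 1 2.6 1.716 1.045        33.99              40.2         12.46

fit <- fit_relaxation(trace)
fit
#> <relaxation_fit> liver_1 (liver): a=0.676 b=0.08338 c=1 d=1.04  r=1.00000  [60s, 3599.5s] converged
decline_per_minute(fit)
#> [1] 8
```

Reading the output: the peak tension is 2.6 N; 33.99% of it is lost in the
first minute (the rapid cutting phase); the fitted declining phase loses 8%
of its above-plateau gap per minute (b = −ln(0.92) = 0.0834/min); the
plateau sits at 40.2% of the peak; and tension falls to half the peak after
12.46 min. These are the liver values of the tissue-characteristics table
the generator was parameterized with, read back through the full measurement
and analysis path (quantization to 0.077 gf steps accounts for the small
departures from round numbers).

A full noisy cohort, end to end:

```r
summary <- run_pipeline(pipeline_config(seed = 1, n_per_tissue = 6,
                                        output_dir = "cohort"))
print(summary)   # tissue table, omnibus tests, collagen correlations
```

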