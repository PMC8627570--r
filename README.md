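# swimkin

Quantifying anguilliform (eel-like) swimming from silhouette video, end to
end: midline tracking, traveling-body-wave parameters, propulsive
efficiency surrogates, and the group statistics used in functional-recovery
studies of spinal-transected swimmers (e.g. lampreys recovering from
complete spinal cord transection, where the percent of regenerated
reticulospinal axons is the recovery covariate).

## Who this is for

Researchers analyzing high-speed video of undulatory swimmers who need a
tested, scriptable replacement for ad hoc ImageJ/MATLAB midline workflows —
and a synthetic ground-truth generator to validate any such pipeline, since
raw swim video is rarely deposited.

## What it computes

From a frame stack (multi-page TIFF / numbered PNG) or a midline CSV, per
trial:

| quantity | definition |
|---|---|
| swimming speed *U* | net centroid displacement along the heading / time (BL s⁻¹) |
| tail-beat frequency *f* | reciprocal mean period between same-sign zero crossings of tail excursion (Hz) |
| wavelength *λ* | 2 × mean arc-length spacing of adjacent wave extrema along the body (BL) |
| peak-to-peak amplitude *A*<sub>pp</sub> | maximum of the per-cycle-averaged excursion envelope (BL) |
| amplitude ratio | caudal/rostral envelope ratio (tail vs head) |
| wave speed *V* | −2π*f* / (phase slope vs *s*), ≈ *λf* for a traveling wave (BL s⁻¹) |
| waves per body | 1/*λ* |
| Strouhal number | *St* = 2*fA*/*U* with *A* = *A*<sub>pp</sub>/2 (half peak-to-peak; see vignette) |
| stride length | *U*/*f* (BL per tail beat) |

Statistics: one-way ANOVA across treatments with Holm–Šidák post hoc
comparisons, regressions of performance on percent axon regeneration, and
a REML mixed model `speed ~ frequency * regeneration + (1 | individual)`
(via nlme), plus Shapiro–Wilk/Levene assumption diagnostics.

The synthetic module generates inextensible swimmers with the traveling
wave h(s,t) = A(s) sin(2π(s/λ − f t)), a geometric amplitude envelope,
rendered silhouette stacks with exact ground truth, and whole virtual
cohorts matching published group means/SDs — so the entire pipeline is
testable without any data download.

## Worked example

```r
library(swimkin)

## a healthy-control swimmer: lambda = 0.79 BL, f = 3.6 Hz,
## A_pp = 0.16 BL, U = 1.83 BL/s, amplitude ratio 4.8
p  <- swimmer_params()
sq <- generate_midline_sequence(p, frame_rate_hz = 250, n_frames = 500)
st <- render_frames(sq, render_spec(follow = TRUE))   # silhouette frames
tr <- track_frames(st)                                # re-tracked midlines
k  <- wave_kinematics(tr)
round(unlist(k[1:7]), 3)
#>      speed_bl_s    frequency_hz       amp_pp_bl   wavelength_bl
#>           1.833           3.607           0.158           0.792
#> wave_speed_bl_s  waves_per_body       amp_ratio
#>           2.854           1.262           4.831

performance_indices(k)[, c("strouhal", "stride_length_bl", "in_optimal_range")]
#>   strouhal stride_length_bl in_optimal_range
#> 1    0.312            0.508             TRUE
```

The tracker recovers the generating parameters to well under 2%, and the
Strouhal number of a healthy control sits inside the 0.25–0.35 band where
oscillating propulsion is most efficient — a transected-swimmer parameter
set (λ = 0.53, A = 0.11, f = 4.1, U = 1.12) lands at St ≈ 0.40, above it.

A complete virtual study (cohort → kinematics → performance → statistics):

```r
res <- run_pipeline(run_config(out_dir = "study", seed = 1))
res$stats          # ANOVAs, Holm-Sidak pairs, regressions, mixed model
```

A thin CLI over the same functions lives at `inst/cli/swimkin.R`
(subcommands `simulate`, `track`, `kinematics`, `performance`, `stats`,
`run-all`).

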