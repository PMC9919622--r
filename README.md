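# limbuse

Quantifying upper-limb use during activities of daily living from wearable
kinematics and forearm EMG.

After a stroke, the degree to which a patient actually uses the affected arm
at home — and whether everyday movements are performed with one hand or both
— is central to planning rehabilitation. `limbuse` analyses paired-limb
recordings (hand position and acceleration in the trunk reference frame at
80 Hz, trunk acceleration, and 8-channel forearm EMG at 200 Hz) with two
complementary strategies:

**Time-based segmentation** splits the session into fixed quants of
T = 0.25 s and computes, per quant *i* and limb,

- activity counts `AC_i = (1/T) ∫ ‖a_h(t)‖ dt` from band-passed
  (0.25–2.5 Hz) hand acceleration, in three correction modes: raw,
  gravity-subtracted (`a_h − g`), and trunk-subtracted (`a_h − a_t`);
- muscle activity counts `MC_i = (1/T) ∫ Σ_n w_n²(t) dt` over an electrode
  set (all 8, or 4-electrode flexor/extensor groups);
- the bilateral sum and the offset log-ratio
  `RAC_i = ln((AC_uaf + 1) / (AC_af + 1))` (likewise `RMC_i`), whose
  distribution is symmetric around 0 for symmetric limb use;
- dwell-time grids (seconds spent at each intensity × ratio combination)
  and windowed path-length log-ratios over 1/3/5 s windows.

**Path-based segmentation** isolates *completed movements*: the trajectory
is parametrized by arc length (separating form from speed), split at rests
(smoothed speed below 0.05 m/s for ≥ 0.2 s) and at direction changes
(heading rotation > 45° between adjacent 20 mm tangent windows), and
candidates shorter than 50 mm are discarded. Each movement *m* is scored by

- per-limb path lengths `L` and their log-ratio `RL = ln(L_uaf / L_af)`;
- the Pearson correlation `PCC` of the two speed profiles;
- the log variance-ratio `RV = ln(V_uaf / V_af)` of the speed profiles;
- the discrete Fréchet distance `F` between the speed profiles;

combined into the **bimanual movement parameter**

```
BMP = 1 − ¼ [ (1 − PCC)/2 + |RV|/5.5 + F/1.3 + |RL|/2.5 ]
```

clamped to [0, 1]. `BMP > 0.7` classifies a movement as mostly bimanual,
`BMP < 0.4` as mostly unimanual, the closed band between as unclassified.
Per-movement EMG activity `W` and its log-ratio `RW` complete the picture.
Synthetic generators (minimum-jerk strokes, hexagon tracing with known
stroke counts, coordinated bimanual and strictly unimanual sessions with
ground truth) back every stage with testable fixtures.

## Worked example

Validate the movement segmentation on a hexagon-tracing task (120 pencil
strokes along 50 mm sides; a 60° heading change at every vertex), then
analyse a coordinated symmetric bimanual session:

```r
library(limbuse)

res <- run_validation(side = 0.05, n_circuits = 20)
sprintf("generated %d strokes, detected %d (%.1f%% error)",
        res$generated, res$detected, res$percent_error)
#> "generated 120 strokes, detected 120 (0.0% error)"

gen <- bimanual_session(scenario_spec("bimanual_symmetric",
                                      n_strokes = 100, seed = 42))
m <- movement_metrics(gen$session, segment_bilateral(gen$session))
bimanual_table(m)
#>   movement_class proportion_pct   n med_l_uaf  med_l_af
#> 1      unimanual              0   0        NA        NA
#> 2   unclassified              0   0        NA        NA
#> 3       bimanual            100 100 0.3016743 0.3023114

dist_summary(m$rl)
#> dist_summary: mean 0.0009407, sd 0.01989, kurtosis 2.681 (n = 100, excluded = 0)

mean(m$bmp)
#> [1] 0.992
```

All 100 generated strokes are recovered, every movement is classified
bimanual, the path-length log-ratio distribution is centred at zero (as it
should be for symmetric use), and the mean BMP is near 1.

File-based pipelines (`run_time_analysis()`, `run_path_analysis()`,
`run_simulation()`) read/write the CSV schema described in
`?read_session` and write a JSON manifest per run; the same pipelines are
available from a shell via the installed `exec/limbuse` script
(subcommands `time`, `path`, `validate-hexagon`, `simulate`).

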