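# File formats

All interchange files are plain text (UTF-8, '.' decimal) or 8-bit PNG.

## Trajectory CSV
`time_s, v_norm` — header required; times in seconds, strictly
increasing; `v_norm` is total volume normalised to the first (isotonic)
sample. Read/written by `read_trajectory_csv()` / `write_trajectory_csv()`.

## Fit results CSV (`fit_results.csv`)
`cpa, conc_M, Lp_um_min_atm, Ps_um_s, rmse, converged` — one row per
concentration; numerics at 9 significant digits. A JSON companion
(`fit_results.json`) adds the 2×2 parameter covariances and the
Lp/Ps-vs-concentration trend labels.

## Mixing report JSON (`mixing_report.json`)
`c_out_mean` (mol/L, flux-weighted at the channel exit), `L90_um`,
`L99_um` (axial positions where the mixing index reaches 0.9 / 0.99),
`wall_shear_rate_s` (1/s), `D_m2_s`.

## Images and masks
8-bit grayscale PNG. Masks are binary: 255 = cytoplasm, 0 = elsewhere
(zona pellucida excluded). `write_mask_png()` / `read_mask_png()`
preserve the convention exactly.

## Benchmark manifest (`manifest.csv`)
`frame_path, mask_path, split` — one row per image/mask pair,
`split ∈ {train, val}`.

## Acceptance output (`results/acceptance.json`)
One object per recomputed quantity: `{"<id>": {"value": <number>,
"n": <problem size>}}`.
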