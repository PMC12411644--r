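# polcontrast

Signed degree-of-polarization (DOP) imaging and tumor-contrast statistics
for reflection-mode tissue polarimetry.

## What problem this addresses

Tumors tend to depolarize backscattered light less than surrounding healthy
tissue, which makes polarimetric imaging a candidate for label-free tumor
localization. The analysis this package implements works on
polarization-resolved intensity images of tissue (e.g. a tumor xenograft
viewed through a dorsal window chamber) and asks: *how well do per-pixel DOP
values separate tumor from non-tumor?*

The core quantities are **signed** DOP metrics:

- signed circular DOP:
  `DOCP = sign(S3_in) * (I_R - I_L) / (I_R + I_L)` in [−1, +1] — negative
  values encode **helicity flipping** (returned circular handedness opposite
  the incident one), positive values helicity preservation; the magnitude
  equals the conventional `|S3_out|/S0_out`.
- signed linear DOP: a two-term sum over an H/V experiment and a ±45°
  experiment, `-sign(S1_in)*(I_H-I_V)/(I_H+I_V) - sign(S2_in)*(I_45-I_-45)/(I_45+I_-45)`,
  negative when **co-linear** detected intensity dominates cross-linear.
- per-pixel 4×4 **Mueller-matrix** images from a 16-state
  generator/analyzer scheme, with beam-splitter correction
  (`M_det^-1 · M_raw · M_ill^-1`).

Contrast between a fluorescence-derived tumor mask (threshold at 95% of the
maximum, 5-px-thick margin outline, fiducial-based co-registration) and the
surrounding tissue is quantified by unit-area histogram **overlap**
(0 = perfect separation, 1 = none), a pixel-level **ROC/AUC** over the
threshold grid −0.95, −0.90, …, +0.95, a stratified bootstrap **95% CI**
for the AUC, and per-class mean/SD summaries with total DOP magnitude
`(|DOLP| + |DOCP|)/2`.

Because the original in-vivo datasets are not public, the package ships a
fully specified, seeded synthetic scene generator (`scene_config()`,
`make_dop_scene()`, `make_mueller_scene()`) whose class-conditional DOP
distributions emulate the reported structure (tumor circular DOP more
negative and larger in magnitude; |DOLP| > |DOCP| everywhere), with a
fluorescence blob, a known fluorescence→polarimetry transform, and fiducial
markers in both frames. Closed-form binormal expectations
(`closed_form_expectations()`) serve as analytic oracles.

## Worked example

```r
library(polcontrast)

bundle <- run_pipeline(list(simulate = TRUE, seed = 1,
                            out_dir = "demo_run", figures = FALSE))
```

which logs (numbers printed by this exact call):

```
[config] seed=1 threshold=0.95 thickness=5 bins=80 step=0.05 n_boot=1000
[simulate] scene 256x256, 7555 tumor px -> demo_run/simulated
[dop] docp valid px=65536, dolp valid px=65536
[segment] mask px=6241, outline px=5475
[register] similarity: rot=0.0200 rad scale=1.0000 shift=(4.00, -6.00) rmse=1.62e-13 px
[contrast] AUC signed=0.0526 magnitude=0.9457 CI=(0.0503, 0.0550) overlap circ=0.2369 lin=0.6197
```

Reading those numbers:

- the registration stage recovered the configured fluorescence→polarimetry
  transform (rotation 0.02 rad, shift (4, −6) px) to machine precision from
  the four fiducials;
- the **signed** AUC is 0.05 — far *below* chance — because the tumor class
  is more negative than non-tumor and positives are defined as pixels above
  the threshold; on **magnitudes** the same image separates the classes
  with AUC 0.95. Both orientations are always reported (`bundle$roc`,
  `bundle$roc_magnitude`);
- the circular-DOP histogram overlap 0.237 (bin width 0.025) against the
  linear-DOP overlap 0.620 reproduces the qualitative finding that circular
  DOP carries most of the tumor contrast;
- the bootstrap CI half-width (~0.002) reflects the large pixel counts.

`bundle$summary` holds the per-class means/SDs (for seed 1: tumor circular
−0.40 ± 0.12 vs non-tumor −0.10 ± 0.12, matching the generator), and
`demo_run/` contains `docp.csv`, `dolp.csv`, `mask.png`, `outline.png`,
`roc_table.csv`, `region_summary.csv`, `contrast.json`, and `run.log`.

A command-line front end with `simulate`, `dop`, `mueller`, `segment`,
`register`, `contrast`, `report` and `run-all` subcommands is installed at
`inst/cli/polcontrast.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/polcontrast.R", package="polcontrast"))')" \
    run-all --config run.yaml --seed 7
```

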