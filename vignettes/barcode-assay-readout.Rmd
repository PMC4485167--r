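---
title: "Methods: barcode-formatted assay readout and ODR scanometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-formatted assay readout and ODR scanometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barscan)
```

# The model

A barcode-formatted assay embeds a sandwich immunoassay inside a Code 39
symbol so that the *qualitative* result is machine-readable and the
*quantitative* result is recoverable from the same image.

**Symbology.** Every Code 39 character is 9 elements — 5 bars interleaved
with 4 spaces — exactly 3 of them wide. The `-`/`+` pair is special: the
two patterns agree on their first 5 elements and differ in exactly the
last 4 (`differential_positions("-", "+")` is `6:9`). `-` realizes the
differential region as two wide bars separated by narrow spaces; `+` puts
two wide spaces next to two narrow bars occupying the trailing portion of
where `-`'s wide bars sit. The `F`/`$` pair has the same structure in
elements 2–5 and is used as the second slot when multiplexing.

**Physical layout.** Each wide bar of the positive character is divided
into a 3 mm test line, a ~0.5 mm white barrier, and a 2 mm control line
(`assay_layout()` defaults). The wide module is therefore
3 + 0.5 + 2 = 5.5 mm and, at the 3:1 wide:narrow ratio adopted here, the
narrow module is ~1.83 mm. The 2 mm control line sits at the end of the
channel that aligns with the negative character's narrow bar, so a
controls-only strip scans as the negative character. The remainder of the
barcode is assumed printed black on the same module grid (the source
design prints it on plain paper; module widths of the printed part are
not stated, so the strip-derived grid is reused).

**The ODR statistic.** Strip darkness is
`ODR = (I_b - I_s) / I_b`, with luminosity the BT.601 weighted average
`0.299 R + 0.587 G + 0.114 B` (the published description calls for a
weighted average grayscale without printing the weights; the standard
weights are adopted and configurable via `luminosity_model()`). ODR is
scale-invariant under uniform illumination changes, which is why it is
preferred over raw gray. Sampling mirrors the readout app: 3 groups of
4715 pixels per region, taken deterministically from vertically stacked
thirds of each region, each center-trimmed to exactly the group size.
ODR is computed from the pooled strip mean (pool first, then ratio); the
alternative — averaging per-group ratios — differs only at second order.
A strip brighter than background yields a flagged negative ODR rather
than a clamped zero, so glare is detectable downstream.

# The synthetic imaging world

`render_assay()` draws the printed skeleton at gray 0 on background 255,
the four binding strips at `background_gray * (1 - ODR)`, then applies —
in this order — Gaussian optical blur, an optional left-to-right linear
lighting ramp, and seeded i.i.d. Gaussian pixel noise, clipping to
[0, 255] and quantizing to 8 bits. Blur precedes lighting and noise
because optics precede the sensor. Geometry is rasterized by converting
cumulative mm positions to pixels with half-up rounding per edge, so
rounding error never accumulates.

Defaults state the emulated conditions: test 3 mm, control 2 mm, barrier
0.5 mm, strip height 5 mm, 300 dpi, quiet zones of 10 narrow modules,
noise off. What the generator does **not** model: perspective and
rotation, Bayer/JPEG artifacts, fixed-pattern noise, chemistry-driven
spatial inhomogeneity of staining. A green round-trip test therefore
establishes the decoder logic and the geometry contract, not robustness
to handheld-phone imaging.

# Calibration of the decoder defaults

The decoder thresholds a column dark when its ODR against the profile's
95th-percentile background reaches `bar_threshold_odr`. Two defaults are
*jointly* calibrated — as the design prescribes — so the readability
floors of the rendered assay land where the physical system's were
observed (0.24 for `+`, 0.44 for `-` on a 0.04 ODR grid):

* `bar_threshold_odr = 0.20`. A lone control line is detected once its
  ODR clears the threshold; on the 0.04 grid the first passing value is
  0.24 (at 0.20 the blurred, quantized strip peaks within a pixel-wide
  hair of the threshold and survives only as a sliver that the speckle
  filter rejects).
* `blur_sigma_mm = 0.35`. The divided wide bar reads as *one* wide bar
  only if the blurred barrier dip stays above threshold. For a barrier of
  width $w$ the dip is $2\,\Phi(-w/2\sigma) \cdot \mathrm{ODR}$; requiring
  it to cross 0.20 between grid values 0.40 and 0.44 gives
  $\sigma \in [0.334, 0.371)$ mm for $w = 0.5$ mm. The mechanism — not a
  hard-coded constant — produces the `-` > `+` asymmetry: below 0.44 the
  barrier splits the channel into a 7-dark-run pattern that matches no
  character. A consequence worth knowing: with *no* blur, a full-black
  assay never decodes as `-` at all; merging the divided bar **requires**
  optics, exactly as a sharp office print of the divided design would
  fail a strict ruler measurement.

The earlier-considered default of 0.15 mm blur is incompatible with the
floors (its barrier dip tops out near 0.10 · ODR, below any sensible
threshold), which is why 0.35 mm is the package default.

Other decoder choices: narrow-width estimates are taken *per polarity*
(dark runs fatten and light runs thin under blur, by opposite amounts),
as the median of the run cluster within `ratio_cut` of the smallest run —
ties break toward narrow, avoiding phantom wide bars. Dark runs below 0.4
of the median dark run are discarded as speckle (narrow bars always
outnumber wide ones in Code 39, so that median is a narrow bar). Reading
direction comes from the start/stop `*`, whose pattern is the one
asymmetric anchor: a mirrored scan turns `*` into the pattern of `P`, so
the forward attempt fails framing and the reversed attempt is reported
with `orientation = "reversed"`. The observed intermittent readability
zones (0.16–0.20 for `+`, 0.28–0.40 for `-`) are camera/operator noise in
origin and are deliberately not modeled; this package models only the
deterministic floor.

# Dose–response model

`fit_calibration()` fits the four-parameter logistic
$\mathrm{ODR}(c) = L + (U - L) / (1 + (c_{50}/c)^h)$ by bounded
least squares (L-BFGS-B; lower asymptote in [0, min(odr) + 0.2], upper
in [max(odr), 1], log-parameterized midpoint and slope). The 4PL is the
standard sandwich-immunoassay curve; the source plots a saturating curve
without naming a model, so the functional form is a package design
choice, with a 3-parameter Langmuir (slope = 1) as the alternative. The
quantifiable range excludes the outer 5% of the dynamic range at each
asymptote; `estimate_concentration()` flags `below_range` / `saturated`
instead of extrapolating and propagates an interval by inverting
`odr ± RMSE`.

The synthetic calibration world (`simulate_calibration()`) states: lower
asymptote 0.04 (the reported blank ODR), upper 0.55 (middle of the
reported 0.50–0.60 saturation band), midpoint 7.5 mIU/mL (saturation
near 15 mIU/mL), Hill slope 2 (typical sandwich steepness), ODR noise sd
0.02, 8 standards from 0 to 25 mIU/mL. These are fixed statements of the
emulated assay, not tuning knobs; wet-lab dose–response values themselves
are not reproducible in software and are out of scope. Units are carried
as given (the source mixes "mIU" and "mIU/mL"; no conversion is
attempted).

# Multiplexing

`design_multiplex()` supports the two published schemes:
`character_alphabet` alternates the `(-,+)` and `(F,$)` pairs per analyte
(two negatives realize the combined barcode `+$`), and `paired_label`
prints a designator letter before each result character (`A+B-`). `F` is
taken as the positive-result character of its pair by analogy with `-`
(wide differential bars); the source never states this polarity, so it is
an explicit assumption surfaced in the documentation. Likewise the base
convention — `+` means *negative* — is kept in `paired_label` mode and
surfaced in output labels. `render_assay()` simulates one physical assay
slot (4 strips) per image; combined multi-assay barcodes are exercised
through `render_barcode()` of the realized string, whose full-contrast
appearance is identical.

# Numerical and degenerate-input choices

* mm→px: half-up rounding of cumulative edges; a narrow module under
  2 px is rejected with an explanatory error.
* 8-bit quantization happens once, after all degradations.
* `odr()` rejects `I_b = 0` (undefined) and negative `I_s`.
* Flat-field correction estimates illumination from column maxima,
  classifies columns below 0.9 of their local closing envelope as
  bars/strips, interpolates the background across them, smooths, divides,
  and rescales to preserve the background median. A clipped highlight
  (background already at 255 under a brightening ramp) is information
  lost and cannot be corrected; tests use a sub-white background when
  exercising gradients.
* Calibration fits reject under-sized (< 5 points), non-monotone
  (Spearman < 0.5) and flat (< 0.02 ODR span) data with diagnostics.
* All randomness (noise fields, synthetic calibration noise) is seeded;
  renders restore the caller's RNG state.

# Known limitations

* The decoder assumes an axis-aligned, horizontally scanned symbol; no
  rectification beyond mirror handling.
* Readability floors are exact for the *default* geometry/dpi; other
  module ratios or dpi shift the quantization edges by design.
* No third-party Code 39 reader exists in the supported environment, so
  the independent cross-check in the test suite is an oracle decoder
  written from scratch against an independently constructed pattern
  table, not an external library.
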