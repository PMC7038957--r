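---
title: "Methods: symbolic recurrence screening of RR intervals from digitized ECG charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbolic recurrence screening of RR intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsrqa)
```

## The screening problem

Atrial fibrillation leaves a dynamical fingerprint in the RR tachogram:
normal sinus rhythm produces quasi-periodic inter-beat intervals, while AF
produces an irregularly irregular sequence with essentially no serial
structure. `ecgsrqa` quantifies that contrast with symbolic recurrence
quantification analysis (SRQA) and feeds it to a logistic classifier. The
front of the chain accepts what low-cost recorders actually emit — a chart
image — and converts it to RR intervals.

This vignette documents the models, the tunable parameters, the numerical
conventions, and what the synthetic validation data do and do not
establish.

## Ordinal symbolization and the symbolic recurrence plot

An RR window $x_1, \dots, x_T$ is delay embedded (delay 1) into
m-histories $\bar x_t = (x_t, \dots, x_{t+m-1})$, $t = 1, \dots, T-m+1$.
Each history maps to its **ordinal pattern**: the permutation of the time
offsets $0, \dots, m-1$ that lists the values in ascending order, with
ties broken by ascending offset (stable sort). With $m = 3$ the alphabet
is the $3! = 6$ permutations, held in canonical lexicographic order by
`symbol_alphabet()`; e.g. $(0.55, 0.65, 0.60) \mapsto (0, 2, 1)$.

Two histories are *recurrent* when they carry the same symbol. The
symbolic recurrence plot is
$SRP_{ts} = k$ if $S(\bar x_t) = S(\bar x_s) = \pi_k$ and $0$ otherwise:
symmetric, integer-coded by symbol, with a fully recurrent main diagonal.
Because the symbols depend only on the ordering of values, **every
SRQA-derived quantity is invariant under any strictly increasing
transformation of the intervals** — in particular under the affine device
calibration below (with positive slope). The test suite asserts this
bit-for-bit for affine, exponential and cubic maps.

### Covariates

From the SRP we extract, excluding the line of identity (self-recurrence
is uninformative and would saturate the rates):

* `det` — fraction of recurrent points in the upper triangle lying on
  diagonal runs of length $\ge \ell_{\min}$ (determinism);
* `l_max`, `l_mean` — longest diagonal run and mean qualifying run length;
* `lam` — fraction of off-diagonal recurrent points on vertical runs of
  length $\ge v_{\min}$ (laminarity), with trapping time as a by-product;
* `symbol_entropy` — Shannon entropy (natural log) of the per-symbol
  recurrence-rate distribution, in $[0, \log m!]$; the per-symbol rate is
  $c_k (c_k - 1) / (N (N-1))$ for $c_k$ occurrences among $N$ symbols, so
  the rates sum to the global off-diagonal recurrence rate.

Defaults $\ell_{\min} = v_{\min} = 2$: the smallest length at which a
"line" is more than an isolated point. A consequence worth knowing: a
fully recurrent $N = 5$ plot has DET $= 9/10$, not 1, because the
far-corner diagonal holds a single point that no length-2 line can cover.

The distribution covariates are the window mean, median, Pearson CV
(sample sd over mean) and a robust CV (median absolute deviation from the
median, over the median). The default covariate vector is those nine
values in the fixed order of `default_features()`. The set is
configurable; nine is the size we consider the practical default for this
framework, balancing the recurrence-geometry and distribution families.

## Classifier and threshold

`fit_af_classifier()` z-scores the covariates with training statistics (an
affine reparameterization that leaves attainable decision boundaries
unchanged but conditions the optimization) and fits logistic regression by
Newton/IRLS with an L2 penalty `ridge = 1e-6` on the slopes only. The
penalty exists purely to keep the MLE finite under complete separation —
common on cleanly separated synthetic benchmarks; set `ridge = 0` for the
pure MLE (the test suite checks equality with `glm` in that case).
Convergence tolerance is `1e-10` on the Newton step, cap 100 iterations;
the fit is deterministic.

The operating threshold is chosen on the training ROC curve, built by
sweeping the rule "AF iff $p > \tau$" over all distinct fitted
probabilities plus the sentinels 0 and 1:
$\tau = \arg\min_\tau \sqrt{FPR_\tau^2 + (1 - Se_\tau)^2}$.
Ties are broken toward the **largest** threshold — the conservative choice
that minimizes false AF alarms; a strict `>` is used so probabilities
exactly at $\tau$ are called NS. `cross_validate()` uses stratified,
seeded folds and re-selects $\tau$ inside each training fold; aggregate
metrics pool the test-fold confusion counts.

## Chart digitization

The digitizer inverts the standard ECG paper conventions: at paper speed
$v$ mm/s and gain $g$ mm/mV on a $d$ dpi raster, one second spans
$d v / 25.4$ pixels and one millivolt $d g / 25.4$ pixels (590.55 px/s and
236.2 px/mV at the 600 dpi, 25 mm/s, 10 mm/mV defaults).

Stages and their conventions (pixel coordinates are 0-based, rows grow
downward):

1. **Grid removal**: pixels whose RGB lies inside a colour box are set to
   white. The default box (`R >= 100`, any G/B) clears white paper and the
   red/pink grid family while keeping a dark trace; the exact box is
   exposed because printed grid hues vary by vendor.
2. **Binarization**: trace mask where $\min(R, G, B) <$ threshold
   (strictly), default 128/255.
3. **Area opening**: 8-connected components with area strictly below
   `min_area` are removed; default 1260 px at 600 dpi, rescaled by
   $(d/600)^2$ at other resolutions. Connected labelling is run-based
   (row runs merged across adjacent rows with ±1 column tolerance).
4. **Thinning**: bounded Zhang–Suen passes (default 2). Thinning never
   adds pixels, preserves 8-connectivity, and leaves isolated pixels
   alone.
5. **Column scan**: each column's trace pixels become a `(top, bottom)`
   span; a column with several disjoint runs keeps the run nearest the
   previous column's trace (residual grid robustness); blank columns
   yield gaps.
6. **Span collapse**: the modal span thickness $\mu$ across the trace
   separates thin columns (take `bottom`, update the running reference
   $\lambda$) from thick ones — steep QRS flanks — which take whichever of
   `top`/`bottom` lies farther from $\lambda$. On a monotone flank this
   tracks the moving edge; the known cost is a one-column lag on the
   descending flank, harmless at ~590 columns/s.
7. **Gap interpolation**: interior gaps linearly, edge gaps by
   nearest-value extension.
8. **Units**: amplitude $(\text{baseline} - y) \cdot 25.4 / (d g)$ mV with
   the baseline at the **median trace row** — robust, and any constant
   offset cancels in RR intervals and ordinal features — and resampling to
   `target_rate` (default 300 Hz, twice the bandwidth of single-lead
   portable recorders; `NULL` keeps one sample per column).

Signals wider than `max_width_px` render as consecutive strips that are
digitized independently and concatenated. PDF chart input is not
rasterized by the package; rasterize to PNG externally at the desired dpi.

## Smoothing and R-peak detection

Smoothing uses the causal direct-form filter with
$b = (0.2, 0.2, 0.2, 0.2, 0.2)$, $a = 1$ (fourth order): unit DC gain and
a constant 2-sample group delay that cancels when differencing peak
positions into RR intervals, so no delay compensation is applied. Filter
state starts at zero, and the output length equals the input length.

Peak detection keeps local maxima (plateau-aware) whose topographic
prominence reaches `min_prominence` (default 0.4) of the robust dynamic
range — the 99th percentile minus the median, insensitive to baseline
offset and isolated artifacts — then enforces the refractory spacing
`min_distance` (default 0.25 s, ≈240 bpm ceiling), with the higher peak
winning any conflict. A flat signal yields an empty peak list. Windowing
defaults to non-overlapping 102-beat windows; discrimination improves with
longer windows, and the window length is a free parameter.

## Device calibration

`fit_calibration()` is ordinary least squares of the gold-standard RR on
the low-cost RR, $RR_M = a + b \, RR_{KM}$; applying it is
`apply_calibration()`, which preserves the rhythm label and clips a
non-positive result (possible with a negative intercept on a degenerate
interval) to 1 ms with a warning rather than aborting a batch. On the
training pairs, MSE after calibration can never exceed MSE before — OLS
minimizes squared error over affine maps — which the tests assert. Since
the calibration is increasing ($b > 0$ in practice), the SRQA covariates
of calibrated and raw series are identical, and only the location/scale
covariates move; on the synthetic benchmark the cross-validated accuracy
shift after calibration is bounded by 0.01 in the acceptance suite.

### Synthetic calibration pairs

`generate_calibration_pairs()` emulates a 400-sample paired acquisition
(20 patients × 20 beats, all normal sinus). Its defaults are derived in
closed form from the published device-pair summary statistics rather than
tuned: with reported slope $b = 1.0679$, intercept $a = -0.011794$,
$R^2 = 0.91$, and mean squared errors $0.001971$ (raw) and $0.000355$
(calibrated),

* residual sd $\sigma = \sqrt{0.000355} = 0.0188$ s (post-calibration MSE
  is the residual variance);
* $\mathrm{sd}(x)$ from $R^2 = b^2 \sigma_x^2 / (b^2 \sigma_x^2 +
  \sigma^2)$, giving $\sigma_x = 0.0561$ s;
* $\mathrm{mean}(x)$ from the raw-MSE identity $\mathbb E[(x - y)^2] =
  (a + (b-1)\mu_x)^2 + (b-1)^2 \sigma_x^2 + \sigma^2$, giving
  $\mu_x = 0.763$ s (≈79 bpm, ordinary for young adults at rest).

A fresh draw at any seed therefore reproduces those summary statistics up
to sampling noise at $n = 400$, which is what `scripts/acceptance.R`
reports.

## What the synthetic generators do and do not emulate

`generate_rr_ns()` is mean + sinusoidal modulation + Gaussian noise
(defaults: 0.8 s mean, modulation amplitude 0.05 s with a 6-beat period —
a respiratory-frequency oscillation — and noise CV 0.03, all inside the
NS regime CV ≤ 0.15), clipped at 0.2 s. `generate_rr_af()` draws i.i.d.
gamma intervals (defaults: mean 0.7 s, CV 0.25 — the AF regime requires
CV ≥ 0.15) clipped to [0.2, 2.0] s: the simplest process that is
"irregularly irregular", with lag-1 autocorrelation ≈ 0. They capture the
ordinal-structure contrast the classifier exploits, **not** real HRV:
no ectopic beats, no fibrillatory baseline waves, no autonomic trends, no
detection errors. The synthetic benchmark accuracy (≈0.99) therefore
demonstrates that the chain is implemented correctly and that the features
separate the two regimes as designed; it is not a clinical performance
estimate, which requires annotated recordings and the usual external
validation.

`synthesize_ecg()` is a Gaussian-bump PQRST model (R amplitude 1 mV
dominant; gentle Q/S/T so that T-wave prominence stays well below the
detection threshold), with true R-peak indices attached.
`render_chart()` draws the trace ~2 px thick over a 1 mm/5 mm pink grid
with optional salt-and-pepper specks — the forward model the digitizer
inverts. Round-trip fidelity on this forward model (correlation > 0.999,
R peaks within ±1 column at 600 dpi) bounds the *algorithmic* error of
digitization; scanner blur, skew and JPEG artifacts of real charts are
out of scope.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. The validation suite uses: 200 random recurrence plots of
$N \le 30$ against brute-force line-counting oracles; 100 random score
sets against exhaustive threshold scans; 100 random series for the
monotone-invariance property; a 100 + 100 window benchmark (102 beats,
10-fold CV) for the end-to-end accuracy; and 6–8 beat charts at 600 dpi
for the digitization round trip — sizes at which the independent oracles
are exact and the full suite runs in well under a minute.

## Known limitations

* Single-lead, single-strip charts; no OCR of printed metadata, no
  automatic grid-pitch estimation (geometry comes from configuration).
* The digitizer assumes one trace per strip; overlapping traces or
  annotations that survive the colour filter will corrupt the scan.
* The covariate set is a documented default, not a canonical law; users
  can pass any subset or extend the matrix with their own columns.
* Recording-level calls are a majority vote over window calls; no
  probability pooling across windows is attempted.
* AF is the only abnormality modelled; other arrhythmias with irregular
  RR (e.g. frequent ectopy) would confound a classifier trained only on
  these two regimes.
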