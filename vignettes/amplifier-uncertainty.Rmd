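---
title: "Monte Carlo uncertainty budgets for a two-stage ECG amplifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo uncertainty budgets for a two-stage ECG amplifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgmcm)
```

## The measurement problem

An ECG front-end turns a fraction-of-a-millivolt electrode signal into a
recordable voltage through two amplification stages: a three-op-amp
instrumentation preamplifier and a final non-inverting stage. Every
component tolerance, every electrode-voltage fluctuation, the baseline
wander and the ambient noise all disperse the output voltage around its
nominal value. At design time — before any hardware exists — that
dispersion can be *computed* by assigning each input a probability density
function (PDF) and propagating the PDFs through the circuit's measurement
equation. `ecgmcm` does this by Monte Carlo simulation, decomposes the
result into a per-source/per-block budget, and cross-checks it against
analytic first-order propagation.

## The measurement equation

With the symmetric duplicates of the instrumentation topology eliminated
(`R3 = R1`, `R6 = R4`, `R7 = R5`, `R10 = R9`), the static model is

$$
v_1 = \left(1 + \frac{2R_1}{R_2}\right)\frac{R_5}{R_4}
      \,(v_{in+} - v_{in-} + b + n), \qquad
v_{out} = \left(1 + \frac{R_{11}}{R_8}\right) v_1 ,
$$

where $b$ is the baseline offset and $n$ the environmental noise, both
**input-referred**: they are physical voltages superimposed on the
electrode signal, so they see the full cascade gain. At the nominal
component values the gains are $25.38$ and $31$, and with a
$0.30\ \mathrm{mV}$ differential input on a $3.00\ \mathrm{mV}$ baseline
the nominal output is $25.38 \times 31 \times 3.3 = 2596.4\ \mathrm{mV}$.

Two RC corners shape the frequency response,

$$
f_1 = \frac{1}{2\pi C_1 R_9} \approx 0.048\ \mathrm{Hz}, \qquad
f_2 = \frac{1}{2\pi C_2 R_{11}} \approx 106\ \mathrm{Hz},
$$

but the budgets are *static*: no frequency-dependent attenuation is applied
to $v_{out}$. Consequently `R9`, `C1` and `C2` are tagged
`block = "frequency_only"`; they never enter the output-voltage
propagation and are budgeted separately through
`cutoff_uncertainty()`.

## PDF assignment

Three families cover all thirteen sources:

| Source | PDF | Parameters | Why |
|---|---|---|---|
| $v_{in+}$, $v_{in-}$ | normal | $\mu = 0.30 / 0.00$, $\sigma = 0.04$ mV | electrode-signal statistics |
| baseline | normal | $\mu = 3.00$, $\sigma = 0.01$ mV | slow wander around its mean |
| noise | normal | $\mu = 0$, $\sigma = 0.01$ mV | broadband ambient pickup |
| resistors | rectangular | nominal $\pm 1\%$ | tolerance interval, nothing more known |
| capacitors | U-shaped | nominal $\pm 1\%$ | bounded periodic drift |

The U-shape is implemented as the arcsine distribution, sampled through its
inverse CDF $x = a + (b-a)\sin^2(\pi u/2)$. The arcsine law is the standard
metrological choice for a quantity that drifts periodically between bounds
(it is the stationary distribution of a sinusoid observed at a random
phase); nothing in the design constrains the U-shape further, so only the
arcsine form is implemented. Its standard deviation, half-width over
$\sqrt{2}$, is what the analytic engine uses, alongside half-width over
$\sqrt{3}$ for rectangular sources.

Tolerances are multiplicative on the nominal (`pdf_from_tolerance()`):
$22\ \mathrm{k\Omega} \pm 1\%$ gives $(21.78, 22.22)$. The `R9` tolerance
is declared as $3.30\ \mathrm{M\Omega} \pm 1\%$, consistent with every
other resistor; since `R9` only moves $f_1$, the output budget is
insensitive to it either way.

## The Monte Carlo engine

`mcm_run()` draws an $M \times n$ matrix — one column per active quantity,
all columns from a single seeded stream in declaration order — evaluates
the model row-wise and summarises the output sample: mean, standard
deviation, expanded uncertainty and the symmetric percentile coverage
interval. The default $M$ follows the minimum-sample rule

$$ M = \left\lceil \frac{10^4}{1-p} \right\rceil, $$

which gives $M = 2 \times 10^5$ at $p = 0.95$. At that size the standard
error of the reported standard deviation is
$\sigma/\sqrt{2M} \approx 0.09\ \mathrm{mV}$, so integer-millivolt summary
values are essentially seed-independent. Every result records its seed and
$M$; identical inputs reproduce bit-identical samples.

`mcm_run_sources()` isolates one source (or block): the named columns keep
their draws, every other quantity is pinned at its nominal. Crucially the
varied columns **reuse the full run's draw matrix** at the same seed, so
the budget rows and the all-sources total produced by `mcm_budget()` are
consistent by construction — one draw matrix, many read-outs. Because the
model is nearly linear over the tolerance ranges, the per-source variances
add in quadrature to the total within a few percent, which the test suite
checks as an invariant.

### Two interval conventions

The expanded uncertainty is reported as $U_{95} = k \cdot s$ with
$k = 1.96$, computed from the *unrounded* standard deviation; report
tables round millivolts to integers and percentages to two decimals, always
from unrounded intermediates. The symmetric percentile interval is reported
alongside. For near-Gaussian outputs the two conventions agree, but they
part ways when the output is not normal: the final-stage block (two
comparable rectangular sources through `1 + R11/R8`) produces a
triangular-like output whose excess kurtosis is about $-0.6$, and there the
95 % percentile half-width is $\approx 1.90\,s$, visibly narrower than
$1.96\,s$ (39 vs 40 mV). Both numbers are carried in every budget row so
the reader can use whichever convention their reporting standard requires.

## Analytic cross-check

`gum_propagate()` implements first-order propagation:
$u(Y)^2 = \sum_i (\partial y/\partial X_i)^2 u(X_i)^2$ with sensitivities
taken by central finite differences at the nominals (relative step
$10^{-6}$, with the absolute step floored at $10^{-6} u(X_i)$ so
zero-nominal quantities like $v_{in-}$ are differentiable). Numeric rather
than symbolic sensitivities keep user-supplied expression models working
without a computer-algebra dependency; for this smooth model the step
balances truncation against round-off comfortably.

For the amplifier the analytic combined uncertainty agrees with the Monte
Carlo standard deviation within a fraction of a percent — the model is
nearly linear — and `compare_gum_mcm()` reports the relative differences
together with the skewness and excess kurtosis of the Monte Carlo sample.
The Monte Carlo route remains the reference: it propagates whole
distributions, not just second moments, which is exactly what the
final-stage shape shows the analytic route cannot do.

## Design variants

`apply_tolerance()` rebuilds the bounded PDFs of named components at a new
tolerance. The two variants bundled in the configuration are the
interesting design questions for this front-end: substituting 0.1 %
resistors in the preamplifier only (its budget share collapses from about
2.1 % to 0.2 % of the mean, and the total expanded uncertainty drops from
about 112 to 99 mV), and substituting them everywhere (total about 90 mV,
3.5 % of the mean). The dominant residual contributor is the electrode
signal itself — a measurand property no component upgrade can touch —
which is the kind of conclusion this methodology exists to make visible.

## Synthetic signals and parameter estimation

The baseline and noise PDF parameters of the model are the kind of numbers
one estimates from waveform recordings, so the package bundles signal
tools plus a generator to validate them against.

`generate_ecg()` sums Gaussian-shaped P, Q, R, S, T deflections at fixed
offsets per beat (R peak centred in each beat interval; default amplitudes
0.15, −0.10, 1.00, −0.25, 0.35 mV and widths 25, 8, 10, 8, 40 ms — typical
resting adult morphology). It emulates the features the estimators care
about — sharp QRS energy up to tens of Hz, non-zero per-beat DC, strict
periodicity — and deliberately not heart-rate variability, beat-to-beat
morphology change or pathological rhythms. Passing round-trip tests on it
therefore demonstrates estimator correctness under clean periodic
morphology, not robustness to arrhythmia.

`add_baseline_and_noise()` superimposes the constant offset, optional slow
sinusoidal wander and white Gaussian noise. `estimate_noise_params()`
inverts it:

* **baseline** — mean and sd of a 2-s running-*median* trend. The window
  (reciprocal of the 0.5 Hz trend/cardiac boundary, below the cardiac
  fundamentals) passes wander and rejects beats; the median matters
  because the ECG waveform has a non-zero per-beat DC (~0.06 mV at the
  default amplitudes) that a moving *average* would absorb into the
  baseline, a 2 % bias on a 3 mV offset. The running median sits on the
  between-beat level and recovers the offset within ~0.3 %.
* **noise** — the residual above a 30 Hz zero-phase low-pass. QRS
  complexes genuinely contain energy above 30 Hz, so a plain MAD of the
  residual is biased high by ~9 %; the estimator therefore flags samples
  exceeding 3×MAD, dilates the flag by ±50 ms to cover the correlated
  leakage around each burst, re-computes the MAD on the quiet samples, and
  rescales by the filter's white-noise residual bandwidth (computed from
  its frequency response) to report a full-band sd. Recovery error on
  generator output is within ±2.5 %. The bandwidth rescaling assumes
  spectrally flat noise — for strongly coloured noise the reported sd is
  the flat-equivalent.

`lowpass_filter()` is a 4th-order Butterworth applied forward and backward
for zero phase; the family and order are chosen for passband flatness
(≤ 2 % amplitude error below half the cut-off) with a usefully steep
stop-band (a 40 Hz tone retains < 1 % power through the 30 Hz filter).
Because the underlying forward-backward filter applies no edge padding,
the wrapper adds odd-symmetric reflection padding of about `10 fs/cutoff`
samples and trims it afterwards; all signal operations preserve sampling
rate and sample count. `power_spectrum()` reports the two-sided,
zero-centred squared Fourier magnitude normalised by the number of
frequency samples (so `sum(power) == sum(x^2)`), and `ecg_spectrogram()`
wraps a Hann-windowed short-time transform with the same per-window
normalisation.

## Numerical choices and degenerate inputs

* Sampling order is the declaration order of quantities from one seeded
  stream; per-source runs reuse the same matrix, so a budget is one draw,
  many projections.
* `required_samples()` guards its ceiling against floating-point dust
  (`1e4/(1-p)` is not exactly representable at, e.g., `p = 0.90`).
* PDF validation is strict (`sigma > 0`, `a < b`, exactly the declared
  family's parameters); a degenerate "point" source is represented by an
  arbitrarily tight PDF rather than a special case.
* The nominal of every quantity must match its PDF mean within 1 part in
  $10^3$ — budget percentages are taken against the row mean, and a silent
  nominal/mean mismatch would bias every row.
* Expression models are parsed once and evaluated in a restricted
  environment (arithmetic, parentheses, unary math); undeclared names and
  non-arithmetic calls are rejected at construction.
* Monte Carlo runs refuse `m < 1000`: below that the summary statistics
  are too noisy to be meaningfully compared with anything.

## Problem sizes

The bundled analyses run at the study conditions, $M = 2\times10^5$, where
a full budget (five rows plus total) takes on the order of a second and
the complete configured pipeline — base system plus both variants with
analytic comparisons — stays within a minute on a single core. The test
suite exercises distribution moments at $10^6$ draws and everything else
at $5\times10^3$ to $2\times10^5$.

## Known limitations

* All input quantities are treated as independent; correlated tolerances
  (e.g. same-batch resistors) are out of scope.
* The output model is static; near- and above-corner attenuation is not
  folded into the voltage budget.
* Op-amp non-idealities (offset, bias current, finite CMRR) are not
  modelled — the budget covers the declared sources only.
* The Monte Carlo engine is fixed-size, not adaptive; choose $p$ (hence
  $M$) rather than a convergence criterion.
* The synthetic ECG is a fixture generator, not a physiological simulator.
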