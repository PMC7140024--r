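---
title: "Models and methods behind scaffoldperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scaffoldperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldperm)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the defaults and why they were chosen,
the numerical decisions, and what the synthetic-data tests do and do not
establish about real laboratory data.

## The falling-head permeability model

A cylindrical tissue sample (diameter 3 mm, thickness $\Delta x$ = 2 mm
by default) is held between porous plates under a standpipe of internal
diameter 6 mm filled with fluid to an initial height of 210 mm. The
pressure difference across the sample is purely hydrostatic, so flow
through it is assumed to follow Darcy's law,
$Q = K A_s \gamma H(t) / \Delta x$, with $K$ the permeability
coefficient (mm⁴/(N·s)), $A_s$ the sample cross-section, $\gamma$ the
fluid specific weight and $H(t)$ the instantaneous column height.
Conservation of volume between standpipe (cross-section $A_p$) and
sample gives $A_p\,dH/dt = -Q$, whose solution is the exponential decay
implemented in `column_height()`:

$$H(t) = H(t_0)\exp\left[-K \frac{A_s}{A_p} \frac{\gamma}{\Delta x}(t-t_0)\right].$$

Assumptions worth stating: the flow is slow enough for Darcy's law to
hold (no inertial or non-Darcy corrections), the sample does not compact
during the run ($\Delta x$ constant), and the fluid column is the only
pressure source. None of these is checked from data; they define the
model's scope (see Non-goals below).

**Units.** Lengths in mm, forces in N, time in s, so $K$ comes out in
mm⁴/(N·s) — the natural bench unit for these devices; `k_to_si()`
converts to m⁴/(N·s). The fluid defaults to water at bench temperature,
$\gamma = 9.81\times10^{-6}$ N/mm³ (9.81 kN/m³). With the default
geometry this reproduces the device's nominal pressure-gradient
endpoints, 1.03 kPa/mm at 210 mm and 0.49 kPa/mm at 100 mm, exactly to
two decimals. The permeating fluid's identity and temperature are not
modelled; $\gamma$ is a configurable scalar for exactly that reason.

**Analysis window.** Observations are used only while the column is
between 210 and 100 mm (closed interval, boundaries included). Above the
start height readings are settling transients; far below, relative
reading error grows and the pressure gradient leaves the regime the
device was characterized in. The window is part of `device_geometry()`
and can be overridden.

## Estimating K

For a trace of observed heights $H_{i,\mathrm{exp}}$ at times $t_i$, the
single unknown $K$ minimizes the mean squared *relative* residual

$$I(K) = \frac{1}{N}\sum_i \left[1 - H(t_i)/H_{i,\mathrm{exp}}\right]^2 .$$

Relative rather than absolute residuals weight the whole descent evenly:
a 1 mm error at 100 mm matters twice what it does at 210 mm, matching
the constant relative precision of reading a graduated pipette.

Numerics: the log-linear regression of $\ln H$ on $t$ gives a slope
whose negation is the decay rate, hence a closed-form initial $K$; a
bounded golden-section/parabolic search on $[0, 100\,K_\mathrm{init}]$
then minimizes $I$ with relative tolerance $10^{-10}$. The objective is
smooth and, for noiseless traces, unimodal in $K$ (asserted in the test
suite by grid scan), so no multistart is needed. A non-decaying trace —
flat or rising log-slope, as measurement jitter can produce on
near-impermeable fresh tissue — is clamped to $K = 0$ with a warning
recorded on the estimate rather than an error: it is a legitimate
physical reading, not a corrupt input. The clamp threshold is a slope of
$-10^{-12}$ s⁻¹, seven orders below the slowest decay of interest, so it
only absorbs floating-point jitter. The clock origin $t_0$ defaults to
the trace's first observation time (devices rarely share a clock), which
also makes the fit invariant to time-origin shifts.

When a sample is measured repeatedly, each repeat is fitted on its own
and the sample's $K$ is the mean of repeat-level fits;
`reliability_summary()` reports per-sample mean, sd and CV, emulating a
reference-material protocol of five repeats on one sample and eight
samples of the same material. Group comparisons
(`compare_permeability_groups()`) run pairwise Mann–Whitney tests on
per-sample estimates — permeabilities are positive, right-skewed and
small-sample, so a rank test is the defensible default; Student's t is
available by flag.

## Dose–response and the IC50

Viability wells are normalized to the mean untreated signal of their own
(cell line, setting, timepoint) stratum (`normalize_viability()`), so
100% is that stratum's untreated level by construction. Untreated wells
are drug-free, so drug identity does not enter the stratum. The model is
the four-parameter logistic on $\log_{10}$ concentration in the
inhibitory parameterization (slope > 0, viability falling with dose),
with $V(\mathrm{IC}_{50}) = (\mathrm{top}+\mathrm{bottom})/2$ by
definition. `top` is initialized at 100 but left free — a screen that
does not fully kill at the top concentration should not be forced to —
and `bottom` is constrained to $[0, \mathrm{top}]$.

Fitting runs two routes and keeps the lower residual sum of squares:

* a bounded Gauss-Newton pass (PORT algorithm) over all four parameters,
  started at top = 100, bottom = the smallest observed response (floored
  at 0), slope = 1, and the IC50 at the first concentration whose mean
  response crosses the midpoint;
* a variable-projection search: for fixed (slope, log IC50) the model is
  linear in (bottom, top), so those are profiled out analytically and a
  bounded quasi-Newton search runs over the two nonlinear parameters
  only, followed by a Gauss-Newton polish.

The second route exists because direct four-parameter least squares on
small dose grids has flat, occasionally degenerate directions; the
profile search is immune to the top/bottom collinearity and reliably
lands in the right basin. Fits are fitted on well-level points, not
replicate means, preserving the error structure. Combination treatments
indexed by one component (a 25:5:1 fixed-ratio cocktail reported by its
largest component) are handled by treating the index component's
concentration as the dose axis.

**Identifiability on 4-point screens.** The default screening design —
concentrations {0.1, 1, 10, 100} µM, triplicates, ~5 percentage points
of well noise — does not pin the midpoint tightly when all four
asymptote and shape parameters are free. On simulated screens (true IC50
log-uniform in 0.3–30 µM, slope 0.5–3) the median relative IC50 error is
about 17%, and an exhaustive grid search for the global least-squares
optimum achieves the same: the limit is the information in twelve noisy
wells, not the optimizer. Fixing both asymptotes at their true values —
maximal regularization, unavailable in practice — only reaches ~10%.
The test suite therefore holds the fitter to the exhaustive-search
benchmark rather than to a tighter bound no least-squares estimator can
attain, and a companion test shows the error dropping below 10% on an
8-point grid. Practical advice follows directly: for IC50s meant to be
compared across culture settings, run more than four concentrations.
Fold changes (`compare_settings()`) are more stable than their
components, since shared normalization error cancels.

## Quantification and cohort filters

Count-based readouts start from count tables; image segmentation is
upstream and out of scope. Percentages are exact ratios
(`100*positive/total`), group dispersion is the sd across images and is
labelled sd — the field's bare "±" is ambiguous, so the output says
which it is. The xenograft filters follow two rules: embryos with fewer
than 100 cells at 2 h post-injection are dropped — *strictly* fewer, so
a count of exactly 100 is retained — and the 72 h timepoint is dropped
for the whole cohort when fewer than half of the retained untreated
embryos still carry cells at 72 h. Per-embryo removals go to an
exclusion log (log rows + retained rows = input rows, an invariant the
tests assert); the timepoint decision is cohort-level and reported as a
separate field, not a log row. Fluorescence response is each embryo's
caudal signal divided by its own time-0 signal, so embryos act as their
own baselines.

## Statistical conventions

The parametric/non-parametric choice is an explicit flag, never
auto-detected from the data — normality pre-tests at n = 3–8 are noise,
and silent auto-switching makes reports irreproducible. The t-test is
Student's (pooled variance) by default with Welch as a toggle. Multiple
comparisons: one-way ANOVA with Bonferroni-corrected pairwise t-tests,
or Kruskal–Wallis with Dunn's post hoc (rank-sum z statistics from the
pooled ranking, tie-corrected variance, Bonferroni family correction —
the standard formulation). Mann–Whitney uses the exact U distribution
when both groups have at most 8 observations and no ties; beyond that,
the normal approximation with tie and continuity correction. Stars
follow the strict thresholds 0.05 / 0.01 / 0.001.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure each analysis
assumes: exponential descents with multiplicative Gaussian height noise
(constant relative reading precision on a graduated pipette); log-normal
between-sample permeability spread with group medians ordered fresh <
recellularized < decellularized; Hill-curve well signals with additive
noise around a configurable raw control level (so normalization is a
real operation on generator output); binomial marker counts; Poisson
injected-cell counts around 200 with log-normal per-24 h fluorescence
decline and arm-specific retention.

Defaults encode the emulated study designs: 5 repeats × 8 samples for
the reliability protocol, 8 samples per tissue group, the
{0.1, 1, 10, 100} µM screening grid with triplicates at 24/48/72 h, 50
embryos per arm, ~200 injected cells. The group median permeabilities
(50 / 500 / 2000 mm⁴/(N·s)) are synthetic magnitudes — chosen so a
simulated descent completes in minutes of simulated time and the groups
are cleanly ordered — not measured tissue values, which exist only as
figure charts in the literature this emulates.

What the generators deliberately do **not** contain: temporal drift or
meniscus-reading bias in height traces (noise is independent across
observations), plate edge effects or signal nonlinearity in viability
wells, spatial or optical structure in counts (every nucleus is an
independent Bernoulli draw), and any definition of the caudal region —
fluorescence inputs are taken as already-integrated signals. Passing
recovery tests on this synthetic data therefore establishes that the
estimators are correct and well-calibrated *under the stated error
model*; it does not establish robustness to systematic instrument error,
which only real data can probe.

Test and acceptance problem sizes — 200 simulated traces for recovery,
1000 replications for the reliability-CV oracle and type-I-error
calibration, 100 simulated screens for IC50 recovery, 200 scenario runs
for the group-separation rate — were chosen as the smallest sizes at
which the Monte-Carlo error of each checked quantity is comfortably
below its assertion margin.

## Known limitations

* No non-Darcy flow, tissue compaction, or time-varying thickness; a
  sample that compacts under the column will read as time-varying $K$.
* No uncertainty intervals on single-trace $K$ beyond repeat-level
  dispersion; the model's residual structure is not propagated.
* The IC50 midpoint is weakly identified on 4-point screens (above);
  reported IC50s from such screens carry ~15–20% typical error even
  with a perfect fitter.
* No pharmacokinetics: drug penetration into the scaffold is treated as
  instantaneous and uniform, which the permeability measurements
  motivate but do not prove.
* The plate-reader signal is treated as an arbitrary monotone viability
  proxy; no background subtraction or linearity correction is applied.
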