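# scaffoldperm

Quantitative analytics for studies that decellularize patient-derived
tumor tissue, reseed the scaffold with cancer cells, and ask whether the
3D construct behaves like a usable preclinical drug-testing model. The
package covers the four quantitative stages such a study runs, for
bench scientists and analysts who have the raw lab tables (filtration
traces, plate-reader wells, image-derived counts, per-embryo xenograft
records) and want a reproducible, scriptable pipeline instead of
spreadsheet arithmetic.

## What it computes

**1. Falling-head permeability.** A tissue disc (area $A_s$, thickness
$\Delta x$) is clamped under a standpipe (area $A_p$) filled to height
$H(t_0)$. Flow through the sample obeys Darcy's law,

$$Q = K\,A_s\,\gamma\,H(t)/\Delta x,$$

with $\gamma$ the fluid specific weight and $K$ the permeability
coefficient in mm⁴/(N·s). Mass conservation between pipe and sample
turns this into an exponential column decay

$$H(t) = H(t_0)\,\exp\!\left[-K\,\frac{A_s}{A_p}\,\frac{\gamma}{\Delta x}\,(t - t_0)\right],$$

and $K$ is estimated per trace by minimizing the mean squared relative
residual

$$I(K) = \frac{1}{N}\sum_{i=1}^{N}\left[1 - \frac{H(t_i)}{H_{i,\mathrm{exp}}}\right]^2$$

over the observations inside the 210–100 mm analysis window. A
reliability summary (per-sample CV over repeated measurements) and
Mann–Whitney group comparisons (fresh vs recellularized vs
decellularized tissue) sit on top.

**2. Chemosensitivity.** Plate-reader viability is normalized to the
untreated wells of each (cell line, culture setting, timepoint) stratum,
a four-parameter logistic

$$V(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + 10^{\,s\,(\log_{10} c - \log_{10} \mathrm{IC}_{50})}}$$

is fitted on log concentration, and the 3D-vs-2D sensitivity shift is
reported as an IC50 fold change.

**3. Count-based quantification.** Percent-positive summaries of marker
count tables (Ki67/MIB1, EdU, TUNEL, ...), drug–cell co-localization
percentages, and the zebrafish xenograft cohort rules: embryos with
fewer than 100 cells at 2 h post-injection are excluded (with a complete
exclusion log), the 72 h timepoint is dropped when untreated retention
falls below 50%, and treatment effects are read as caudal fluorescence
fold changes versus baseline.

**4. Statistical reporting.** Two-sided Student's t / Mann–Whitney for
two groups (exact U distribution at small n), one-way ANOVA + Bonferroni
or Kruskal–Wallis + Dunn for several, and the usual star convention
(\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001).

Seed-deterministic generators (`gen_*`) emulate all four input kinds so
everything is testable without lab data.

## Worked example

```r
library(scaffoldperm)

# one noisy filtration trace of a decellularized sample, then fit K
tr <- gen_filtration_trace(k_true = 1500, n_points = 50,
                           noise_sd_rel = 0.01, seed = 7,
                           sample_id = "decell_01", group = "decellularized")
fit_permeability(tr)
#> Permeability fit: sample decell_01 (decellularized, repeat 1)
#>   K = 1495.67 mm^4/(N s); objective I = 9.35e-05; 49 points in [100, 210] mm

# a 2D-vs-3D drug screen at IC50s of 1.3 and 11.58 uM
plate <- rbind(gen_dose_response(1.3,  setting = "2D",  seed = 1),
               gen_dose_response(11.58, setting = "3DT", seed = 2))
norm <- normalize_viability(plate)
fit_2d  <- fit_dose_response(norm[norm$setting == "2D"  & norm$conc_uM > 0, ])
fit_3dt <- fit_dose_response(norm[norm$setting == "3DT" & norm$conc_uM > 0, ])
fit_3dt
#> Hill fit: IC50 = 13.29 uM (slope 0.926, top 99.9%, bottom 0%)
#>   rss = 195.9 over 12 wells; converged: TRUE
compare_settings(fit_3dt, fit_2d, "3DT", "2D")$fold_change
#> [1] 9.16  # the 3D culture needs ~9x more drug for the same inhibition

# group comparison in the reporting convention
two_group_test(c(12, 18, 25, 31), c(210, 340, 480, 520),
               parametric = FALSE, comparison = "fresh vs decellularized")
#> fresh vs decellularized [mann_whitney]: statistic = 0, p = 0.02857 (*)
```

The fitted K sits within 0.3% of the generating value, the recovered
IC50s reproduce the simulated ~9-fold sensitivity shift, and the exact
Mann–Whitney p-value (complete separation at n = 4 vs 4) is 2/70 ≈ 0.029.

`run_full_analysis()` ties the stages together from a JSON config and
writes per-stage CSVs plus a JSON summary and run manifest; a thin
command-line wrapper with `simulate` / `fit-perm` / `fit-ic50` /
`quantify` / `compare` / `run-all` subcommands lives at
`inst/cli/scaffoldperm.R`.

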