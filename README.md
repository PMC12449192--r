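# xanthoq

Quantitative analysis of xanthophyll-cycle-driven non-photochemical quenching
(NPQ) in diatoms, with a mechanistic simulator of the diadinoxanthin (Dd) and
violaxanthin (Vx) cycles under enzyme knockouts.

Diatoms dissipate excess absorbed light as heat (NPQ), driven by the
light-regulated de-epoxidation of xanthophyll pigments: the one-step Dd cycle
(diadinoxanthin ⇄ diatoxanthin, Dd ⇄ Dt) and the two-step Vx cycle
(violaxanthin ⇄ antheraxanthin ⇄ zeaxanthin, Vx ⇄ Ax ⇄ Zx). Under prolonged
high light (HL) the pool is additionally replenished by de novo synthesis from
β-carotene. `xanthoq` is for photophysiologists who need to turn pigment
tables (HPLC, pigment:chl *a* molar ratios) and pulse-amplitude-modulated
maximum-fluorescence traces (F′m) into the standard quantities of this
analysis, and to test those analysis chains end to end against a simulator
with known ground truth.

## What it computes

* **Pigment metrics** — pool sums (Dd+Dt, Vx+Ax+Zx, epoxidized Dd+Vx+Ax,
  de-epoxidized Dt+Zx) and de-epoxidation states
  `DES_Dd = Dt/(Dd+Dt)`, `DES_Vx = (Zx + Ax/2)/(Vx+Ax+Zx)`.
* **Quenching** — the diatom low-light-reference convention (no dark
  adaptation): `NPQ = (Fm − F′m)/F′m` with Fm the first low-light (LL) pulse,
  and the rapidly relaxing component `qE = (F″m − F′m)/F′m` with F″m at the
  end of the 30 min recovery, which cancels the slowly relaxing
  photoinhibition term qI.
* **Recovery kinetics** — first-order fits of qE relaxation (R0) and Dt→Dd
  epoxidation (kT), and the consecutive two-step chain Zx→Ax→Vx (kZ, kA) via
  the closed-form (Bateman) solution, including the equal-rate limit and the
  Ax transient peak time `ln(kZ/kA)/(kZ − kA)`.
* **Quenching-pool regression** — OLS of qE against five candidate
  de-epoxidized pool deltas (Dt; Zx; Dt+Zx; Dt+Zx+½Ax; Dt+Zx+Ax), per strain
  and combined, plus a continuous estimate of the Ax weight.
* **Group statistics** — per-time-point Welch tests of mutant vs wild type
  with Holm correction, and a Shapiro–Wilk normality screen.
* **Synthetic data** — a light-gated mass-action ODE model of both cycles
  (VDE, ZEP2, ZEP3, de novo synthesis) for wt, *vde* KO, *zep2* KO and
  *zep3* KO genotypes under a 5-day 6 h HL : 18 h LL regime, with a
  fluorescence emulator and seeded replicate noise.

## Worked example

```r
library(xanthoq)

params <- scenario_params(seed = 1)           # cv 5 %, n = 3 replicates
ds     <- generate_dataset(params, genotypes = c("wt", "zep2_ko"))

qe    <- compute_quenching(ds$fluorescence)
rates <- fit_recovery_kinetics(ds$pigments, qe)
aggregate(estimate ~ strain + parameter, rates, mean)
#>    strain parameter   estimate
#> 1      wt        kA 0.05623749
#> 2 zep2_ko        kA 0.04422933
#> 3      wt        kT 0.12224900
#> 4 zep2_ko        kT 0.11134945
#> 5      wt        kZ 0.16677430
#> 6 zep2_ko        kZ 0.15395179
#> 7      wt        R0 0.12288304
#> 8 zep2_ko        R0 0.09910443
```

The fitted recovery rates (min⁻¹) sit on the generating constants: the wild
type relaxes Dt at kT ≈ 0.12 and runs the Zx→Ax→Vx chain at kZ ≈ 0.165,
kA ≈ 0.055 (Ax transient peaking near `ax_peak_time(0.165, 0.055)` ≈ 10 min),
while the *zep2* KO, lacking the slow always-on epoxidase, is consistently
slower (0.11 / 0.155 / 0.045).

```r
# candidate-pool comparison on the noise-free mean trajectories
mean_params <- scenario_params(cv_pigment = 0, cv_fluor = 0, n_replicates = 1)
ds0  <- generate_dataset(mean_params, genotypes = c("wt", "zep2_ko"))
qe0  <- compute_quenching(ds0$fluorescence)
fits <- fit_pool_models(qe0, build_delta_pools(ds0$pigments))
select_best_pool(fits)
#> [1] "dt_zx_half_ax"
#> attr(,"r_squared")
#> [1] 0.8420935
```

Among the five candidate pools, Dt + Zx + ½Ax explains qE best across both
strains (combined R² 0.842, against 0.840 for the full-Ax variant and 0.796
for Dt + Zx) — the signature that the Vx-cycle pigments contribute to
quenching with antheraxanthin counting at half weight. At the default
replicate noise (5 % CV, n = 3) the top candidates sit within noise of each
other, so on a single noisy dataset the ranking can flip; the vignette
discusses this.

Plot helpers: `plot_pigments()`, `plot_quenching()`,
`plot_pool_correlation()`, and `autoplot()` methods for fit objects.
`run_pipeline(seed = 1, out_dir = "out")` executes the whole chain
(simulate → metrics → quenching → kinetics → correlation → statistics) and
writes every table as CSV plus the resolved configuration and a log.

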