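# stdnmr

Ligand-observed NMR binding analysis for weak, fast-exchanging
protein–ligand systems — the regime typical of protein–glycosaminoglycan
recognition (e.g. sulfated heparin-mimetic oligosaccharides binding a
growth factor such as FGF-1, Kd in the µM–mM range). When binding is too
weak for competition assays and the ligand is in large excess, the
observables of choice are ligand resonances: saturation transfer
difference (STD) intensities, transferred NOEs, and selective longitudinal
relaxation times. This package turns per-proton peak-intensity tables into
binding epitopes and IC50 values, and forward-simulates STD intensities
from a complex structure.

## What it computes

**STD build-up initial rates.** Per-proton STD fractions
(I₀ − I_sat)/I₀ versus saturation time are fitted to

    STD(t) = a · [1 − exp(−b t)]

where `a` = STDmax (asymptotic plateau) and `b` = k_sat (1/s). The initial
rate `STD0 = a·b` removes the proton-relaxation dependence of
single-time-point STD values; relative STD0 (percent of the per-compound
maximum) maps the binding epitope.

**STD amplification-factor IC50.** STD-AF = STD × [L]₀/[P]₀. The initial
slopes STD-AF₀ across a ligand titration form a binding isotherm fitted to
a Langmuir equation, AF₀(L) = AF₀max·L/(L + IC50).

**Selective-T1 IC50.** Under two-site fast exchange with ligand excess,

    1/T1obs = 1/T1free + f_bound/(T1bound + τ_bound)

and, dropping the free-relaxation term in the dilute limit,

    [P]₀·T1obs = ([L]₀ + IC50)(T1bound + τ_bound)

so a line through ([L]₀, [P]₀·T1obs) crosses the x axis at −IC50.
Inversion-recovery traces are fitted to f(t) = I₀[1 − a·exp(−t/T1)] with
the inversion efficiency `a` free.

**CORCEMA-ST-style forward simulation.** From proton coordinates of the
free ligand and the bound complex, exchange kinetics (Kd, kon) and
correlation times, the package assembles the exchange-coupled complete
relaxation matrix over {free-ligand, bound-ligand, bound-protein} spins,
clamps the saturated protein protons at zero magnetization, and propagates
the deviation magnetization by the matrix-exponential solution of the
linear system, yielding predicted STD build-up per ligand proton and an
NOE R-factor against experiment. The two-spin cross-relaxation rate
σ = (q/r⁶)[6J(2ω₀) − J(0)] changes sign at ω₀τ = √5/2, which is also the
package's model for the tr-NOESY sign flip on binding.

Every input has a seedable synthetic generator (`gen_buildup`,
`gen_af_titration`, `gen_t1_titration`, `gen_toy_complex`), so the whole
pipeline is testable by parameter recovery without any spectrometer data.

## Worked example

```r
library(stdnmr)

## epitope mapping: three anomeric protons of one trisaccharide
curves <- lapply(list(c("H1-A", 0.28), c("H1-B", 0.34), c("H1-C", 0.42)),
                 function(p) gen_buildup(a = as.numeric(p[2]), b = 1, sigma = 0,
                                         proton_label = p[1], ligand_id = "1"))
std0_table(lapply(curves, fit_buildup))
#>   ligand_id proton_label std0 relative_std0
#> 1         1         H1-A 0.28            67
#> 2         1         H1-B 0.34            81
#> 3         1         H1-C 0.42           100

## selective-T1 IC50 from inversion-recovery traces (80-640 uM ladder,
## 20 uM protein); generator truth 49.2 uM is recovered exactly
tr  <- gen_t1_titration(49.2, sigma = 0, output = "traces")
res <- t1_ic50(tr)
sprintf("IC50 = %.1f uM, R^2 = %.4f", res$ic50, res$r_squared)
#> "IC50 = 49.2 uM, R^2 = 1.0000"

## Langmuir isotherm with 2% noise
fit_langmuir(gen_af_titration(10, 1.7, sigma = 0.02, seed = 4))
#> Langmuir isotherm fit: AF0max = 10.43 /s, IC50 = 1.815 +/- 0.045 mM

## STD prediction for a toy 2+3-proton complex at the default conditions
## (30 uM protein, 1.5 mM ligand, Kd 10 uM, 600 MHz, tau_c 22/0.4 ns)
sys <- gen_toy_complex(2, 3, seed = 42)
predict_std(sys, corcema_conditions(), c(0.5, 1, 2, 3, 4))
#> CORCEMA STD prediction: 2 ligand protons x 5 saturation times
#>           L1      L2
#> [1,] 0.03831 0.02471
#> [2,] 0.05719 0.04043
#> [3,] 0.07228 0.05481
#> [4,] 0.07670 0.05930
#> [5,] 0.07803 0.06067
```

The STD0 table reads: magnetization is spread fairly evenly along the
three rings (67/81/100%), the signature of an extended binding epitope.
An IC50 of 49.2 µM from the T1 route versus ~1.8 mM from the STD-AF route
illustrates the large method-dependent dispersion these weak systems show;
the package reproduces each estimator and does not reconcile them.

## Command line

```sh
stdnmr simulate t1-titration --ic50-uM 49.2 --sigma 0 --out traces.csv
stdnmr t1-ic50 --input traces.csv --output report.json
stdnmr fit-buildup --input peaks.csv --output table.csv
stdnmr corcema-predict --complex complex.pdb --tsat 0.5,1,2,3,4 --output std.csv
```

Exit codes: 0 success, 2 validation failure, 1 computational failure.
The wrapper script is installed at `inst/exec/stdnmr`
(`Rscript <library>/stdnmr/exec/stdnmr ...` or add it to PATH).

## Documentation

The methods vignette (`vignettes/ligand-observed-binding.Rmd`) describes
the models, assumptions, tunable parameters, numerical choices, what the
synthetic generators do and do not emulate, and known limitations.
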