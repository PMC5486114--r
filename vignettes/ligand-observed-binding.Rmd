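---
title: "Ligand-observed NMR binding analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-observed NMR binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdnmr)
```

# Scope

`stdnmr` quantifies weak (µM–mM) protein–ligand binding from
ligand-observed NMR observables, the regime of protein–glycosaminoglycan
recognition where the ligand is held in fast exchange and in large excess
over the receptor. Four connected stages are implemented: STD build-up
initial rates, STD amplification-factor (STD-AF) titrations with a
Langmuir IC50, selective-T1 titrations with a linear-relation IC50, and a
complete relaxation and exchange matrix (CORCEMA-ST-style) forward
simulator of STD intensities from a complex structure. A synthetic-data
module generates every input from the same models the estimators assume,
so each stage is verified by parameter recovery.

# Equilibrium and exchange model

All stages share the 1:1 binding equilibrium. The complex concentration is
the smaller root of $[PL]^2 - (P_0+L_0+K_d)[PL] + P_0 L_0 = 0$, evaluated
in the numerically stable form $2P_0L_0/(s + \sqrt{s^2 - 4P_0L_0})$ with
$s = P_0+L_0+K_d$; $K_d = 0$ reduces analytically to the stoichiometric
limit, avoiding cancellation. Exchange is two-site:
$k_{off} = K_d k_{on}$, $\tau_{bound} = 1/k_{off}$, with
$k_{on} = 10^8\,\mathrm{M^{-1}s^{-1}}$ by default (near diffusion-limited;
only $K_d$ is usually measured for these systems). Interfaces accept µM/mM
and convert once; everything internal is molar and seconds.

The estimators report "IC50" although the single-site isotherm's
half-saturation point is algebraically a dissociation constant; the two
names are used interchangeably in this assay tradition and the package
follows that usage without asserting biological equivalence.

# STD build-up and STD0

STD fractions per proton are fitted to $STD(t) = a[1-e^{-bt}]$; the
initial rate $STD_0 = ab$ is the relaxation-corrected transfer efficiency,
and relative STD0 (percent of the per-compound maximum) maps the epitope.
Report tables round STD0 to 2 decimals and relative STD0 to integers, but
relatives are always computed from unrounded fits — reference tables
computed the same way can therefore disagree with ratios of their own
rounded columns by a unit or two. Unintegrable protons (entered as `-` in
input tables) are skipped with a warning and the maximum is taken over the
protons present.

## Numerical choice: profiled least squares

The build-up, Langmuir and inversion-recovery models all have exactly one
nonlinear parameter once their amplitude-like parameters are profiled out
(for fixed $b$, the optimal $a$ is a linear least-squares coefficient).
The fitters therefore scan the nonlinear parameter on a log grid (80
points over a generous range) and refine by Brent's method in the
bracketing interval, instead of running restarted Gauss–Newton. This was a
deliberate deviation from the more conventional `nls`-with-restarts
approach, for three reasons: (i) it cannot fail to converge, even on the
sparse 5-point curves and on near-linear curves far from saturation that
the relaxation-matrix simulator legitimately produces; (ii) Brent's search
uses only objective comparisons, so a scalar rescaling of the data leaves
the nonlinear parameter bit-identical — scale equivariance of STD0 and the
identity $AF_0 = (L_0/P_0)\,STD_0$ hold to rounding error rather than to
optimizer tolerance; (iii) it beats any finite parameter grid by
construction, which the test suite checks against 200×200 brute-force
grids. Parameter uncertainties are asymptotic standard errors from the
Jacobian at the optimum ($\sigma^2 (J^TWJ)^{-1}$).

Default fits are unweighted (no error model accompanies typical peak
tables); per-point σ columns and error-propagated weighted Langmuir fits
are available but off by default.

# STD-AF titration and Langmuir IC50

$STD\text{-}AF = STD \times L_0/P_0$ amplifies the per-ligand response by
the excess; its initial slope $AF_0$ versus ligand concentration follows
$AF_0(L) = AF_{0,max} L/(L + IC_{50})$. The fitted isotherm is strictly
increasing and concave; rescaling all $AF_0$ moves only the plateau. When
the fitted IC50 exceeds the largest concentration the fit warns that the
isotherm is not saturating and the interval is wide. The synthetic ladder
default is a geometric series two octaves either side of the target IC50 —
the source experiments do not report their ladder, so this is a documented
package choice made once for identifiability of both parameters, not a
reproduction.

# Selective-T1 IC50

Inversion-recovery traces are fitted to $f(t) = I_0[1 - a e^{-t/T_1}]$
with the inversion efficiency $a$ fitted rather than fixed at 2, because
real selective inversions are imperfect; the recovery null sits at
$t = T_1 \ln a$. Under fast exchange,
$1/T_{1,obs} = 1/T_{1,free} + f_{bound}/(T_{1,bound} + \tau_{bound})$.
Dropping the free-relaxation term and linearizing
$f_{bound} \approx P_0/(L_0 + K_d)$ gives
$[P]_0 T_{1,obs} = ([L]_0 + IC_{50})(T_{1,bound} + \tau_{bound})$: an
ordinary least-squares line through $([L]_0, [P]_0 T_{1,obs})$ crosses the
x axis at $-IC_{50}$, with a delta-method standard error.

The default estimator follows this linear relation verbatim, including its
omission of $1/T_{1,free}$ — reproduce-first, correct-second. An optional
`subtract_free` mode removes the free-ligand rate using a ligand-only
reference trace; with a finite $T_{1,free}$ generator it reduces the bias
substantially but not exactly, because the exact bound fraction is not the
linearized one. The suite documents (as a property, not an error) that the
verbatim estimator's bias is monotone in $1/T_{1,free}$, and that the
full two-site generator converges to the linear model as
$T_{1,free} \to \infty$ — the residual deviation at $T_{1,free} = 10^6$ s
is bounded below around $10^{-3}$ at practical ladders because the
free-rate term $X(L+K_d)/(T_{1,free}P_0)$ and the linearization error
$\sim P_0 L/(L+K_d)^2$ trade off against each other.

Packaged benchmark configs fix the ladder to 80–640 µM at 20 µM protein
(1:4 … 1:32), the standard setup for this assay. Default generator
$T_{1,bound}+\tau_{bound} = 0.1$ s, a plausible bound-state value for a
small saccharide riding a ~16 kDa protein, putting $T_{1,obs}$ at
0.6–4 s over the ladder.

# Relaxation/exchange matrix simulator

The bound state comprises the ligand protons plus every protein proton
within a cutoff (default 8 Å) of any ligand proton. Dipolar rates use the
isotropic rigid-rotor spectral density $J(\omega)=\tau/(1+\omega^2\tau^2)$
(prefactors live in the rates): $\sigma = (q/r^6)[6J(2\omega_0)-J(0)]$ and
$\rho = (q/r^6)[J(0)+3J(\omega_0)+6J(2\omega_0)]$, with
$q = \tfrac{1}{10}\gamma_H^4\hbar^2(\mu_0/4\pi)^2 =
5.6965\times10^{10}\,\mathrm{Å^6 s^{-2}}$ from CODATA constants; tests
compare rate ratios wherever possible so they are convention-proof. Pairs
involving methyl protons use the Lipari–Szabo model-free density with
internal correlation time 10 ps and $S^2 = 0.25$ (threefold-axis
geometry). The sign change of $\sigma$ at $\omega_0\tau=\sqrt5/2$
reproduces the transferred-NOE sign flip on complexation at 600 MHz: a
0.4 ns free trisaccharide sits just past the null (weak/near-zero
cross-peaks), a 22 ns complex is deep in the negative spin-diffusion
regime.

Magnetization is tracked in concentration units over the blocks
{free ligand, bound ligand, unsaturated bound protein}. Exchange enters
with pseudo-first-order rate $k_{on}[P]_{free}$ (free→bound) and $k_{off}$
(bound→free); written this way the kinetic part has zero column sums over
each exchanging pair, i.e. it conserves ligand magnetization (a tested
invariant). Saturation is modeled as instantaneous and complete: the
user-specified saturated protein spins are clamped at zero z-magnetization
from $t=0$, entering the linear system $\dot w = -Dw + c$ as the constant
source $c$. The solution $w(t) = (I - e^{-Dt})D^{-1}c$ is evaluated by
eigendecomposition of $D$, falling back to the scaled-and-squared matrix
exponential (`Matrix::expm`) when the eigenbasis is ill-conditioned; the
two routes agree to ~1e-8 and both are checked against an independent
adaptive Runge–Kutta integration of the same system. The reported STD
fraction of a ligand proton is its population-weighted total deviation,
$-(w_{free}+w_{bound})/L_0$.

Simplifications, all deliberate and documented:

* **Bound-state correlation time.** All bound-state pairs use the complex
  $\tau_c$ (rigid complex); the free-vs-bound-ligand distinction is in the
  two matrices, not in per-pair mobility.
* **Free protein omitted.** At ~1:50 protein:ligand the free-protein
  saturation dynamics are irrelevant to ligand STD.
* **Single pose.** Geometry comes from one bound conformation;
  population-weighted multi-pose averaging is possible by summing
  predictions but is off by default, matching single-binding-mode
  analyses. Systems that average over poses with opposite faces engaged
  cannot be described by one structure — the simulator makes no attempt
  to fix that.
* **Leak relaxation.** An optional uniform external rate `rho_leak`
  (default 0) emulates unmodelled sinks; with it the build-up time
  constant is bounded, which is also how the test suite keeps simulated
  curves in their saturating regime.
* **Saturated set is explicit input.** Which protein protons fall in the
  irradiated band depends on chemical shifts the package does not predict.
  For PDB input the default is all protein methyl protons (irradiation in
  the methyl region); `chain:resname` filters override it.

The PDB reader is a minimal fixed-column ATOM/HETATM proton reader
(ownership: HETATM or named ligand residues; methyls: HB1/HB2/HB3-style
triples sharing a stem, a bare `H`+digit stem is never a methyl). It
rejects structures without explicit hydrogens rather than guessing
positions — protonate upstream.

# Synthetic data: what a green test establishes

Each generator is the pushforward of the corresponding estimator's model:
mono-exponential build-up (clipped to [0,1]), Langmuir isotherms,
inversion-recovery traces under the linear or full two-site model, and
packed random toy complexes (pairwise distances ≥ 1.7 Å, ligand protons
inside the cutoff shell). Noise is additive Gaussian, by default relative
to the signal, at 2% for STD-type data and 1% for T1 data — plausible
spectrometer-grade values chosen once, since the source experiments report
no noise figures. All randomness flows through one seeded helper that
restores the caller's RNG state.

Noise-free generation followed by estimation is the identity on
parameters, and the published benchmark values (STD-AF IC50 1.70 mM;
selective-T1 IC50s 49.2/84.7/180.9/132.4 µM; STD0 0.42 s⁻¹) are used as
generator ground truths for those round trips. That is deliberately
circular: it verifies the estimators, the algebra and the plumbing, not
the original spectra, which were never deposited. What the generators do
not emulate: spectral overlap and baseline errors, partial saturation
spill-over, temperature drift between titration points, heteroscedastic
integration noise, or any FID-level effect. A green suite therefore
establishes correctness of the analysis chain, and the stochastic
calibration tests (median |IC50 error| ≤ 10% at the stated noise levels
and ladders) establish its statistical behaviour under idealized noise —
no more.

# Known limitations

* Single-site 1:1 binding only; no cooperative or ternary models.
* The two IC50 estimators can disagree by more than an order of magnitude
  on real weak electrostatic complexes (the motivating system shows
  1.70 mM vs 49.2 µM for the same compound); the package reproduces each
  method and does not arbitrate.
* The CORCEMA module predicts; it does not refine $K_d$ or poses against
  experimental STD.
* Config files are JSON (no YAML reader in the dependency set).
* CPMG/T1ρ, relaxation dispersion, and raw spectrometer data are out of
  scope: the package consumes integrated peak intensities.
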