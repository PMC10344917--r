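---
title: "Modeling ternary-complex formation and degradation SAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ternary-complex formation and degradation SAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternarySAR)
```

## The system and the model

A PROTAC (P) is a heterobifunctional molecule that binds an E3 ligase (L)
through one ligand and a target protein (T) through the other ("warhead"),
so that degradation proceeds through a ternary complex L·P·T. Four coupled
equilibria govern the system: the two binary engagements (dissociation
constants $K_{LP}$, $K_{TP}$) and the two paths into the ternary complex,
summarised by the ternary dissociation constant $K_{LPT}$. The cooperativity

$$\alpha = \frac{K_{LP}}{K_{LPT}}$$

measures how much the target's presence strengthens (or weakens) the
PROTAC--ligase interaction through protein--protein contacts: $\alpha > 1$
is synergistic, $\alpha < 1$ antagonistic.

`eq_params()` bundles these constants (all in nM; unit conversion belongs at
the I/O boundary, not inside the model). `solve_ternary()` computes the
exact equilibrium for arbitrary totals. The ternary binding polynomial of a
cooperative system has no useful closed form, so the solver reduces the
problem to one dimension: for a trial free-PROTAC concentration $p$ the two
protein conservation laws become a quadratic whose positive root gives free
T (and then free L) in closed form, and the remaining PROTAC-conservation
residual is strictly increasing in $p$ on $[0, P_t]$. A bracketing
bisection driven to machine precision finds the unique root; a
cancellation-free form of the quadratic (dividing out the subtractive
root) keeps the result accurate even when one total dwarfs the others.
Degenerate inputs (any total equal to zero) short-circuit to the binary or
empty closed forms so that no mass-action ratio ever evaluates 0/0.

`hook_curve()` sweeps a PROTAC titration and exhibits the hook effect:
past the optimum, excess PROTAC sequesters both proteins in unproductive
binary complexes and the ternary complex collapses.

### The surface (SPR) limit

On a sensor chip the immobilised ligase is vanishingly dilute relative to
every solution-phase scale, and the preformed binary complex is maintained
by running the target at roughly 25-fold excess over $K_{TP}$. In that
limit the maximal ternary fraction over a titration has the closed form

$$\frac{[LPT]_{\max}}{[L]_t} \simeq \frac{\alpha}{\alpha + \beta},
\qquad
\beta = \frac{\left(\sqrt{K_{LP}/K_{TP}} + 1\right)^2}{25},$$

implemented by `max_ternary_fraction()` and `beta_factor()`. The excess
factor 25 is exposed as an argument (`excess`) rather than hard-coded,
since it is an assay design choice. Note a small rounding wrinkle: for
matched binary affinities the formula gives $\beta = 4/25 = 0.16$, which
discussions of this model conventionally round to 0.2; the package
implements the formula and leaves the rounding to the caller. The
equilibrium tests verify that the numeric maximum of `hook_curve()` under
the surface constraint ($L_t = 10^{-4}\,\min(K_{LP}, K_{LPT})$, $T_t = 25
K_{TP}$) reproduces this closed form within 5% across $\alpha \in [0.1,
100]$ and affinity ratios in $[0.1, 10]$. The surface limit is modeled as
a concentration limit only; flow-cell mass transport (diffusion-layer
thickness) is deliberately out of scope.

## Ubiquitination initial rate

Under rapid binding equilibrium the initial rate of target ubiquitination
is

$$v = \frac{V_{\max}}
{\left(1 - \frac{K_{LPT}}{K_{LP}}\right) +
 \left(1 + \frac{[P]_t}{K_{LP}}\right) \frac{2 K_{LPT}}{D}},
\qquad
D = S - \sqrt{S^2 - 4 [P]_t [T]_t},\; S = [P]_t + [T]_t + K_{TP},$$

where $V_{\max}$ is the product of the ternary-complex breakdown rate
constant and total ligase. $D$ is exactly twice the binary target--PROTAC
complex concentration, so the package evaluates it through the same
stable quadratic root as the equilibrium module
(`binary_complex()`) -- the naive subtractive form loses all precision in
the saturation regime. Substituting $\alpha$ gives the equivalent
normalised form implemented by `normalized_rate()`; the two
implementations agree to $10^{-10}$ relative over random parameter draws
(they are one equation), which the test suite asserts.

Two limiting regimes matter for SAR reasoning:

* **Linear regime** ($[P]_t$ far below $[T]_t$, $K_{LP}$, $K_{TP}$):
  $v/V_{\max} \approx [P]_t / (2 K_{LPT})$ (`linear_rate()`): potency-side
  degradation readouts should track ternary affinity.
* **Saturation regime** ($[P]_t$ far above those scales):
  $v/V_{\max} \approx \alpha [T]_t / (2 [P]_t)$ (`saturation_rate()`):
  rate-side readouts at maximally active dose should track cooperativity.

The saturation expression is implemented exactly as stated, but the exact
$P_t \to \infty$ asymptote of the full rate law is $\alpha [T]_t / [P]_t$
-- a factor 2 larger. The discrepancy is recorded and tested (the ratio
converges to 2), not silently "fixed": the stated form is kept verbatim
because its role is the proportionality $v \propto \alpha$, which the
factor does not affect. Zero totals return the analytic limit 0 rather
than raising, so rate curves can start at $[P]_t = 0$.

## SPR data reduction

`simulate_sensorgram()` and `fit_langmuir()` use the closed-form 1:1
Langmuir solution per phase (association toward $C R_{\max}/(C + K_D)$
with observed rate $k_{on} C + k_{off}$; exponential dissociation), never
numerical integration -- the model is piecewise analytic, so fitting the
closed form is both faster and exact. Single-cycle mode carries the
response at each injection boundary forward as the next phase's initial
condition, mirroring sequential injections without regeneration;
multi-cycle mode restarts each concentration from a bare surface. The fit
estimates $(k_{on}, k_{off}, R_{\max})$ in log space for positivity, with
$k_{off}$ started from the log-linear tail of the final dissociation.
By construction $K_D = k_{off}/k_{on}$ and the complex half-life is
$t_{1/2} = \ln 2 / k_{off}$.

For ternary assays the analyte is the PROTAC premixed with excess target;
target excess is assumed saturating so the 1:1 model applies to the
ternary complex itself. Real ternary dissociation can be bi-phasic
(binary rebinding); the 1:1 treatment is the standard reduction and is
what the fitted half-lives mean here. Instrument-specific corrections
(solvent correction, drift) are out of scope; `reference_subtract()`
provides the single-pass reference subtraction. Non-identifiable input
(a flat trace, or a single concentration) returns a failure report with a
reason instead of an error, so batch reduction never crashes.

`fit_steady_state()` fits the equilibrium isotherm
$R = R_{\max} C/(C + K)$; on a noiseless synthetic system its $K$ and the
kinetic fit's $K_D$ agree to $10^{-3}$ relative (tested).

## Cellular degradation metrics

`normalize_poc()` converts raw signals to percent-of-control. The
dose-response reduction follows the standard plate workflow:

* **4PL fit** (`fit_dose_response()`): variable-slope logistic on
  $\log_{10}$ concentration. The reported DC50 is the concentration at
  which the *fitted curve* crosses 50 POC -- not the EC50 parameter; the
  two differ whenever the fitted asymptotes are not exactly 0 and 100.
  When the curve never reaches 50 within the tested range the DC50 is
  censored and rendered as "> top-tested". Dmax is reported both as
  $100 - \text{fitted bottom}$ (clamped to $[0, 100]$) and as the
  observed $100 - \min(\mathrm{POC})$, because tabulated Dmax values in
  the field are ambiguous between the two.
* **AUC** (`auc_trapezoid()`): trapezoid area over the dose *index* with
  unit spacing, so a 10-point curve pinned at 100 POC scores
  $100 \times 9 = 900$. The 10-point 1:3 titration is the package's
  default dose design -- the only count under which a flat non-degrader
  curve yields that canonical 900.
* **Hook handling**: points above 100 POC at the top doses can be masked
  from the 4PL fit (`mask_top`) while still counting toward the AUC,
  since the AUC is a description of the observed curve and the 4PL is a
  model of the monotone part.
* **Time course** (`fit_time_course()`): one-phase decay
  $\mathrm{POC}(t) = \text{plateau} + (\text{start} -
  \text{plateau})e^{-kt}$. The degradation half-life is the fitted
  curve's 50-POC crossing solved in closed form (interpolation on the
  model, not on raw points), the rate constant is $\tau = 0.693/t_{1/2}$
  and the initial degradation rate is $100\tau$ %/min. The constant
  0.693 is used as such because that is how the rate is conventionally
  defined in degradation work; the SPR module uses exact $\ln 2$. A
  fitted plateau at or above 50 POC censors the half-life with a reason.

## Correlation-based SAR

`sar_cor()` wraps Pearson and Spearman correlation with explicit
per-variable scale flags; two-tailed significance comes from the exact
t-distribution null (Pearson) or the exact small-sample Spearman null via
`stats::cor.test`, with a seeded Monte-Carlo permutation option for
small panels. The scale convention is configuration, not hard-coding:
affinity and cooperativity axes are conventionally displayed
log-scaled, but which scale reproduces a given published coefficient
varies by panel, so `default_sar_pairs()` records one choice per pair
(log10 cooperativity against linear rate; linear ternary affinity
against rate; log-log affinity against DC50) and users can edit it.
Censored DC50 values are excluded by default; `include_censored = TRUE`
substitutes the censoring bound as a sensitivity analysis, since
inclusion rules for censored potencies are rarely stated.

The packaged compound tables (`compound_table()`) ship as plain CSV with
an MD5 manifest checked at load time, so transcription drift is an error
rather than a silent change. For the BRD4-BD2 panel the packaged
configuration reproduces the published coefficients exactly at display
rounding (0.99 for log-cooperativity against initial rate; -0.90 for
linear ternary affinity against rate). The corresponding SMARCA2
coefficients are *not* pinned anywhere: the published compound subset for
those panels is ambiguous, so the pipeline simply reports what the table
yields. One tabulated cooperativity (the 210/33 nM compound) is
consistent with its affinity ratio only once the rounding of the printed
affinities is propagated; the test suite encodes exactly that
rounding-interval rule.

## Geometric scoring of candidate ternary models

The structural toolkit scores externally generated candidate models; it
performs no conformational search, docking, MD or force-field energetics.

* **Clash filter**: cross-component heavy-atom pairs closer than 2.2 Å
  (`count_clashes()`); a model is kept when protein--protein clashes ≤ 5
  and protein--PROTAC clashes ≤ 2 (`assembly_filter()`, thresholds
  configurable).
* **Pose pruning** (`warhead_similarity()`): after superposing models on
  the shared ligase (Kabsch), the warhead is summarised by its centre of
  geometry and the principal axes of its coordinate scatter; models are
  similar when the COG distance is < 6 Å and the first *and* second
  principal-axis deviations are each < 20°. The two-separate-angle-tests
  reading is the most literal one of "deviation in the first and the
  second principal axes"; axis angles are folded to $[0°, 90°]$ because
  eigenvectors have no sign.
* **Strain/RMSD selection** (`model_selection()`): linker strain energies
  are *inputs* (they come from a force-field engine outside this
  package); the two-stage rule keeps models with strain ≤ 4 kcal/mol and
  finally selects those within thermal fluctuation (≤ 0.6 kcal/mol) with
  warhead RMSD < 3 Å. A missing strain value fails pruning with an
  explicit reason.
* **SASA/BSA**: `sasa()` is a Shrake--Rupley implementation over a
  deterministic Fibonacci lattice (default 960 points, probe 1.4 Å,
  Bondi-style radii pinned in a versioned CSV; hydrogens ignored). A
  deterministic lattice makes areas reproducible bit-for-bit; at 960
  points the quadrature error against the 1- and 2-sphere closed forms
  is below 0.5%, and buried-area *differences* carry roughly 1--2%
  error, which the tests budget for. `buried_surface_area()` decomposes
  the burial as protein--protein (computed on the PROTAC-removed
  two-body subsystem) plus protein--PROTAC (the remainder), so the two
  terms sum to the total by construction; small negative quadrature
  residues are clamped to zero. The algorithm, probe and radii set used
  by any given published workflow are usually unstated, so all three are
  configurable here.

`read_ternary_pdb()` maps PDB chains/residue names to components via a
small configuration list (first model, altloc "A" preferred), using
`bio3d` when available.

## Synthetic data: what it emulates, and what it does not

Every input format has a seeded generator, so the whole pipeline is
testable without instrument data, and the generators' defaults are the
study conditions, not tuning knobs:

* `generate_spr_dataset()`: 5-point five-fold dilution from 100 nM,
  60 s contact, 300 s final dissociation (single-cycle) or 120 s
  (multi-cycle), Gaussian noise of 1 RU on an $R_{\max} = 100$ RU
  surface -- the scale of a low-density ternary-assay surface.
* `generate_degradation_dataset()`: 10-point 1:3 titration from
  10 µM, POC noise 3 (typical plate replicate scatter), truth at the
  potent-degrader scale (DC50 8 nM, Dmax 98, half-life 36.5 min, i.e.
  initial rate 1.9 %/min); the hook option derives the dose-response
  truth from the exact equilibrium via `hook_curve()` instead of a 4PL.
* `generate_toy_complex()`: equal spheres on a line with only adjacent
  overlaps, so every buried area follows the spherical-cap closed form
  and the analytic truth ships with the model.

Gaussian noise on closed-form truths is all these generators claim:
no plate effects, drift, mass-transport artifacts, bi-phasic
dissociation or compound-specific behaviour. Passing recovery tests
therefore demonstrates that the fitters are unbiased and correctly
implemented at realistic noise, not that real instrument data will be
this clean.

All randomness flows through one explicit seed argument per call, and
the generators restore the caller's RNG state, so seeded runs are
byte-stable and composable.

## Problem sizes and numerical tolerances used by the test suite

The suite cross-checks the equilibrium solver against an independent
fixed-point/bisection oracle on 100 random systems (relative $10^{-8}$)
and sweeps conservation/non-negativity over 1000 random systems; rate-law
identity is checked to $10^{-10}$ relative on 100 draws; kinetic recovery
runs a 50-replicate seeded study at 1 RU noise (sampling interval 2 s to
keep the study quick); dose-response and time-course recovery use
20-replicate studies; clash counting is compared with a quadratic
all-pairs oracle on 100 random systems; permutation p-values are checked
against full enumeration at $n = 6$. These sizes were chosen to give the
oracles real coverage while keeping a full run around half a minute.

## Known limitations

* The equilibrium model is well-mixed and closed: no synthesis,
  degradation-driven target depletion, or compartmentalisation; cellular
  dose-response shapes will deviate accordingly.
* The SPR surface limit ignores transport; measured on-rates on dense
  surfaces can be transport-limited, which the 1:1 fit will absorb into
  biased constants.
* The ubiquitination model stops at the ternary-complex turnover
  abstraction ($V_{\max}$): no explicit E2 kinetics, chain elongation or
  proteasome engagement.
* BSA is a geometric surrogate for interface quality; it carries no
  energetics and is comparable only within one ligase--target system.
* The correlation module makes no multiplicity correction and fits no
  regression models: it reports pairwise coefficients, as SAR panels of
  this size warrant nothing stronger.
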