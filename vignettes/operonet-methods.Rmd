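---
title: "From regulatory graphs to mass-action models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From regulatory graphs to mass-action models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonet)
```

## The modeling framework

`operonet` turns a *double graph* — a vertex set with an activation edge set
and a repression edge set — into a chemical reaction network under mass-action
kinetics, and derives everything downstream (rate equations, conservation
laws, steady states, thresholds, spatial patterns) from that single object.

The kinetic picture is the Jacob–Monod operon model. Every vertex with
incoming regulation edges stands simultaneously for a gene and its protein.
The gene carries binding sites for its regulators, and the occupancy pattern
of those sites is an explicit chemical species (an *operon state*). Two
semantics are supported:

* **per-site** (`per_site`): each regulator has its own site; a gene with
  $a$ activators and $r$ repressors has $2^{a+r}$ operon states.
* **one-site** (`one_site`): all regulators compete for a single site; the
  gene has $a + r + 1$ states (free, or bound by exactly one regulator).

The compiler emits, for each gene:

* reversible binding/unbinding between each free regulator protein and the
  operon (`kb_<gene>_<reg>`, `ku_<gene>_<reg>`), at most bimolecular;
* catalytic transcription `state -> state + protein` from every operon state
  with at least one activator bound, one rate per occupancy pattern
  (`kp_<gene>_<tag>`) — under per-site semantics a state that has an
  activator *and* a repressor bound still transcribes, with its own
  (typically small) rate, which calibration is free to set;
* first-order degradation of the free protein (`kd_<protein>`). A regulator
  bound to DNA does not degrade while bound; this keeps the gene totals
  exactly conserved.

Genes never degrade: they are catalysts. Consequently the stoichiometric
matrix $\Gamma$ has, for every gene, a left-null vector summing its operon
states, and the total gene concentration is a conserved quantity. These
conservation laws are not a numerical nicety — they are the mechanism behind
concentration thresholds (below).

Two modeling conventions fill gaps the framework leaves open:

* a gene with **no incoming activation edges** transcribes at a basal rate
  from its repressor-free state (`kp_<gene>_basal`); a gene that could never
  produce would be inert by construction;
* vertices flagged as **mRNA** are annotation-only: translation of maternal
  transcripts is folded into initial protein concentrations rather than
  modeled as kinetic reactions. This matches how the *Drosophila* model is
  calibrated, where maternal *bcd*/*hb* transcripts appear only through the
  initial BCD and HB protein profiles.

## Rate equations and exact conservation laws

For reaction $j$ with reactant stoichiometries $\alpha_{ij}$ the flux is
$v_j = k_j \prod_i X_i^{\alpha_{ij}}$ and the system is
$\dot{X} = \Gamma v(X)$, a polynomial (at most quadratic — binary collisions)
vector field. Constant species (pure regulator inputs such as BCD and TLL)
are excluded from the state and folded into the rate factors; otherwise every
constant input would generate a spurious conservation law.

Conservation laws are computed as a basis of the left null space of $\Gamma$
in **exact rational arithmetic** (`R/rational.R`): a reduced row echelon form
with numerator/denominator bookkeeping, scaled to coprime integers with
positive leading coefficient. Stoichiometric entries are tiny integers, so
doubles hold every intermediate exactly. The payoff is bit-stable laws:
`t(w) %*% Gamma` is *identically* zero, not zero up to rounding, and the test
suite asserts `max(abs(...)) == 0` literally.

`reduce_by_conservation()` eliminates one chosen species per law through the
affine relation the law implies, and differentiates the reduced system by the
chain rule through that affine lift, so reduced Jacobians are analytic too.

## The emergent concentration threshold

The simplest self-activating gene (protein A activates its own operon)
compiles to three state variables — free operon $A_0$, bound operon $A_1$,
protein $A$ — with the law $A_0 + A_1 = C$. The reduced two-variable system
is

$$\dot{A_1} = k_b A (C - A_1) - k_u A_1, \qquad
  \dot{A} = -k_b A (C - A_1) + (k_u + k_p) A_1 - k_d A.$$

It has the trivial steady state $(0, 0)$ and the positive branch
$A^* = k_p C / k_d - k_u / k_b$, $A_1^* = k_d A^* / k_p$. The Jacobian at the
trivial branch is

$$J(0) = \begin{pmatrix} -k_u & k_b C \\ k_u + k_p & -k_b C - k_d \end{pmatrix},
\qquad \det J(0) = k_u k_d - k_b k_p C,$$

with negative trace, so the trivial branch loses stability exactly where the
determinant changes sign:

$$C^* = \frac{k_u\, k_d}{k_b\, k_p}.$$

This is a transcritical bifurcation tuned by the conserved gene total: below
$C^*$ the protein relaxes to zero, above it to a level increasing
continuously in $C$. `threshold_scan()` reproduces this numerically —
steady states and stability on a grid of $C$, then bisection (relative
tolerance $10^{-6}$) on the leading eigenvalue of the trivial branch — and
the tests require agreement with the closed form above to a relative
$10^{-4}$, plus the stability exchange on both branches. In the limit
$k_d \to 0$, $C^* \to 0$: without degradation any amount of gene suffices.

Steady-state location uses multistart damped Newton iteration (default 50
log-uniform random starts plus the origin and scaled coordinate vertices,
fixed internal seed, steps confined to the non-negative orthant), analytic
Jacobians, deduplication at $10^{-8}$, and a stability margin of $10^{-9}$ on
the leading real part for the `marginal` label.

## Spatial patterning without transport

`simulate_field()` runs the compiled kinetics independently at every position
of a shared grid on $[0,1]$ (scaled embryo length, default 100 points):
regulator inputs vary with position but are constant in time, and there is no
diffusion or advection — whatever pattern appears is produced purely by the
threshold response to the non-homogeneous inputs. The stacked system is
integrated in a single `deSolve` call through a compiled C right-hand side
with a banded Jacobian (block width = state dimension), which is numerically
identical to position-by-position integration but far faster.

When every regulator is a constant input the kinetics are affine in the
state, and `linear_steady_state()` solves the per-position steady state
exactly: conservation constraints are substituted first (they fix the gene
totals), then the reduced linear system is solved; positive rates make it
nonsingular. The regression suite requires the linear solution and the
$t \to \infty$ integration to agree to a relative $10^{-8}$.

The demonstration fixture is one protein C with a spatially flat activator
and two *flanking* Gaussian repressor profiles (centers 0.1 and 0.9, width
0.18, amplitude 5 — chosen once as a readable caricature of
anterior/posterior repression; the grid uses 101 points so symmetric peaks
are sampled at a point rather than a plateau). Both semantics produce a
single interior spike between the repressor domains; under per-site
semantics the repressor-bound production rates must of course be set small
(0.02, 0.01), since with all production rates equal repression would be
ineffective by construction.

## The gap-gene model

The *Drosophila* cross-regulation network — BCD activates *hb* and *kni*;
HB and KNI repress each other; TLL represses *kni*; BCD and TLL constant;
maternal HB as initial condition — compiles under per-site semantics to

* 4 *hb*-operon states (sites: BCD, KNI),
* 8 *kni*-operon states (sites: BCD, HB, TLL),
* the proteins HB and KNI,

i.e. 14 state equations per position, with exactly two conservation laws
(one gene total per gene); `build_gapgene_model()` asserts both counts as
internal trip-wires. Initial operon occupancy is the fully-free state at the
gene total — the natural pre-transcription condition. Gene totals are
spatially uniform fit parameters, and the readout time `T` is deliberately a
*free parameter*: predicted profiles are out-of-equilibrium patterns at time
`T`, not steady states.

## Synthetic study and calibration

Because the quantified embryo profiles live in an external database, the
package generates a synthetic stand-in study (`generate_inputs()`,
`generate_ground_truth()`): an exponential anterior BCD gradient (decay
length 0.2), a sigmoidal maternal HB domain (midpoint 0.45, width 0.05), a
posterior TLL bump (center 0.85, width 0.05) with a small anterior bump, all
in arbitrary units on the unit interval; Gaussian noise with
$\mathrm{sd} = a + b\,\mathrm{value}$ (defaults $a = 0.02$, $b = 0.05$),
clipped at zero with the sd recorded. The documented ground-truth rates put
the model in a *moderate-binding* regime — dissociation constants of order
the mid-embryo input levels (binding 5–8 versus unbinding 1), weak
transcription from repressor-bound states, degradation 0.1, readout
`T = 6` — chosen so that operon occupancies respond smoothly to the
gradients. This matters for the recovery study: in a switch-like
strong-binding regime the chi-square surface around the generating
parameters becomes needle-sharp relative to the measurement noise, and an
objective-level recovery criterion would be unattainable by construction
rather than informative. In this regime the study reproduces the qualitative
biology: an anterior HB domain and a single posterior KNI stripe, with no
transport. What passing these tests shows is that the *machinery*
(compiler, integrator, calibrator) is correct and that the threshold
mechanism suffices for patterning; it does not validate the model against
real embryo measurements, which differ in registration error, non-Gaussian
noise, embryo-to-embryo variability and unknown true kinetics.

Calibration minimizes $\chi^2 = \sum_s \sum_{x \in \mathrm{mask}_s}
\left((\mathrm{pred} - \mathrm{obs})/\mathrm{sd}\right)^2$ over the fitted
species $s$, reporting per species also the reduced (penalized) statistic
$\chi^2 / (N - p)$ — the "penalized chi-square" is implemented as this
standard reduced form, since no other formula is specified anywhere.
Fit masks (x-ranges per species) are configuration, mirroring the practice
of scoring each gap protein only in the region its regulators are modeled.

The optimizer is a generational genetic algorithm on $\log_{10}$ parameters:
Latin-hypercube initialization, tournament selection (size 3), BLX-$\alpha$
blend crossover (rate 0.7, $\alpha = 0.5$: children are sampled in the
per-gene parent interval extended by half its length on each side, which
lets the population track the narrow curved valleys typical of ODE
chi-square surfaces), Gaussian mutation (rate 0.25, sigma 0.3 in log10
units, optionally annealed geometrically), elitism (2), reflection at the
bounds, failures scored $+\infty$, fully deterministic under a seed.
Parameter-wise recovery is *not* asserted anywhere: the model is sloppy, and
many rate combinations produce indistinguishable profiles. Recovery is
asserted at the objective level — the GA must reach within 20% of the
objective value scored by the generating parameters on the noisy data.

Default problem sizes were chosen for desk-scale runs: 50 spatial positions
for calibration (100 for simulation fixtures), population 200 with at most a
few hundred generations and early stopping after 30 stalled generations, and
class-specific bounds spanning the plausible ranges of each parameter type
in the scaled units of the study.

## Numerical choices

* Integration: `deSolve::lsoda`, `rtol = 1e-8`, `atol = 1e-10` by default
  (`1e-6`/`1e-8` inside the calibration objective, where chi-square needs
  only ~0.1% accuracy); states are clamped at zero inside the right-hand
  side so small negative integrator excursions cannot generate spurious
  fluxes. Conservation drift along trajectories stays below $10^{-6}$
  relative, which the test suite asserts on randomized networks.
* "Steady" for nonlinear spatial comparisons means integrating to a time
  where $\max |\dot{X}| < 10^{-8}$ (in practice `t_final = 500` for the
  spike fixture).
* Ties and degenerate inputs: duplicate steady-state roots are merged at
  $10^{-8}$; a conservation law whose chosen species has zero coefficient is
  an error; systems with a state-variable product are rejected by the linear
  solver with a not-applicable error.
* Peak counting (`interior_maxima()`) merges equal-value plateaus before
  counting strict interior maxima, so symmetric profiles sampled on even
  grids are not double-counted.

## Known limitations

* Cooperative binding, regulator dimerization and chromatin state are out of
  scope; so are stochastic (master-equation) refinements and Hill-function
  reductions.
* Spatial structure is a 1D axis of independent positions: no diffusion,
  advection, growth or discrete nuclei.
* The affine closed-form solver applies only when all regulators are
  constant inputs; self- and cross-regulating networks must be integrated.
* The gap-gene model covers HB/KNI cross-regulation with BCD/TLL inputs
  only; the anterior and posterior extremes of real embryos are under
  additional regulators, so fits there are expected to be masked out.
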