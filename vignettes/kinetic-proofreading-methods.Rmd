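---
title: "Modeling kinetic proofreading in DNA strand-displacement networks"
author: "kproof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinetic proofreading in DNA strand-displacement networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kproof)
```

## The system and the model

Kinetic proofreading (KP) enhances molecular recognition by spending chemical
fuel to exploit one binding free-energy difference at more than one step of a
reaction cycle. `kproof` models an enzyme-free DNA implementation of this
motif built from toehold-mediated strand displacement (TMSD) and
handhold-mediated strand displacement (HMSD). A template strand T invades a
blocked monomer ML to form the intermediate MT; from MT the system branches:
a proofreader strand P strips the monomer into inert waste MP and recovers
the template (the discard pathway), or a second monomer N completes
dimerization to the product MN, again recovering T. Mismatched monomer
variants bind the template more slowly *and* are proofread faster, so the
same single-base free-energy difference acts twice — the direct analog of
Hopfield's cycle, with the template as the recognition site.

Five networks cover the experimental programme:

* `template_binding` — ML + T &#8652; MT + L;
* `template_recovery` — MT + P &#8652; MP + T, with the waste reporter
  MP + RQ &#8594; MPR + Q;
* `full_discard` — the union of the two, triggered by template injection;
* `dimerization` — adds MT + N &#8594; MN + T (HMSD) and a dimer reporter,
  optionally a direct monomer-reporter leak, and optionally several monomer
  variants competing in one pool;
* `snp_detection` — a blocked probe discriminating a target strand from
  single-base mutants, with reporter, proofreader and a sink that
  sequesters proofread waste.

Every reaction is an *effective* uni- or bimolecular mass-action step. TMSD
binding physically proceeds through a transient three-strand complex, but
the experimentally reported quantity is an effective second-order rate
constant, so the one-step description is the default; `two_step = TRUE`
rebuilds the binding block with an explicit MLT intermediate for sensitivity
analysis. Blocker/template exchange and proofreading are reversible;
reporter, dimerization and sink steps are irreversible (they are strongly
thermodynamically driven by design). Single-nucleotide discrimination enters
only through per-variant rate constants, never structurally: the spectator
toeholds and hidden mismatches that create the drive are not modeled
base-by-base.

Species carry their strand composition, which gives one exact linear
conservation law per strand. These laws are checked symbolically at build
time (`validate_network()`) and numerically on every trajectory
(`conservation_drift()`), and they back the package-wide invariant that
every simulated strand total is constant to better than $10^{-6}$ relative.

## Simulation

`integrate_network()` solves the mass-action ODEs with a stiff-capable
integrator (deSolve's `lsoda`). Internal units are nanomolar and seconds;
bimolecular rate constants are accepted in M$^{-1}$s$^{-1}$ and converted by
$10^{-9}$ at the interface. Default tolerances are `rtol = 1e-8`,
`atol = 1e-12` nM — deliberately tight because rate constants span many
orders of magnitude; tolerance choices are the package's own, validated by
requiring self-consistency against a run at ten-fold tighter tolerances.
Concentrations may undershoot zero by integrator tolerance during a solve
and are clipped to zero only on output, never during integration.

`gillespie()` is an exact direct-method stochastic simulation, used as an
independent oracle: at $\geq 10^4$ molecules per species, replicate means
must match the ODE solution within standard error. Its seed argument is
mandatory, so every stochastic result in the package is reproducible.

## Observation and calibration

Two channels emulate the plate reader. A Cy3-like channel reports every
complex containing the labeled monomer strand; an AlexaFluor-647-like
channel reports opened reporter complexes. Signals are linear:
$s(t) = b + \sum_s \alpha_s [s](t)$, with one shared slope per fluorophore
(the fluorophore's local environment is the same in all complexes, so one
calibration serves all of them). Quenched complexes (blocked monomer,
intact reporter) keep a residual slope of 5% of the shared slope by default
— the studies list the blocked monomer among the signaling species, but no
residual value is published, so 5% is the package's choice and is
configurable (`quenched_frac`).

`signal_to_concentration()` inverts the map for a species group sharing one
slope (within 1%); `estimate_intermediate_by_subtraction()` implements the
crude intermediate estimator — unblocked monomer minus reported waste —
and tags its output accordingly. On simulations its bias is provably
nonnegative when the waste reporter is the only lagging step: a slow
reporter leaves formed waste invisible, inflating the apparent
intermediate. Both behaviors are asserted in the test suite.

## Synthetic data

The generator reproduces the statistical structure the analysis assumes:
injection-triggered time zero, a dead time before the first read (default
30 s, within the reported 10–30 s shaking window), and additive plus
proportional Gaussian noise. Default noise is 0.5% of a typical full-scale
signal additive plus 2% proportional — plausible plate-reader values, the
package's own choice since no noise model is published. Every dataset
carries its ground truth and is a pure function of (design, rates, seed).

Study presets encode the printed designs: binding wells at 8 nM blocked
monomer triggered by 2–10 nM template; recovery wells at a range of
pre-formed MT with 50 nM proofreader and 20 nM reporter; discard wells at
8 nM ML, 50 nM P, 20 nM reporter triggered by 4 nM (or a series of) T;
dimerization wells at 8 nM M'L, 10 nM N, 2 nM T' with and without 50 nM
proofreader, plus a competitive pool at 5 nM of each variant; SNP wells at
15 nM candidate, 20 nM reporter, 20 nM sink, 10 nM probe-lock, with and
without 20 nM proofreader. Two deliberate simplifications: the dimer
reporter is present from the start (the experiments added it after three
days to dodge its leak; the leak reaction is available as an option but off
by default), and sampling intervals are chosen so a full study integrates
in seconds (the `interval_scale` argument thins grids further when many
refits are needed).

The published fitted rate tables are not reproduced in the articles'
main text, so the default ground-truth rates are the package's own, fixed
once from the qualitative orderings: matched-monomer template binding of
order $10^5$ M$^{-1}$s$^{-1}$ with 10–20× slower binding for mismatched
variants, proofreading 10–20× faster for mismatched variants, dimerization
at $3.5\times10^5$ M$^{-1}$s$^{-1}$, reporters at $5\times10^4$ (waste) and
$10^4$ (SNP, deliberately slow). These reproduce the qualitative
phenomenology — binding order M1 > M2 > M3, proofreading order reversed,
discrimination factors near 1 without proofreader and several-fold with —
but make no claim to match the deposited data quantitatively.

## Fitting

The objective is a weighted mean-squared error between predicted and
observed concentrations across all traces and time points. Points before
the per-trace plateau time $t_1$ get weight $w_1 = 1$; points from $t_1$
onward get $w_2 = 0.2$ (the boundary point takes $w_2$). The published
display of the objective is not reproduced in the extracted text, so the
normalization — division by the total weight — is the package's
reconstruction; it leaves the minimizer unchanged. The plateau time was
chosen manually in the original analysis; `auto_t1()` automates it as the
earliest time from which the trace stays within 2% of its final value,
overridable per trace.

Model predictions pass through the same linear observation map as the data:
a fit trace stores per-species weights (slope ratios), so quenched species
contribute at their residual fraction on both sides and the noiseless-data
fit is exactly consistent. Unknown rates are searched in log10 space within
finite bounds by multi-start L-BFGS-B (default 8 starts: the log-midpoint
plus seeded log-uniform samples). Integration failures during a search are
mapped to a large finite objective so the optimizer can retreat. A
curvature probe at the optimum (each unknown moved a factor of two) flags
parameters the data barely constrain; the threshold compares the probe's
MSE change against $10^{-4}$ of the mean squared data value, four orders of
magnitude away from both the flagged and unflagged cases observed in
practice.

`staged_fit()` reproduces the three-stage protocol. Stage 1 fits the
blocker/template exchange rates on binding wells; these become known rates
downstream. Stage 2 handles the uncertainty in the reporter wells' total
monomer concentration by fitting the reporter rate once per candidate
concentration on a grid of 80%–115% of nominal in 5% steps — eight
candidates, matching the published count; the grid itself is the package's
choice since only "plausible estimates" is stated. Stage 3 fits the
proofreading rates per candidate simultaneously on recovery and discard
wells and selects the candidate minimizing the summed stage-3 error, ties
broken by lowest index and reported. Two design features matter for
identifiability: recovery wells at more than one MT level (only the higher
levels deplete the reporter appreciably, which separates the proofreading
and reporting stages — a single recovery curve cannot, because the
composition of two sequential pseudo-first-order steps is symmetric in
their rates), and discard wells at more than one template level.
Reverse proofreading is structurally near-unidentifiable at these designs
(its propensity is $\sim 10^{-6}$ s$^{-1}$); it is fitted, flagged weak,
and excluded from recovery assertions — the original analysis makes the
same caveat about those constants.

## Specificity statistics

`discrimination_factor()` is the endpoint product-yield ratio of the
matched variant over a mismatched one at matched inputs. The prose of the
source defines it on intermediate yields where context clearly means the
dimer products; the package computes it on product yields. The endpoint is
the final simulated time with a convergence check (yield change below 1%
over the final 10% of the run) reported alongside. `turnover_number()` is
waste per template added, with turnover above one flagging catalysis.
`initial_rate()` is a least-squares slope over a window defaulting to the
rise to 10% of plateau. `kp_enhancement_report()` ties these together for
matched dimerization arms with and without proofreader.

The idealized Hopfield cycle is implemented as a five-state master
equation over the recognition site (free, bound and activated states for
each of two competing ligands), with discrimination applied at the two
unbinding steps only and the chemical drive entering as an explicit
dimensionless ratio of clockwise to counterclockwise cycle rate products —
not as free energies in physical units. The stationary distribution is
solved exactly; enrichment equals the stationary-probability ratio of the
two activated states. Its limits — $f_0$ at detailed balance, $f_0^2$
under strong drive with slow product formation and rare activation — are
verified against an independent combinatorial solution (Markov-chain tree
theorem) in the tests.

## Numerical choices and degenerate inputs

* Integrator tolerances $10^{-8}$/$10^{-12}$ nM; self-convergence asserted
  at ten-fold tighter.
* Negative concentrations clipped only on output; conservation checked to
  $10^{-6}$ relative.
* Optimizer bounds are mandatory for unknowns; searches run in log10
  space; seeds are explicit everywhere.
* Zero rates, zero proofreader, empty candidate lists, heterogeneous
  calibration groups, non-overlapping subtraction grids, unknown species
  and degenerate (reducible) Hopfield cycles all fail fast with named
  errors — or, for diagnostics, return violation tables rather than throw.
* Selection ties are exact-equality ties, broken by lowest index and
  reported.

## Problem sizes

The test suite and the acceptance script run everything at reduced but
honest sizes chosen once: binding studies at two to three template levels
with 40–120 points per trace; recovery/discard wells at two levels each;
ten noise seeds for the recovery and selection replications; sixteen
stochastic replicates at $\geq 10^4$ copies per species for the SSA-ODE
comparison; 97–145-point grids for the three-day dimerization runs. A full
synthetic study generates in seconds; a complete staged fit takes tens of
seconds.

## What passing tests do and do not show

The synthetic generator reproduces the designs, the noise structure and
the qualitative rate orderings of the experiments, so passing tests
demonstrate that the estimation machinery is correct and that the KP
phenomenology follows from mass-action kinetics at plausible rates. They
do not validate the one-step TMSD approximation against real three-strand
intermediates, do not model pipetting/evaporation drift, inner-filter
effects or photobleaching, and make no quantitative claim about the
deposited experimental data or the real strands' thermodynamics — the
published headline discrimination factors are measured on experimental
fluorescence, and the fitted rate tables live outside the main text.
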