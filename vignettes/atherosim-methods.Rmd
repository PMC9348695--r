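---
title: "Modelling murine atherosclerosis with atherosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling murine atherosclerosis with atherosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atherosim)
library(dplyr)
```

## The model

`atherosim` implements a compartment model of early atherosclerotic plaque
formation in APOE-deficient mice. Seven normalized (dimensionless) states
evolve in time (days since birth):

* blood monocytes $MONO_B$ and blood LDL-cholesterol $L_B$, both normalized
  to 1 at baseline;
* intimal monocytes $MONO$, inflammatory macrophages $IM$, oxidized
  LDL-cholesterol $L$ and foam cells $F$ inside the plaque;
* the normalized vessel radius $R$, with $R = 1$ the lesion-free vessel.

The dynamics are

$$\begin{aligned}
MONO_B' &= k_{MONO} - d_{MONO_B}\,MONO_B\\
MONO'   &= a\,\tfrac{R^3}{R^3+\alpha}\,\tfrac{L}{1+L}\,MONO_B
           - (\epsilon + c)\,MONO\\
IM'     &= c\,MONO - b\,IM\,L\\
L_B'    &= d_{in}(t) - d_{L_B}\,L_B\\
L'      &= k_{LDL}\,L_B\,\tfrac{MONO}{f+MONO} - e\,L\,IM - d_{LDL}\,L\\
F'      &= b\,IM\,L - d_F\,F\\
R'      &= \tfrac{\xi}{2}\,\bigl(R - \tfrac1R\bigr)\,F'
\end{aligned}$$

Monocytes enter the intima at a rate that grows with plaque lipid ($L$,
saturating as $L/(1+L)$) and falls as the vessel narrows (the shear-stress
motivated factor $R^3/(R^3+\alpha)$). Macrophages convert plaque lipid into
foam cells, and only foam-cell dynamics move the radius. Lesion area is
reported relative to the lesion-free cross-section, $1 - R^2$ (the factor
$\pi$ cancels), as a percentage.

Diet and treatments act solely through the LDL-uptake input $d_{in}(t)$, a
piecewise-constant step function: normal diet is 1, high-fat diet multiplies
uptake by $d_{HFD}$, antibiotics by $d_{ABIO}$, IL-10-receptor blockage by
$d_{Immod}$ and propionate by $d_{PA}$; concurrent interventions multiply.
Evaluation is right-continuous, so a treatment acts from its start day.

Two structural facts shape everything downstream:

1. **The lesion-free state is an equilibrium, and the set
   $\{MONO = L = 0\}$ is invariant.** Monocyte influx requires plaque lipid
   and lipid influx requires intimal monocytes, so a simulation started with
   an empty intima stays empty forever, whatever $R_0$. Plaque growth needs
   both a small initial lesion $R_0 < 1$ (at $R = 1$ the factor $R - 1/R$
   vanishes and the radius can never move) and a non-zero seed in at least
   one intimal compartment. The reference calibration uses $R_0 = 0.9996$
   and seeds all four intimal states at $10^{-4}$; `read_params()` defaults
   the seeds to 0 so that a parameter file must opt in explicitly.
2. **The radius equation integrates in closed form.** Dividing $R'$ by $F'$
   gives $\mathrm{d}\ln(1-R^2) = \xi\,\mathrm{d}F$, hence along any
   trajectory
   $$1 - R(t)^2 = \bigl(1 - R_0^2\bigr)\,e^{\xi (F(t) - F(0))}.$$
   The test suite uses this identity as an analytic oracle for the
   integrator: the numerically transported radius must match the
   transformation of the numerically transported foam-cell mass to
   $10^{-7}$.

## Numerics

Integration uses `deSolve`'s variable-step multistep solver (`lsodar`,
which runs in non-stiff Adams mode for this system) at absolute and
relative tolerances of $10^{-10}$. The step input $d_{in}$ is handled by
hard restarts: integration stops at every breakpoint and resumes with the
new constant, so discontinuities are never stepped over and no smoothing is
applied. A classical fixed-step Runge–Kutta route (`method = "fixed"`) is
kept for cross-validation; at steps below 0.1 d both solutions agree to
well under $10^{-6}$ on all states, and the test suite pins this at step
0.05 d.

Integrator noise below $100\times$ the absolute tolerance is clamped to
zero inside the right-hand side; anything more negative on the output grid
raises an error, as does a radius reaching zero. A root function stops
integration as soon as $R$ falls to 0.02 (99.96% occlusion): the model has
no validity there, and stopping early makes infeasible parameter sets fail
fast during optimization instead of grinding the solver.

Reported trajectories are solver outputs at the requested grid (daily by
default); refining the grid changes no reported value beyond solver
tolerance.

## Scenarios

`builtin_scenario(1:13)` encodes the thirteen diet/treatment designs the
model was developed against: untreated controls (1, 2), high-fat diet from
week 8 (3, 5, literature) or week 16 (4), and the combinations of
antibiotics (from week 12), propionate (from week 18) and IL-10 blockage
(from week 18) under either diet. All treatments run to the end of the
observation window by default. The antibiotic course is also described as a
six-week treatment in part of the source material; `abio_weeks = 6` selects
that reading. Treatment windows with finite ends support the prediction
experiments (stop-all-interventions reversibility; propionate applied to an
established lesion).

## Parameters and the reference calibration

All rates are per day on normalized states. Three rates are fixed at 1 by
the normalization of the blood compartments ($k_{MONO}$, $d_{MONO_B}$,
$d_{L_B}$) and are excluded from fitting. The observation map multiplies
$L_B$ and $MONO_B$ by the baseline constants `L_B_nor` and `MONO_B_nor`
(data units) and reports lesion area as $100\,(1-R^2)$.

The defaults of `athero_params()`/`athero_factors()` — identical to the
bundled file `extdata/parameters_synthetic_reference.yaml` — are a
**synthetic reference calibration**: they were obtained by running the
package's own evolutionary-strategy fit against published group-level
summary values of lesion area (long-run burden under each single
intervention, scenario readouts at six months and one year, and the
diet-then-propionate rescue experiment), with $R_0$ fixed at 0.9996 and the
intimal seeds at $10^{-4}$. They are a realistic working point, not a
measured ground truth: blood-observable baselines (`L_B_nor`,
`MONO_B_nor` = 430, roughly mg/dL and cells/µL scales for this mouse
strain) in particular are stated assumptions. The fitted uptake factors
reproduce the expected intervention pattern
$d_{HFD}, d_{ABIO}, d_{Immod} > 1 > d_{PA}$ without any sign constraint
having been imposed.

With this set, "six months" and "one year" readouts are interpreted as
mouse ages of 26 and 52 weeks (the convention is configurable by passing
any readout age).

```{r}
ref <- reference_params()
tibble::tibble(
  condition = c("control", "propionate", "high-fat diet", "IL-10 blockage",
                "antibiotics"),
  din = c(1, ref$factors$d_PA, ref$factors$d_HFD, ref$factors$d_Immod,
          ref$factors$d_ABIO),
  lesion_pct = sapply(din, function(d)
    steady_state(ref$params, d)$observables$lesion_area_pct)
)
```

## Fitting

The goal function is the weighted least-squares (chi-square) sum
$$\sum_j \Bigl(\frac{f_{model}(t_j, \mathbf k) - f_{data}(t_j)}{\sigma_j}\Bigr)^2$$
over all non-holdout records of a measurement table (scenario, observable,
age, group mean, SD, n); several scenarios are fitted simultaneously by
adding their sums. The week-28 records of the untreated scenarios 2 and 4
are flagged as holdout in the bundled design: they validate predictions and
never enter the sum. Records with an unusable spread — a zero SD, or a
single-animal group — receive a floored $\sigma$ of 10% of the mean (at
least $10^{-6}$); the data this emulates contain groups of only two
animals, and the floor keeps such records informative without letting them
dominate.

Optimization uses a (1+3)-evolutionary strategy with self-adaptive
mutation step sizes. Each generation draws three offspring from the
incumbent by multiplicative log-normal perturbation; by default every free
parameter carries its own step size, mutated by a shared global factor and
a per-coordinate factor (Schwefel's rule),
$$\sigma_i' = \sigma_i\,e^{\tau N(0,1) + \tau_c N_i(0,1)}, \qquad
  \theta_i' = \theta_i\,e^{\sigma_i' N_i'(0,1)},$$
with $\tau = 1/\sqrt{2d}$ and $\tau_c = 1/\sqrt{2\sqrt d}$ for $d$ free
parameters. The coordinate-wise scheme is the default because the
chi-square surface of this model is extremely anisotropic: lesion burden
depends exponentially on foam-cell mass through the radius equation, so an
isotropic step that is productive for one parameter is hopeless for
another, and a single shared step size freezes (a measurable effect: with
one global step, not one of thousands of isotropic mutations around a
known optimum succeeds). A single-step variant remains available
(`self_adaptation = "global"`). Mutated step sizes are floored at
$10^{-6}$ so the search cannot freeze itself entirely.

Multiplicative mutation searches the natural log scale of positive rate
constants and can never produce a negative rate. Bounds
($[10^{-4}, 10^4]$ on rates and factors, $[0.9, 1-10^{-6}]$ on $R_0$) are
enforced by projection. Selection is elitist and strict — the incumbent is
replaced only by a strictly better offspring — so the fitness trace is
non-increasing by construction, and ties (e.g. a perfect zero fitness)
leave the incumbent in place. The default free set is the eleven
therapy-free kinetic parameters, $R_0$ and the four uptake factors.

For final convergence `polish_fit()` offers a Nelder–Mead simplex
refinement on the log-parameter scale, started from the ES estimate. The
evolutionary strategy handles the rugged large-scale landscape; the
simplex, whose shape adapts to the narrow curved valley around the
optimum, reliably finishes the local descent that isotropic mutation
cannot. The recovery studies below chain the two.
Search-time fitness evaluations run at relaxed solver tolerance
($10^{-8}$, or $10^{-6}$ in the heavier test fixtures); the reported
fitness is recomputed at $10^{-10}$. Stopping: a generation budget
(default 2000) or 200 generations without improvement beyond $10^{-6}$.
Offspring whose simulation fails (e.g. parameters driving the vessel to
occlusion) count as infinitely bad rather than aborting the search.

## Uncertainty

`bootstrap_ci()` implements a parametric bootstrap: each replicate redraws
every record's group mean from a normal law centred on the observed mean,
refits the model to the virtual table (starting from the point estimate,
with a reduced ES budget — 300 generations by default; the refit protocol
is a package choice), and percentile intervals are taken across replicate
estimates. The spread of the virtual means is read as the standard error
$sd/\sqrt{n}$ by default; `resample = "sd"` selects the literal-SD reading,
since "mean and variance of the existing data" admits both. Virtual means
of the non-negative observables are truncated at zero by redrawing.
Replicate seeds derive deterministically from the master seed, so the whole
computation is reproducible; the full analysis uses 1000 replicates, while
tests run 5–25 (scaled down).

`sensitivity()` perturbs each free parameter by ±1% (all others fixed) and
reports the fitness deterioration relative to the optimum. Near a genuine
local optimum both deteriorations are non-negative up to solver noise, and
the identity
$\Delta_+ + \Delta_- \approx \delta^2 p^2 \partial^2_p f$ lets the test
suite check the values against an independent finite-difference stencil.

## The synthetic-data generator

`generate_measurements()` emulates the statistical structure of the study:
sparse ages (one to three per scenario), group means with per-point SDs,
and small groups. It simulates the model under the true parameters, draws
`n` individual animals per planned point from a normal law with
coefficient of variation `cv` around the model value (truncated at zero,
since all observables are non-negative), and summarizes to mean/SD/n —
noise on lesion area is applied on the percentage scale and on the blood
observables on their measurement scales, matching how such data are
reported. Drawing individuals rather than perturbing the mean directly
makes the group size enter realistically ($SE \propto cv/\sqrt n$).
`study_design()` returns the thirteen-scenario layout: in-house scenarios
read out at ages 22 and 28 weeks (6 and 12 weeks on the assigned diet,
n = 8), literature scenarios at 26/52 weeks (scenarios 1 and 3) or
14/20/26 weeks (scenario 5) with n = 4 — the literature ages are generator
assumptions, as the sources report them only graphically. Default CVs of
10% (blood LDL) and 15% (lesion area) are likewise stated assumptions.

What the generator does *not* emulate: measurement-technique artifacts
(histology sectioning, chromatography), between-study heterogeneity of the
literature arms, non-Gaussian or correlated within-group variation, and
drop-out. Passing recovery tests on these synthetic tables therefore
demonstrates that the estimation machinery is consistent at the study's
data shape — not that the biological parameters of real mice are
identifiable beyond it.

## Scaled-down study sizes in tests

The test suite and the acceptance script keep the full pipelines but scale
replication: the recovery fit starts from a ±15% jittered truth and runs
up to three rounds of 1400 ES generations each, every round finished by a
simplex polish, stopping early once the chi-square reaches the scale
expected from 5% noise; bootstrap coverage uses two synthetic datasets ×
25 replicates over four free parameters, with a 60-generation ES refit
plus a short polish per replicate; all fitting-time solver tolerances are
$10^{-6}$ with final evaluations at $10^{-10}$. These sizes are the package's chosen test
design; the full-size analysis (2000 generations, 1000 bootstrap
replicates, 13-scenario fits) runs with the same code by changing
`fit_config()` and `n_reps`.

## Known limitations

* The model describes early, inward plaque growth; advanced plaque
  morphology, spatial structure, HDL-cholesterol, smooth-muscle cells and
  inflammation-driven monocytosis are outside its scope.
* Interventions act only through the multiplicative uptake factors; no
  pharmacokinetics.
* With 16 free parameters against sparse group means the fit is sloppy:
  lesion *trajectories* are recoverable, individual parameters need not
  be. The bootstrap intervals quantify exactly this.
* The bundled parameter set is a synthetic calibration to published
  summary values, suitable for simulation studies and as a fitting start —
  not a substitute for fitting to primary data.
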